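#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Seeded spin-glass (constant Potts) module search.
//
// The graph is passed in CSR form (ptr: length n+1, idx: length 2|E|,
// both 0-based). Node weights nw are the |z| statistics; an edge (u,v)
// carries weight (nw[u]+nw[v])/2. A candidate module S (connected, seed
// inside) is scored by
//
//    Q(S) = sum_{edges inside S} w_uv  -  lambda * |S|(|S|-1)/2
//
// where lambda = gamma * mean observed edge weight, i.e. every internal
// pair is charged the expected weight of a random edge under the
// degree-preserving rewiring null. Optimised by simulated annealing
// (geometric cooling) with restarts, followed by a greedy polish.
// Randomness comes from R's RNG so results are reproducible via set.seed().

namespace {

struct Graph {
  const int *ptr;
  const int *idx;
  const double *nw;
  int n;
  inline double w(int u, int v) const { return 0.5 * (nw[u] + nw[v]); }
};

// sum of edge weights from v into the current module
inline double link_weight(const Graph &g, const std::vector<char> &in, int v) {
  double s = 0.0;
  for (int k = g.ptr[v]; k < g.ptr[v + 1]; ++k) {
    int u = g.idx[k];
    if (in[u]) s += g.w(u, v);
  }
  return s;
}

// is the module still connected after dropping v? BFS from the seed.
bool connected_without(const Graph &g, const std::vector<char> &in,
                       const std::vector<int> &members, int v, int seed) {
  if ((int)members.size() <= 2) return true;  // seed + one other remains
  std::vector<char> seen(g.n, 0);
  std::vector<int> stack;
  stack.reserve(members.size());
  seen[v] = 1;  // pretend v is gone
  stack.push_back(seed);
  seen[seed] = 1;
  int found = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    for (int k = g.ptr[u]; k < g.ptr[u + 1]; ++k) {
      int t = g.idx[k];
      if (in[t] && !seen[t]) {
        seen[t] = 1;
        ++found;
        stack.push_back(t);
      }
    }
  }
  return found == (int)members.size() - 1;
}

inline int runif_int(int n) {  // uniform on 0..n-1 via R's RNG
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

struct State {
  std::vector<char> in;
  std::vector<int> members;
  double q;
};

void remove_member(State &st, int v) {
  st.in[v] = 0;
  for (size_t i = 0; i < st.members.size(); ++i) {
    if (st.members[i] == v) {
      st.members[i] = st.members.back();
      st.members.pop_back();
      break;
    }
  }
}

// one full greedy sweep to a local optimum: best single add or remove
void greedy_polish(const Graph &g, State &st, double lambda, int seed,
                   int max_size) {
  const double eps = 1e-12;
  for (;;) {
    double best_dq = eps;
    int best_v = -1;
    bool best_add = true;
    // candidate additions: neighbours of the module
    std::vector<char> cand(g.n, 0);
    for (int m : st.members) {
      for (int k = g.ptr[m]; k < g.ptr[m + 1]; ++k) {
        int v = g.idx[k];
        if (!st.in[v] && !cand[v]) {
          cand[v] = 1;
          if ((int)st.members.size() >= max_size) continue;
          double dq = link_weight(g, st.in, v) -
                      lambda * (double)st.members.size();
          if (dq > best_dq) {
            best_dq = dq;
            best_v = v;
            best_add = true;
          }
        }
      }
    }
    // candidate removals
    for (int m : st.members) {
      if (m == seed) continue;
      double dq = -link_weight(g, st.in, m) +
                  lambda * (double)(st.members.size() - 1);
      if (dq > best_dq && connected_without(g, st.in, st.members, m, seed)) {
        best_dq = dq;
        best_v = m;
        best_add = false;
      }
    }
    if (best_v < 0) break;
    if (best_add) {
      st.in[best_v] = 1;
      st.members.push_back(best_v);
    } else {
      remove_member(st, best_v);
    }
    st.q += best_dq;
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector grow_module_cpp(IntegerVector ptr, IntegerVector idx,
                              NumericVector nw, int seed, double lambda,
                              int max_size, double t0, double cool,
                              double tmin, int moves_per_size, int restarts,
                              double temp_scale) {
  Graph g{INTEGER(ptr), INTEGER(idx), REAL(nw), (int)ptr.size() - 1};
  if (seed < 0 || seed >= g.n) stop("seed index out of range");
  if (max_size < 1) stop("max_size must be >= 1");
  double scale = temp_scale > 0 ? temp_scale : 1.0;

  State best;
  best.q = -std::numeric_limits<double>::infinity();

  for (int r = 0; r < restarts; ++r) {
    State st;
    st.in.assign(g.n, 0);
    st.in[seed] = 1;
    st.members.assign(1, seed);
    st.q = 0.0;

    for (double T = t0 * scale; T > tmin * scale; T *= cool) {
      int sz = (int)st.members.size();
      int moves = moves_per_size * (sz > 4 ? sz : 4);
      for (int mv = 0; mv < moves; ++mv) {
        bool try_add = unif_rand() < 0.5;
        if (try_add) {
          if ((int)st.members.size() >= max_size) continue;
          // random boundary node, sampled via a random member's neighbour
          // (bias toward well-connected candidates is harmless here)
          int m = st.members[runif_int((int)st.members.size())];
          int deg = g.ptr[m + 1] - g.ptr[m];
          if (deg == 0) continue;
          int v = g.idx[g.ptr[m] + runif_int(deg)];
          if (st.in[v]) continue;
          double dq = link_weight(g, st.in, v) -
                      lambda * (double)st.members.size();
          if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
            st.in[v] = 1;
            st.members.push_back(v);
            st.q += dq;
          }
        } else {
          if ((int)st.members.size() <= 1) continue;
          int v = st.members[runif_int((int)st.members.size())];
          if (v == seed) continue;
          double dq = -link_weight(g, st.in, v) +
                      lambda * (double)(st.members.size() - 1);
          if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
            if (connected_without(g, st.in, st.members, v, seed)) {
              remove_member(st, v);
              st.q += dq;
            }
          }
        }
      }
    }
    greedy_polish(g, st, lambda, seed, max_size);
    if (st.q > best.q) best = st;
  }

  IntegerVector out(best.members.size());
  for (size_t i = 0; i < best.members.size(); ++i)
    out[i] = best.members[i] + 1;  // back to 1-based
  return out;
}

// [[Rcpp::export]]
double module_score_cpp(IntegerVector ptr, IntegerVector idx,
                        NumericVector nw, IntegerVector members1,
                        double lambda) {
  Graph g{INTEGER(ptr), INTEGER(idx), REAL(nw), (int)ptr.size() - 1};
  std::vector<char> in(g.n, 0);
  for (int i = 0; i < members1.size(); ++i) {
    int v = members1[i] - 1;
    if (v < 0 || v >= g.n) stop("member index out of range");
    in[v] = 1;
  }
  double sum_w = 0.0;
  for (int i = 0; i < members1.size(); ++i) {
    int v = members1[i] - 1;
    for (int k = g.ptr[v]; k < g.ptr[v + 1]; ++k) {
      int u = g.idx[k];
      if (in[u] && u > v) sum_w += g.w(u, v);
    }
  }
  double m = (double)members1.size();
  return sum_w - lambda * m * (m - 1.0) / 2.0;
}

// [[Rcpp::export]]
List module_internal_edges_cpp(IntegerVector ptr, IntegerVector idx,
                               NumericVector nw, IntegerVector members1) {
  Graph g{INTEGER(ptr), INTEGER(idx), REAL(nw), (int)ptr.size() - 1};
  std::vector<char> in(g.n, 0);
  for (int i = 0; i < members1.size(); ++i) in[members1[i] - 1] = 1;
  int n_edge = 0;
  double sum_w = 0.0;
  for (int i = 0; i < members1.size(); ++i) {
    int v = members1[i] - 1;
    for (int k = g.ptr[v]; k < g.ptr[v + 1]; ++k) {
      int u = g.idx[k];
      if (in[u] && u > v) {
        ++n_edge;
        sum_w += g.w(u, v);
      }
    }
  }
  return List::create(_["n_edges"] = n_edge, _["sum_weight"] = sum_w);
}
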