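# Independent oracles and small fixture builders used across the suite.

# Exhaustive search over all connected, seed-containing vertex subsets,
# scored by the same objective as the module search. Brute force (2^n),
# for graphs up to ~12 nodes.
oracle_best_module <- function(net, seed_name, gamma = 1) {
  g <- net$graph
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  sidx <- match(seed_name, igraph::V(g)$name)
  best <- -Inf
  bestS <- sidx
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (!(sidx %in% S)) next
    seen <- sidx
    front <- sidx
    while (length(front) > 0) {
      nb <- unique(unlist(adj[front]))
      nb <- nb[nb %in% S & !(nb %in% seen)]
      seen <- c(seen, nb)
      front <- nb
    }
    if (length(seen) != length(S)) next
    q <- module_objective(net, S, gamma = gamma)
    if (q > best) {
      best <- q
      bestS <- S
    }
  }
  list(objective = best, members = igraph::V(g)$name[bestS])
}

# Maximum-likelihood logistic LRT by iterative 2-parameter grid refinement;
# independent of glm. The log-likelihood is concave; the window shrinks only
# by half per refinement so the running maximum can drift along the
# correlated intercept-slope ridge without escaping the grid.
oracle_logistic_lrt <- function(x, y, iters = 40, half_a = 25, half_b = 80) {
  n <- length(x)
  ll_row <- function(a_vec, b) {
    eta <- outer(a_vec, rep(1, n)) + matrix(b * x, length(a_vec), n,
                                            byrow = TRUE)
    as.numeric(eta %*% y - rowSums(log1p(exp(eta))))
  }
  ca <- 0; cb <- 0
  ha <- half_a; hb <- half_b
  for (it in seq_len(iters)) {
    ga <- seq(ca - ha, ca + ha, length.out = 33)
    gb <- seq(cb - hb, cb + hb, length.out = 33)
    vals <- vapply(gb, function(b) ll_row(ga, b), numeric(33))
    k <- arrayInd(which.max(vals), dim(vals))
    ca <- ga[k[1]]; cb <- gb[k[2]]
    ha <- ha / 2; hb <- hb / 2
  }
  pbar <- mean(y)
  ll0 <- sum(y) * log(pbar) + (n - sum(y)) * log(1 - pbar)
  max(0, 2 * (ll_row(ca, cb) - ll0))
}

# Hypergeometric upper-tail P(X >= a) from first principles (log-binomials),
# independent of phyper/fisher.test.
oracle_hyper_tail <- function(a, n_list, n_set, n_universe) {
  kmax <- min(n_list, n_set)
  if (a > kmax) return(0)
  ks <- a:kmax
  lp <- lchoose(n_set, ks) + lchoose(n_universe - n_set, n_list - ks) -
    lchoose(n_universe, n_list)
  min(1, sum(exp(lp)))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (small n only), using the doubled-smaller-tail convention.
oracle_wilcoxon_exact <- function(x1, x0) {
  v <- c(x1, x0)
  n1 <- length(x1)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(v), n1)
  ws <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  lo <- mean(ws <= obs + 1e-9)
  hi <- mean(ws >= obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# random connected weighted test network on n nodes
make_random_network <- function(n, p = 0.35, boost = 2) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- paste0("g", seq_len(n))
  z <- stats::rnorm(n)
  hot <- sample(n, boost)
  z[hot] <- z[hot] + stats::rnorm(boost, mean = 3)
  build_weighted_network(g, data.frame(gene = paste0("g", seq_len(n)),
                                       z_dnam = z))
}

# 8-node toy: a 4-clique of high-statistic genes joined by one bridge edge
# to a 4-node path of quiet genes
make_clique_path_network <- function(z_hot = 5, z_cold = 1) {
  edges <- rbind(t(utils::combn(1:4, 2)),      # clique A B C D
                 c(4, 5),                      # bridge
                 c(5, 6), c(6, 7), c(7, 8))    # path E F G H
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- LETTERS[1:8]
  build_weighted_network(g, data.frame(
    gene = LETTERS[1:8], z_dnam = c(rep(z_hot, 4), rep(z_cold, 4))))
}

# small synthetic benchmark reused by several test files
make_small_benchmark <- function(seed = 11, n_nodes = 150, planted = 8,
                                 n_cases = 25, n_controls = 25) {
  set.seed(seed)
  simulate_fem_dataset(n_nodes = n_nodes, planted_size = planted,
                       n_cases = n_cases, n_controls = n_controls,
                       n_expr_cases = 20, n_expr_controls = 20)
}
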