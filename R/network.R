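#' Configuration for the module search
#'
#' Bundles the tunable parameters of EpiMod/FEM detection.
#'
#' @param n_seeds number of seed genes (top nodes by statistic magnitude)
#' @param max_module_size hard cap on module size
#' @param gamma spin-glass resolution: internal pairs are charged
#'   `gamma x` the network-mean edge weight
#' @param B_perm number of statistic permutations for the significance test
#' @param B_rewire number of degree-preserving rewired networks for the
#'   modularity-gap diagnostic (0 skips it)
#' @param swaps_per_edge attempted double-edge swaps per edge per rewiring
#' @param alpha per-module significance level
#' @param min_module_size smallest module retained (needs at least one edge)
#' @param t0,cool,tmin annealing schedule (temperatures in units of the
#'   network-mean edge weight; geometric cooling)
#' @param moves_per_size annealing proposals per temperature level, per
#'   current module size
#' @param restarts independent annealing restarts (best kept); a greedy
#'   polish to a local optimum always follows
#' @return list of class `fem_config`
#' @export
fem_config <- function(n_seeds = 100, max_module_size = 100, gamma = 1.0,
                       B_perm = 1000, B_rewire = 100, swaps_per_edge = 10,
                       alpha = 0.05, min_module_size = 2,
                       t0 = 2, cool = 0.95, tmin = 0.02,
                       moves_per_size = 15, restarts = 2) {
  for (nm in c("n_seeds", "max_module_size", "B_perm", "swaps_per_edge",
               "moves_per_size", "restarts"))
    .assert_scalar_count(get(nm), nm)
  stopifnot(alpha > 0, alpha < 1, gamma >= 0, B_rewire >= 0,
            t0 > tmin, tmin > 0, cool > 0, cool < 1)
  structure(list(n_seeds = as.integer(n_seeds),
                 max_module_size = as.integer(max_module_size),
                 gamma = gamma, B_perm = as.integer(B_perm),
                 B_rewire = as.integer(B_rewire),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 alpha = alpha, min_module_size = as.integer(min_module_size),
                 t0 = t0, cool = cool, tmin = tmin,
                 moves_per_size = as.integer(moves_per_size),
                 restarts = as.integer(restarts)),
            class = "fem_config")
}

# compressed sparse adjacency for the C++ search (0-based)
.graph_csr <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  ptr <- c(0L, cumsum(deg))
  idx <- integer(sum(deg))
  pos <- ptr[-length(ptr)]
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1]; b <- el[k, 2]
    pos[a] <- pos[a] + 1L; idx[pos[a]] <- b - 1L
    pos[b] <- pos[b] + 1L; idx[pos[b]] <- a - 1L
  }
  list(ptr = as.integer(ptr), idx = as.integer(idx),
       ends = el, n = n)
}

# mean edge weight for node-weight vector nw under the half-sum combiner
.mean_edge_weight <- function(csr, nw) {
  if (nrow(csr$ends) == 0) return(0)
  mean((nw[csr$ends[, 1]] + nw[csr$ends[, 2]]) / 2)
}

#' Build the statistic-weighted network
#'
#' Attaches the signed gene-level methylation statistics to an interactome:
#' each node carries weight `|z_dnam|` (0 where the gene was not measured),
#' and each edge the mean of its endpoint node weights, so edges between two
#' strongly differentially methylated promoters weigh most. The network is
#' restricted to its largest connected component (logged via a message).
#'
#' @param interactome undirected igraph over gene symbols
#'   (see [read_interactome()])
#' @param gene_stats data.frame with `gene` and `z_dnam`
#'   (see [select_promoter_cpg()])
#' @return object of class `fem_network`: list with the igraph `graph`
#'   (vertex attributes `z`, `weight`; edge attribute `weight`), the CSR
#'   cache used by the search, and `n_dropped` nodes outside the largest
#'   component
#' @export
build_weighted_network <- function(interactome, gene_stats) {
  if (igraph::vcount(interactome) == 0) stop("empty interactome")
  stopifnot(all(c("gene", "z_dnam") %in% names(gene_stats)))
  g <- interactome
  z <- gene_stats$z_dnam[match(igraph::V(g)$name, gene_stats$gene)]
  z[is.na(z)] <- 0
  igraph::V(g)$z <- z
  igraph::V(g)$weight <- abs(z)
  comp <- igraph::components(g)
  n_dropped <- as.integer(igraph::vcount(g) - max(comp$csize))
  if (n_dropped > 0) {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
    message(sprintf(
      "restricted to largest connected component: dropped %d node(s)",
      n_dropped))
  }
  w <- igraph::V(g)$weight
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  igraph::E(g)$weight <- (w[ends[, 1]] + w[ends[, 2]]) / 2
  csr <- .graph_csr(g)
  structure(list(graph = g, csr = csr,
                 node_weight = setNames(w, igraph::V(g)$name),
                 mean_edge_weight = .mean_edge_weight(csr, w),
                 n_dropped = n_dropped),
            class = "fem_network")
}

#' @export
print.fem_network <- function(x, ...) {
  cat(sprintf(
    "fem_network: %d nodes, %d edges, mean edge weight %.4g (%d measured)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$mean_edge_weight, sum(x$node_weight > 0)))
  invisible(x)
}

.resolve_members <- function(network, members) {
  if (is.character(members)) {
    idx <- match(members, igraph::V(network$graph)$name)
    if (anyNA(idx)) stop("member gene(s) absent from network: ",
                         paste(members[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(members)
}

#' Module modularity: mean internal edge weight
#'
#' The arithmetic mean of edge weights over the edges induced by the member
#' set — the statistic whose significance the permutation test assesses.
#'
#' @param network `fem_network`
#' @param members gene names or vertex indices
#' @param node_weight optional replacement node-weight vector (used by the
#'   permutation machinery); edge weights are recomputed from it
#' @return mean internal edge weight
#' @export
module_modularity <- function(network, members, node_weight = NULL) {
  idx <- .resolve_members(network, members)
  nw <- node_weight %||% unname(network$node_weight)
  res <- module_internal_edges_cpp(network$csr$ptr, network$csr$idx,
                                   as.numeric(nw), as.integer(idx))
  if (res$n_edges == 0) stop("member set induces no edges")
  res$sum_weight / res$n_edges
}

# modularity that tolerates degenerate modules (used inside null loops)
.modularity0 <- function(network, idx, nw) {
  if (length(idx) < 2) return(0)
  res <- module_internal_edges_cpp(network$csr$ptr, network$csr$idx,
                                   as.numeric(nw), as.integer(idx))
  if (res$n_edges == 0) 0 else res$sum_weight / res$n_edges
}

#' Grow a module around a seed gene
#'
#' Seeded spin-glass search: finds a connected subgraph containing the seed
#' that (approximately) maximises
#' `sum of internal edge weights - gamma * wbar * #internal pairs`,
#' where `wbar` is the network-mean edge weight — the expected weight of a
#' random edge under the degree-preserving rewiring null. Optimised by
#' simulated annealing with restarts plus a greedy polish; deterministic
#' given `set.seed()`.
#'
#' @param network `fem_network`
#' @param seed seed gene name (or vertex index)
#' @param config `fem_config`
#' @param node_weight optional replacement node-weight vector
#' @return character vector of member genes (seed included)
#' @export
grow_module <- function(network, seed, config = fem_config(),
                        node_weight = NULL) {
  g <- network$graph
  if (is.character(seed)) {
    sidx <- match(seed, igraph::V(g)$name)
    if (is.na(sidx)) stop("seed gene absent from network: ", seed)
  } else sidx <- as.integer(seed)
  if (igraph::degree(g, sidx) == 0)
    stop("seed is isolated in the network")
  nw <- as.numeric(node_weight %||% unname(network$node_weight))
  wbar <- .mean_edge_weight(network$csr, nw)
  idx <- grow_module_cpp(network$csr$ptr, network$csr$idx, nw,
                         sidx - 1L, config$gamma * wbar,
                         config$max_module_size,
                         config$t0, config$cool, config$tmin,
                         config$moves_per_size, config$restarts,
                         max(wbar, 1e-8))
  igraph::V(g)$name[idx]
}

#' Objective value of a member set under the module-search score
#'
#' Exposed mainly for oracle testing: scores an arbitrary member set by the
#' same objective that [grow_module()] optimises.
#'
#' @inheritParams module_modularity
#' @param gamma resolution parameter
#' @return objective value
#' @export
module_objective <- function(network, members, gamma = 1.0,
                             node_weight = NULL) {
  idx <- .resolve_members(network, members)
  nw <- as.numeric(node_weight %||% unname(network$node_weight))
  wbar <- .mean_edge_weight(network$csr, nw)
  module_score_cpp(network$csr$ptr, network$csr$idx, nw,
                   as.integer(idx), gamma * wbar)
}

#' Degree-preserving rewiring null networks
#'
#' Produces randomized copies of the network by double-edge swaps
#' (`swaps_per_edge x |E|` attempted swaps each). Node degrees are preserved
#' exactly, the graph stays simple, node weights are untouched, and edge
#' weights are recomputed from the node weights.
#'
#' @param network `fem_network`
#' @param config `fem_config` (uses `B_rewire`, `swaps_per_edge`)
#' @return list of `fem_network` objects
#' @export
rewire_null <- function(network, config = fem_config()) {
  g <- network$graph
  ne <- igraph::ecount(g)
  if (ne < 2) {
    warning("fewer than 2 edges: returning the original network unrewired")
    return(replicate(max(config$B_rewire, 1), network, simplify = FALSE))
  }
  lapply(seq_len(config$B_rewire), function(b) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = config$swaps_per_edge * ne))
    w <- igraph::V(gr)$weight
    ends <- igraph::ends(gr, igraph::E(gr), names = FALSE)
    igraph::E(gr)$weight <- (w[ends[, 1]] + w[ends[, 2]]) / 2
    csr <- .graph_csr(gr)
    structure(list(graph = gr, csr = csr,
                   node_weight = setNames(w, igraph::V(gr)$name),
                   mean_edge_weight = .mean_edge_weight(csr, w),
                   n_dropped = 0L),
              class = "fem_network")
  })
}
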