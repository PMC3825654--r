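# Step 1 of the FEM analysis: EpiMod detection.

# One full detection pass for a given node-weight vector: seed selection,
# seeded growth, overlap collapse, ranking by modularity. Returns indices.
.run_detection <- function(network, nw, config) {
  ord <- order(nw, decreasing = TRUE)
  ord <- ord[nw[ord] > 0]
  seeds <- utils::head(ord, config$n_seeds)
  wbar <- .mean_edge_weight(network$csr, nw)
  lambda <- config$gamma * wbar
  mods <- list()
  for (s in seeds) {
    if (network$csr$ptr[s + 1] == network$csr$ptr[s]) next  # isolated
    idx <- grow_module_cpp(network$csr$ptr, network$csr$idx, nw,
                           s - 1L, lambda, config$max_module_size,
                           config$t0, config$cool, config$tmin,
                           config$moves_per_size, config$restarts,
                           max(wbar, 1e-8))
    if (length(idx) < config$min_module_size) next
    mods[[length(mods) + 1]] <- list(seed = s, members = sort(idx))
  }
  if (length(mods) == 0)
    return(list(seed = integer(), members = list(), modularity = numeric()))
  modularity <- vapply(mods, function(m)
    .modularity0(network, m$members, nw), numeric(1))
  keepable <- order(modularity, decreasing = TRUE)
  kept <- list(); kept_mod <- numeric(); kept_seed <- integer()
  for (i in keepable) {
    mi <- mods[[i]]$members
    overlap <- FALSE
    for (k in kept) {
      if (length(intersect(mi, k)) > 0.5 * min(length(mi), length(k))) {
        overlap <- TRUE
        break
      }
    }
    if (!overlap) {
      kept[[length(kept) + 1]] <- mi
      kept_mod <- c(kept_mod, modularity[i])
      kept_seed <- c(kept_seed, mods[[i]]$seed)
    }
  }
  list(seed = kept_seed, members = kept, modularity = kept_mod)
}

#' Permutation p-value for a single module
#'
#' Significance of a module's modularity against the statistic-permutation
#' null: node statistics are shuffled over the nodes (topology fixed), edge
#' weights recomputed, and either the seeded search re-run from the same
#' seed (`mode = "rerun"`, default) or the fixed member set re-scored
#' (`mode = "rescore"`). `p = (1 + #(null >= observed)) / (B_perm + 1)`.
#'
#' The same-seed re-run null is exchangeable — hence calibrated — when the
#' seed was *not* chosen from the observed statistics. For seeds selected as
#' the top-ranked nodes (as [detect_epimods()] does) use the pipeline-level
#' null built into [detect_epimods()] instead.
#'
#' @param network `fem_network`
#' @param seed seed gene of the observed module
#' @param observed_modularity modularity of the observed (already grown)
#'   module
#' @param config `fem_config` (uses `B_perm` and the search parameters)
#' @param mode `"rerun"` or `"rescore"`
#' @param members member genes, required for `mode = "rescore"`
#' @return list: `p_perm`, `n_perm`, `null_modularity`
#' @export
permutation_pvalue <- function(network, seed, observed_modularity,
                               config = fem_config(),
                               mode = c("rerun", "rescore"),
                               members = NULL) {
  mode <- match.arg(mode)
  if (mode == "rescore" && is.null(members))
    stop("members must be given for mode = 'rescore'")
  g <- network$graph
  sidx <- if (is.character(seed)) match(seed, igraph::V(g)$name)
          else as.integer(seed)
  if (is.na(sidx)) stop("seed gene absent from network: ", seed)
  nw0 <- unname(network$node_weight)
  midx <- if (!is.null(members)) .resolve_members(network, members) else NULL
  nullmod <- numeric(config$B_perm)
  for (b in seq_len(config$B_perm)) {
    nw <- sample(nw0)
    if (mode == "rerun") {
      wbar <- .mean_edge_weight(network$csr, nw)
      idx <- grow_module_cpp(network$csr$ptr, network$csr$idx, nw,
                             sidx - 1L, config$gamma * wbar,
                             config$max_module_size,
                             config$t0, config$cool, config$tmin,
                             config$moves_per_size, config$restarts,
                             max(wbar, 1e-8))
      nullmod[b] <- .modularity0(network, idx, nw)
    } else {
      nullmod[b] <- .modularity0(network, midx, nw)
    }
  }
  p <- (1 + sum(nullmod >= observed_modularity)) / (config$B_perm + 1)
  list(p_perm = p, n_perm = config$B_perm, null_modularity = nullmod)
}

#' Detect differential methylation hotspots (EpiMods)
#'
#' Step 1 of the FEM analysis. Seeds are the `n_seeds` genes with the
#' largest statistic magnitude; one module is grown per seed by the seeded
#' spin-glass search; modules sharing more than half of the smaller module's
#' members are collapsed (the higher-modularity one kept); surviving modules
#' are ranked by modularity (mean internal edge weight, descending).
#'
#' Significance uses a pipeline-level statistic-permutation null: for each
#' of `B_perm` permutations of the node statistics over the network, the
#' *entire* detection (seed re-selection, growth, collapse, ranking) is
#' re-run, and the observed rank-r modularity is compared with the null
#' rank-r modularities. This keeps the null subject to the same selection
#' steps as the observed analysis, so p-values are calibrated. Modules with
#' `p_perm < alpha` are classified EpiMods.
#'
#' A degree-preserving rewiring diagnostic (observed minus mean rewired
#' modularity, regrowing from the same seed on each rewired network) is
#' reported per module when `config$B_rewire > 0`.
#'
#' @param network `fem_network` from [build_weighted_network()]
#' @param config `fem_config`
#' @param rewire_diagnostic compute the rewiring modularity gap
#' @return object of class `epimod_result`: list with `summary` data.frame
#'   (`seed`, `size`, `modularity`, `p_perm`, `n_perm`, `classification`,
#'   `rewire_gap`), `modules` (named list of member gene vectors),
#'   `sign_profile` (per-member sign of z), and `config`
#' @export
detect_epimods <- function(network, config = fem_config(),
                           rewire_diagnostic = TRUE) {
  g <- network$graph
  nw0 <- unname(network$node_weight)
  obs <- .run_detection(network, nw0, config)
  nmod <- length(obs$members)
  if (nmod == 0) {
    return(structure(list(
      summary = data.frame(seed = character(), size = integer(),
                           modularity = numeric(), p_perm = numeric(),
                           n_perm = integer(), classification = character(),
                           rewire_gap = numeric(), stringsAsFactors = FALSE),
      modules = list(), sign_profile = list(), config = config),
      class = "epimod_result"))
  }
  # pipeline-level permutation null, rank-matched; an absent rank counts 0
  null_rank <- matrix(0, nrow = config$B_perm, ncol = nmod)
  for (b in seq_len(config$B_perm)) {
    det <- .run_detection(network, sample(nw0), config)
    k <- min(length(det$modularity), nmod)
    if (k > 0) null_rank[b, seq_len(k)] <- det$modularity[seq_len(k)]
  }
  p_perm <- vapply(seq_len(nmod), function(r)
    (1 + sum(null_rank[, r] >= obs$modularity[r])) / (config$B_perm + 1),
    numeric(1))

  rewire_gap <- rep(NA_real_, nmod)
  if (rewire_diagnostic && config$B_rewire > 0) {
    nulls <- rewire_null(network, config)
    for (r in seq_len(nmod)) {
      rw <- vapply(nulls, function(netr) {
        idx <- grow_module_cpp(netr$csr$ptr, netr$csr$idx, nw0,
                               obs$seed[r] - 1L,
                               config$gamma * netr$mean_edge_weight,
                               config$max_module_size,
                               config$t0, config$cool, config$tmin,
                               config$moves_per_size, config$restarts,
                               max(netr$mean_edge_weight, 1e-8))
        .modularity0(netr, idx, nw0)
      }, numeric(1))
      rewire_gap[r] <- obs$modularity[r] - mean(rw)
    }
  }

  nm <- igraph::V(g)$name
  zs <- igraph::V(g)$z
  modules <- lapply(obs$members, function(ix) nm[ix])
  names(modules) <- nm[obs$seed]
  sign_profile <- lapply(obs$members, function(ix)
    setNames(sign(zs[ix]), nm[ix]))
  names(sign_profile) <- nm[obs$seed]
  structure(list(
    summary = data.frame(
      seed = nm[obs$seed],
      size = vapply(obs$members, length, integer(1)),
      modularity = obs$modularity,
      p_perm = p_perm,
      n_perm = config$B_perm,
      classification = ifelse(p_perm < config$alpha, "EpiMod",
                              "not-significant"),
      rewire_gap = rewire_gap,
      stringsAsFactors = FALSE),
    modules = modules, sign_profile = sign_profile, config = config),
    class = "epimod_result")
}

#' @export
print.epimod_result <- function(x, ...) {
  cat(sprintf("epimod_result: %d module(s), %d EpiMod(s) at alpha = %g\n",
              nrow(x$summary),
              sum(x$summary$classification == "EpiMod"),
              x$config$alpha))
  if (nrow(x$summary) > 0)
    print(utils::head(x$summary, 10), row.names = FALSE)
  invisible(x)
}

#' Export one module as GraphML
#'
#' Writes the induced subgraph with node attributes `z`, `weight` and
#' `member` (all 1 here) and the edge weights, for viewing in e.g. Cytoscape.
#'
#' @param network `fem_network`
#' @param members member gene names
#' @param path output file
#' @export
export_module_graphml <- function(network, members, path) {
  idx <- .resolve_members(network, members)
  sub <- igraph::induced_subgraph(network$graph, idx)
  igraph::V(sub)$member <- 1L
  igraph::write_graph(sub, path, format = "graphml")
  invisible(path)
}
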