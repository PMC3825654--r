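# Step 2 of the FEM analysis: integration with differential expression.

#' Per-gene differential expression statistics
#'
#' Two-sided Wilcoxon rank-sum test per gene (cases vs controls), with
#' `delta_expr` = median difference (case - control) and
#' `z_expr = sign(delta_expr) * qnorm(1 - p/2)`. The expression cohort may
#' be entirely different from the methylation cohort: integration downstream
#' happens at the statistic level, never at the sample level.
#'
#' @param expr expression matrix (gene rows, sample columns)
#' @param samples sample sheet with `sample_id`, `phenotype` for the
#'   expression cohort
#' @param method `"wilcoxon"` (default, robust) or `"welch"` t-test
#' @return data.frame: `gene`, `delta_expr`, `p_expr`, `z_expr`
#' @export
expression_stats <- function(expr, samples,
                             method = c("wilcoxon", "welch")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (anyDuplicated(rownames(expr))) stop("duplicate gene symbols")
  ph <- align_phenotype(samples, colnames(expr))
  case <- ph == 1
  if (sum(case) < 2 || sum(!case) < 2)
    stop("need at least 2 samples per class")
  n <- nrow(expr)
  p <- delta <- numeric(n)
  for (i in seq_len(n)) {
    x1 <- expr[i, case]; x0 <- expr[i, !case]
    ok1 <- !is.na(x1); ok0 <- !is.na(x0)
    if (sum(ok1) < 2 || sum(ok0) < 2) { p[i] <- NA; delta[i] <- NA; next }
    x1 <- x1[ok1]; x0 <- x0[ok0]
    delta[i] <- stats::median(x1) - stats::median(x0)
    p[i] <- if (stats::var(c(x1, x0)) == 0) 1 else if (method == "wilcoxon")
      suppressWarnings(stats::wilcox.test(x1, x0)$p.value)
    else stats::t.test(x1, x0)$p.value
  }
  p <- ifelse(is.na(p), NA, .floor_p(p))
  z <- rep(NA_real_, n)
  ok <- !is.na(p)
  z[ok] <- signed_zstat(p[ok], delta[ok])
  data.frame(gene = rownames(expr), delta_expr = delta, p_expr = p,
             z_expr = z, stringsAsFactors = FALSE)
}

#' Integrated methylation-expression node weight
#'
#' Combines a gene's methylation and expression statistics into a single
#' non-negative node weight: the average of the two magnitudes when the
#' signs are discordant (hypermethylation with under-expression, or the
#' reverse — the expected anti-correlation between promoter methylation and
#' transcription), and 0 otherwise. A missing expression statistic gives 0.
#'
#' @param z_dnam signed methylation statistic(s)
#' @param z_expr signed expression statistic(s)
#' @return non-negative weight(s)
#' @examples
#' integrated_node_weight(3, -2)  # 2.5: anti-correlated
#' integrated_node_weight(3, 2)   # 0: concordant, wrong direction
#' @export
integrated_node_weight <- function(z_dnam, z_expr) {
  n <- max(length(z_dnam), length(z_expr))
  z_dnam <- rep_len(z_dnam, n); z_expr <- rep_len(z_expr, n)
  w <- ifelse(!is.na(z_dnam) & !is.na(z_expr) &
                sign(z_dnam) * sign(z_expr) < 0,
              (abs(z_dnam) + abs(z_expr)) / 2, 0)
  as.numeric(w)
}

#' Detect functional epigenetic modules (FEMs)
#'
#' Runs (or reuses) step-1 EpiMod detection, then rebuilds the network with
#' the integrated methylation-expression node weights and re-runs the seeded
#' search from each EpiMod seed. An EpiMod is classified FEM when its
#' integrated module remains significant against a permutation null.
#'
#' The default null (`perm_mode = "expression"`) permutes the expression
#' statistics over the measured genes while keeping the methylation layer
#' fixed, then recomputes the integrated weights and re-grows the module.
#' This tests precisely the functional question: is the anti-correlated
#' expression concordance inside this methylation hotspot stronger than
#' chance? A hotspot whose genes show no coherent expression change — the
#' situation the FEM filter exists to catch — is therefore not significant
#' here, however strong its methylation signal.
#' `perm_mode = "tuple"` instead permutes the paired `(z_dnam, z_expr)`
#' tuples over the nodes (preserving the within-gene coupling).
#'
#' @param interactome undirected igraph over gene symbols
#' @param gene_stats gene-level methylation statistics
#'   (see [select_promoter_cpg()])
#' @param expr_stats gene-level expression statistics
#'   (see [expression_stats()])
#' @param config `fem_config`
#' @param perm_mode `"expression"` (default) or `"tuple"`
#' @param epimods optional precomputed [detect_epimods()] result on the same
#'   interactome/statistics
#' @return object of class `fem_result`: the `epimod_result` summary
#'   extended with `integrated_modularity`, `integrated_size`, `p_perm_fem`
#'   and `fem_flag`; plus `modules_integrated`
#' @export
detect_fem_modules <- function(interactome, gene_stats, expr_stats,
                               config = fem_config(),
                               perm_mode = c("expression", "tuple"),
                               epimods = NULL) {
  perm_mode <- match.arg(perm_mode)
  stopifnot(all(c("gene", "z_expr") %in% names(expr_stats)))
  network <- build_weighted_network(interactome, gene_stats)
  g <- network$graph
  genes <- igraph::V(g)$name
  if (!any(expr_stats$gene %in% genes))
    stop("expression statistics share no genes with the network")
  if (is.null(epimods))
    epimods <- detect_epimods(network, config)
  smry <- epimods$summary

  zd <- igraph::V(g)$z
  ze <- expr_stats$z_expr[match(genes, expr_stats$gene)]
  measured <- which(!is.na(ze))
  w_int <- integrated_node_weight(zd, ze)

  grow_int <- function(seed_idx, nw) {
    wbar <- .mean_edge_weight(network$csr, nw)
    idx <- grow_module_cpp(network$csr$ptr, network$csr$idx, nw,
                           seed_idx - 1L, config$gamma * wbar,
                           config$max_module_size,
                           config$t0, config$cool, config$tmin,
                           config$moves_per_size, config$restarts,
                           max(wbar, 1e-8))
    idx
  }

  nmod <- nrow(smry)
  int_mod <- rep(NA_real_, nmod)
  int_size <- rep(NA_integer_, nmod)
  p_fem <- rep(NA_real_, nmod)
  modules_int <- vector("list", nmod)
  for (r in seq_len(nmod)) {
    if (smry$classification[r] != "EpiMod") next
    sidx <- match(smry$seed[r], genes)
    idx <- grow_int(sidx, w_int)
    obs <- .modularity0(network, idx, w_int)
    int_mod[r] <- obs
    int_size[r] <- length(idx)
    modules_int[[r]] <- genes[idx]
    nullmod <- numeric(config$B_perm)
    for (b in seq_len(config$B_perm)) {
      if (perm_mode == "expression") {
        zeb <- ze
        zeb[measured] <- ze[sample(measured)]
        nwb <- integrated_node_weight(zd, zeb)
      } else {
        perm <- sample(length(genes))
        nwb <- integrated_node_weight(zd[perm], ze[perm])
      }
      idxb <- grow_int(sidx, nwb)
      nullmod[b] <- .modularity0(network, idxb, nwb)
    }
    p_fem[r] <- (1 + sum(nullmod >= obs)) / (config$B_perm + 1)
  }
  smry$integrated_modularity <- int_mod
  smry$integrated_size <- int_size
  smry$p_perm_fem <- p_fem
  smry$fem_flag <- !is.na(p_fem) & p_fem < config$alpha
  smry$classification[smry$fem_flag] <- "FEM"
  names(modules_int) <- smry$seed
  structure(list(summary = smry, modules = epimods$modules,
                 modules_integrated = modules_int,
                 sign_profile = epimods$sign_profile,
                 config = config, perm_mode = perm_mode,
                 network = network),
            class = "fem_result")
}

#' @export
print.fem_result <- function(x, ...) {
  cat(sprintf("fem_result: %d module(s), %d EpiMod(s), %d FEM(s)\n",
              nrow(x$summary),
              sum(x$summary$classification %in% c("EpiMod", "FEM")),
              sum(x$summary$fem_flag)))
  if (nrow(x$summary) > 0)
    print(utils::head(x$summary, 10), row.names = FALSE)
  invisible(x)
}
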