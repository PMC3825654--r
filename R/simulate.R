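# Synthetic methylome + interactome + transcriptome triples with a planted
# hotspot and full ground truth, so every stage of the analysis is testable
# without any external download.

#' Ground truth for a synthetic FEM benchmark
#'
#' @param genes all gene symbols of the simulated interactome
#' @param planted_genes genes forming the planted hotspot (must induce a
#'   connected subgraph of the generated interactome)
#' @param delta_beta planted case-control beta shift at planted promoter
#'   CpGs, in (0, 1)
#' @param delta_expr planted under-expression of planted genes in cases
#'   (log-scale units; anti-correlated with the hypermethylation)
#' @param n_cases,n_controls methylation cohort sizes
#' @param n_expr_cases,n_expr_controls expression cohort sizes (a disjoint
#'   cohort, mirroring the two-data-set design the analysis assumes)
#' @return list of class `synthetic_truth`
#' @export
synthetic_truth <- function(genes, planted_genes, delta_beta = 0.3,
                            delta_expr = 1.5, n_cases = 50, n_controls = 50,
                            n_expr_cases = 40, n_expr_controls = 40) {
  stopifnot(delta_beta >= 0, delta_beta < 1,
            all(planted_genes %in% genes))
  structure(list(genes = genes, planted_genes = planted_genes,
                 delta_beta = delta_beta, delta_expr = delta_expr,
                 n_cases = n_cases, n_controls = n_controls,
                 n_expr_cases = n_expr_cases,
                 n_expr_controls = n_expr_controls),
            class = "synthetic_truth")
}

# preferential attachment starting from 2 unlinked founder nodes, so the
# edge count is exactly m * (n - 2); degree+1 weighting bootstraps the start
.sample_pa_graph <- function(n, m = 2) {
  stopifnot(n >= 3)
  edges <- vector("list", n - 2)
  deg <- numeric(n)
  for (v in 3:n) {
    k <- min(m, v - 1)
    tgt <- sample.int(v - 1, size = k, prob = deg[seq_len(v - 1)] + 1)
    edges[[v - 2]] <- rbind(v, tgt)
    deg[tgt] <- deg[tgt] + 1
    deg[v] <- deg[v] + k
  }
  el <- t(do.call(cbind, edges))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Simulate an interactome with an embedded connected module
#'
#' Generates a connected simple graph over gene symbols `G0001...` and
#' embeds a planted module: a random spanning tree over the planted genes
#' plus extra internal edges up to a target internal density, guaranteeing
#' the planted genes induce a connected subgraph.
#'
#' @param n_nodes number of genes
#' @param topology `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"`
#' @param planted_size number of planted genes (0 plants nothing)
#' @param m edges per new node for the scale-free generator
#' @param p_er edge probability for the Erdos-Renyi generator (default
#'   targets mean degree 4)
#' @param internal_density target edge density inside the planted module
#' @return igraph with graph attribute `planted` (character vector)
#' @export
simulate_interactome <- function(n_nodes,
                                 topology = c("scale_free", "erdos_renyi"),
                                 planted_size = 0, m = 2,
                                 p_er = NULL, internal_density = 0.5) {
  topology <- match.arg(topology)
  if (planted_size > n_nodes)
    stop("planted module larger than the network")
  g <- if (topology == "scale_free") {
    .sample_pa_graph(n_nodes, m = m)
  } else {
    p_er <- p_er %||% min(1, 4 / (n_nodes - 1))
    gg <- igraph::sample_gnp(n_nodes, p_er)
    # stitch components together so the graph is connected
    comp <- igraph::components(gg)
    while (comp$no > 1) {
      pick <- vapply(seq_len(comp$no), function(k)
        sample(which(comp$membership == k), 1), integer(1))
      gg <- igraph::add_edges(gg, rbind(pick[-length(pick)], pick[-1]))
      comp <- igraph::components(gg)
    }
    gg
  }
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  planted <- character(0)
  if (planted_size > 0) {
    pidx <- sample.int(n_nodes, planted_size)
    planted <- igraph::V(g)$name[pidx]
    newe <- NULL
    if (planted_size > 1) {
      perm <- sample(pidx)
      tree <- vapply(2:planted_size, function(i)
        c(perm[i], perm[sample.int(i - 1, 1)]), numeric(2))
      newe <- t(tree)
      target <- ceiling(internal_density * choose(planted_size, 2))
      pairs <- t(utils::combn(pidx, 2))
      extra <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
      need <- max(0, target - (planted_size - 1))
      newe <- rbind(newe, utils::head(extra, need))
    }
    if (!is.null(newe))
      g <- igraph::add_edges(g, t(newe))
    g <- igraph::simplify(g)
  }
  g <- igraph::set_graph_attr(g, "planted", planted)
  g
}

#' Simulate a two-group beta-value matrix with a planted promoter shift
#'
#' Per CpG, a baseline mean `mu ~ Uniform(0.1, 0.9)` and beta values drawn
#' from a Beta distribution with mean `mu` and precision (a+b) `precision`
#' — values stay in \[0,1\] with the heteroscedastic, boundary-compressed
#' dispersion typical of array beta values. For the promoter CpG (smallest
#' `|tss_distance|`) of each planted gene the case-group mean is shifted to
#' `clip(mu + delta_beta, 0.01, 0.99)`. Each gene gets `cpgs_per_gene` CpGs
#' with distinct signed TSS distances.
#'
#' @param truth `synthetic_truth`
#' @param cpgs_per_gene CpGs per gene
#' @param precision Beta-distribution precision (a+b)
#' @return list: `beta` matrix, `samples` sheet, `annotation` table
#' @export
simulate_beta <- function(truth, cpgs_per_gene = 2, precision = 50) {
  genes <- truth$genes
  ng <- length(genes)
  ns <- truth$n_cases + truth$n_controls
  pheno <- c(rep(0L, truth$n_controls), rep(1L, truth$n_cases))
  sample_ids <- sprintf("S%03d", seq_len(ns))
  ncpg <- ng * cpgs_per_gene
  cpg_ids <- sprintf("cg%07d", seq_len(ncpg))
  gene_of <- rep(genes, each = cpgs_per_gene)
  # distinct signed TSS distances per gene, 60..1500 bp either side
  tss <- as.vector(vapply(seq_len(ng), function(i) {
    d <- sample(60:1500, cpgs_per_gene)
    s <- sample(c(-1, 1), cpgs_per_gene, replace = TRUE)
    d * s
  }, numeric(cpgs_per_gene)))
  annotation <- data.frame(
    cpg_id = cpg_ids, gene = gene_of, tss_distance = tss,
    chromosome = "chr1", position = seq_len(ncpg) * 1000L,
    stringsAsFactors = FALSE)
  # promoter CpG per gene = smallest |tss_distance|
  promoter <- unlist(lapply(split(seq_len(ncpg), gene_of), function(ix)
    ix[which.min(abs(tss[ix]))]), use.names = FALSE)
  is_planted_prom <- logical(ncpg)
  is_planted_prom[promoter[gene_of[promoter] %in% truth$planted_genes]] <- TRUE

  mu <- stats::runif(ncpg, 0.1, 0.9)
  beta <- matrix(NA_real_, ncpg, ns, dimnames = list(cpg_ids, sample_ids))
  for (i in seq_len(ncpg)) {
    mui <- rep(mu[i], ns)
    if (is_planted_prom[i])
      mui[pheno == 1] <- pmin(pmax(mu[i] + truth$delta_beta, 0.01), 0.99)
    beta[i, ] <- stats::rbeta(ns, mui * precision, (1 - mui) * precision)
  }
  samples <- data.frame(sample_id = sample_ids, phenotype = pheno,
                        stringsAsFactors = FALSE)
  list(beta = beta, samples = samples, annotation = annotation)
}

#' Simulate a gene expression matrix with planted under-expression
#'
#' Gaussian log-scale expression, background `N(8, 1)`; planted genes are
#' shifted down by `delta_expr` in cases (anti-correlated with the planted
#' promoter hypermethylation). The cohort is independent of the methylation
#' cohort.
#'
#' @param truth `synthetic_truth`
#' @return list: `expr` matrix, `samples` sheet
#' @export
simulate_expression <- function(truth) {
  genes <- truth$genes
  ns <- truth$n_expr_cases + truth$n_expr_controls
  pheno <- c(rep(0L, truth$n_expr_controls), rep(1L, truth$n_expr_cases))
  sample_ids <- sprintf("E%03d", seq_len(ns))
  expr <- matrix(stats::rnorm(length(genes) * ns, mean = 8, sd = 1),
                 nrow = length(genes),
                 dimnames = list(genes, sample_ids))
  planted <- genes %in% truth$planted_genes
  expr[planted, pheno == 1] <- expr[planted, pheno == 1] - truth$delta_expr
  list(expr = expr,
       samples = data.frame(sample_id = sample_ids, phenotype = pheno,
                            stringsAsFactors = FALSE))
}

#' Simulate a complete benchmark data set with planted ground truth
#'
#' Convenience wrapper generating interactome, beta matrix (+ sample sheet
#' and CpG annotation) and expression matrix (+ its own, disjoint cohort)
#' with one planted hotspot.
#'
#' @param n_nodes interactome size
#' @param planted_size planted hotspot size
#' @param topology interactome topology
#' @param delta_beta,delta_expr planted effect sizes
#' @param n_cases,n_controls,n_expr_cases,n_expr_controls cohort sizes
#' @param cpgs_per_gene CpGs per gene
#' @param internal_density planted module internal edge density
#' @return list: `interactome`, `beta`, `beta_samples`, `annotation`,
#'   `expr`, `expr_samples`, `truth`
#' @export
simulate_fem_dataset <- function(n_nodes = 500, planted_size = 10,
                                 topology = "scale_free",
                                 delta_beta = 0.3, delta_expr = 1.5,
                                 n_cases = 50, n_controls = 50,
                                 n_expr_cases = 40, n_expr_controls = 40,
                                 cpgs_per_gene = 2,
                                 internal_density = 0.5) {
  g <- simulate_interactome(n_nodes, topology, planted_size = planted_size,
                            internal_density = internal_density)
  truth <- synthetic_truth(genes = igraph::V(g)$name,
                           planted_genes = igraph::graph_attr(g, "planted"),
                           delta_beta = delta_beta, delta_expr = delta_expr,
                           n_cases = n_cases, n_controls = n_controls,
                           n_expr_cases = n_expr_cases,
                           n_expr_controls = n_expr_controls)
  meth <- simulate_beta(truth, cpgs_per_gene = cpgs_per_gene)
  ex <- simulate_expression(truth)
  list(interactome = g, beta = meth$beta, beta_samples = meth$samples,
       annotation = meth$annotation, expr = ex$expr,
       expr_samples = ex$samples, truth = truth)
}

#' Score recovery of the planted module
#'
#' Precision, recall and F1 of reported modules against the planted genes,
#' taking the best-matching (highest-F1) module. An empty report scores 0.
#'
#' @param modules list of character vectors (or an `epimod_result` /
#'   `fem_result`, whose modules are used)
#' @param truth `synthetic_truth`
#' @return list: `precision`, `recall`, `f1`, `best_module`
#' @export
score_recovery <- function(modules, truth) {
  if (inherits(modules, "epimod_result") || inherits(modules, "fem_result"))
    modules <- modules$modules
  planted <- truth$planted_genes
  if (length(modules) == 0)
    return(list(precision = 0, recall = 0, f1 = 0, best_module = character()))
  score1 <- function(m) {
    tp <- length(intersect(m, planted))
    prec <- if (length(m) > 0) tp / length(m) else 0
    rec <- if (length(planted) > 0) tp / length(planted) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  sc <- vapply(modules, score1, numeric(3))
  best <- which.max(sc[3, ])
  list(precision = unname(sc[1, best]), recall = unname(sc[2, best]),
       f1 = unname(sc[3, best]), best_module = modules[[best]])
}
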