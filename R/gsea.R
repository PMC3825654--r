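#' Fisher exact enrichment of a gene list in a gene set
#'
#' One-tailed (enrichment direction) Fisher exact test of the overlap
#' between a gene list and a gene set within a universe. Inputs are
#' deduplicated and the gene set is intersected with the universe first, so
#' multiple CpGs mapping to the same gene cannot be overcounted. The odds
#' ratio is `a*d / (b*c)` on the 2x2 table (overlap, list-only, set-only,
#' neither), with `Inf` when `b*c = 0` and `a*d > 0`, and 0 when the
#' overlap is empty. The 95% CI uses the Woolf log-OR normal approximation
#' with a Haldane 0.5 correction when any cell is zero.
#'
#' @param gene_list character vector of genes of interest (subset of
#'   universe)
#' @param gene_set character vector defining the biological term
#' @param universe all genes eligible for the list (e.g. every gene with a
#'   computed statistic)
#' @return one-row data.frame: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `or_ci_lo`, `or_ci_hi`, `p_one_tailed`, `degenerate`
#' @export
fisher_enrichment <- function(gene_list, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  gene_list <- unique(gene_list)
  if (length(gene_list) == 0) stop("empty gene list")
  if (!all(gene_list %in% universe))
    stop("gene_list must be a subset of the universe")
  gene_set <- intersect(unique(gene_set), universe)
  a <- length(intersect(gene_list, gene_set))
  b <- length(gene_list) - a
  cc <- length(gene_set) - a
  d <- length(universe) - a - b - cc
  degenerate <- (b + d) == 0 || (cc + d) == 0 || length(gene_set) == 0
  p <- if (a == 0) 1 else
    stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                       alternative = "greater")$p.value
  or <- if (a == 0) 0 else if (b * cc == 0) Inf else (a * d) / (b * cc)
  # Woolf CI on log OR, Haldane-corrected when any cell is zero
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  data.frame(a = a, b = b, c = cc, d = d, odds_ratio = or,
             or_ci_lo = exp(lor - 1.96 * se),
             or_ci_hi = exp(lor + 1.96 * se),
             p_one_tailed = p, degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (monotone, capped at 1), via [stats::p.adjust()].
#'
#' @param p p-values in (0, 1]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation of hyper- and hypomethylated genes
#'
#' Runs [fisher_enrichment()] of the hypermethylated and hypomethylated gene
#' lists (independently) against every set of a collection, BH-adjusts each
#' table within itself, and ranks by p.
#'
#' @param hyper_genes genes hypermethylated in cases
#' @param hypo_genes genes hypomethylated in cases
#' @param collections named list of gene sets (see [read_gmt()])
#' @param universe all genes with a computed gene-level statistic
#' @return list of data.frames `hyper` and `hypo` with one row per set:
#'   `set`, counts, `odds_ratio`, CI, `p_one_tailed`, `p_bh`
#' @export
run_gsea <- function(hyper_genes, hypo_genes, collections, universe) {
  one <- function(gl) {
    gl <- intersect(unique(gl), universe)
    if (length(gl) == 0 || length(collections) == 0) {
      return(data.frame(set = character(), a = integer(), b = integer(),
                        c = integer(), d = integer(), odds_ratio = numeric(),
                        or_ci_lo = numeric(), or_ci_hi = numeric(),
                        p_one_tailed = numeric(), p_bh = numeric(),
                        stringsAsFactors = FALSE))
    }
    rows <- lapply(names(collections), function(nm) {
      r <- fisher_enrichment(gl, collections[[nm]], universe)
      cbind(data.frame(set = nm, stringsAsFactors = FALSE),
            r[, c("a", "b", "c", "d", "odds_ratio", "or_ci_lo", "or_ci_hi",
                  "p_one_tailed")])
    })
    tab <- do.call(rbind, rows)
    tab$p_bh <- bh_adjust(tab$p_one_tailed)
    tab <- tab[order(tab$p_one_tailed, tab$set), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  list(hyper = one(hyper_genes), hypo = one(hypo_genes))
}
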