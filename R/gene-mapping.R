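#' Collapse CpG statistics to one statistic per gene (closest-to-TSS rule)
#'
#' For each gene, among its annotated CpGs that have a computed statistic,
#' the CpG closest to the transcription start site (smallest
#' `|tss_distance|`) is chosen and its signed statistic becomes the gene's
#' methylation statistic. Ties in `|tss_distance|` prefer the upstream
#' (negative-distance) CpG; any remaining tie is broken lexicographically by
#' CpG id, so the mapping is deterministic. Genes with no annotated,
#' measured CpG are omitted (not an error).
#'
#' @param annotation CpG annotation data.frame (see [read_cpg_annotation()])
#' @param stats per-CpG statistics from [dmc_stats()] (rows with `NA` z are
#'   ignored)
#' @return data.frame: `gene`, `chosen_cpg`, `tss_distance`, `z_dnam`,
#'   plus `delta`, `p`, `q` carried over from the chosen CpG
#' @export
select_promoter_cpg <- function(annotation, stats) {
  stopifnot(all(c("cpg_id", "gene", "tss_distance") %in% names(annotation)),
            all(c("cpg_id", "z") %in% names(stats)))
  st <- stats[!is.na(stats$z),
              intersect(c("cpg_id", "delta", "p", "q", "z"), names(stats)),
              drop = FALSE]
  mg <- merge(annotation[, c("cpg_id", "gene", "tss_distance")], st,
              by = "cpg_id")
  if (nrow(mg) == 0) {
    return(data.frame(gene = character(), chosen_cpg = character(),
                      tss_distance = numeric(), z_dnam = numeric(),
                      delta = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(mg$gene, abs(mg$tss_distance), mg$tss_distance >= 0, mg$cpg_id)
  mg <- mg[ord, , drop = FALSE]
  sel <- mg[!duplicated(mg$gene), , drop = FALSE]
  out <- data.frame(gene = sel$gene, chosen_cpg = sel$cpg_id,
                    tss_distance = sel$tss_distance, z_dnam = sel$z,
                    stringsAsFactors = FALSE)
  for (cn in c("delta", "p", "q"))
    out[[cn]] <- if (cn %in% names(sel)) sel[[cn]] else NA_real_
  rownames(out) <- NULL
  out
}
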