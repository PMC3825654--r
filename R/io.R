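#' Read a beta-value methylation matrix
#'
#' Reads a CpG-by-sample matrix of methylation beta values (fractions in
#' \[0,1\]) from a delimited text file. The first column holds CpG
#' identifiers, the header row holds sample identifiers. The tokens `NA`,
#' `NaN` and the empty cell are treated as missing.
#'
#' @param path file path
#' @param sep field separator (default tab)
#' @param tol numeric slack allowed outside \[0,1\] before a value is
#'   rejected; values within `tol` of the boundary are clamped
#' @return numeric matrix with CpG rownames and sample colnames
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path, sep = "\t", tol = 1e-9) {
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty beta matrix: need at least one CpG row and one sample column")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  numok <- vapply(vals, is.numeric, logical(1))
  if (!all(numok))
    stop("non-numeric beta values in column(s): ",
         paste(names(vals)[!numok], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_beta_matrix(m, tol = tol)
}

#' Validate a beta-value matrix
#'
#' Checks unique CpG and sample identifiers and that all non-missing values
#' lie in \[0,1\] (within `tol`, clamping tiny excursions).
#'
#' @param m numeric matrix, CpGs in rows
#' @param tol slack outside \[0,1\]
#' @return the validated (possibly clamped) matrix
#' @export
validate_beta_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m)) stop("beta matrix must be numeric")
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty beta matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("CpG identifiers must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("sample identifiers must be present and unique")
  bad <- !is.na(m) & (m < -tol | m > 1 + tol)
  if (any(bad))
    stop(sprintf("%d beta value(s) outside [0,1], e.g. %g",
                 sum(bad), m[which(bad)[1]]))
  m[!is.na(m) & m < 0] <- 0
  m[!is.na(m) & m > 1] <- 1
  m
}

#' Write a beta-value matrix
#'
#' @param m beta matrix as returned by [read_beta_matrix()]
#' @param path output file
#' @param sep field separator
#' @export
write_beta_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(cpg_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet with a binary phenotype
#'
#' Expects columns `sample_id` and `phenotype`, phenotype coded 0 (control /
#' normal) and 1 (case).
#'
#' @param path file path
#' @param sep field separator
#' @return data.frame with character `sample_id` and integer `phenotype`
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  ph <- df$phenotype
  if (!all(ph %in% c(0, 1))) stop("phenotype must be coded 0/1")
  df$phenotype <- as.integer(ph)
  df[, need]
}

#' Check a sample sheet against a data matrix
#'
#' Verifies that every matrix sample appears exactly once in the sheet and,
#' for supervised analyses, that both phenotype classes are non-empty.
#'
#' @param sheet sample sheet data.frame
#' @param sample_ids sample identifiers of the paired matrix
#' @return integer phenotype vector aligned to `sample_ids`
#' @export
align_phenotype <- function(sheet, sample_ids) {
  idx <- match(sample_ids, sheet$sample_id)
  if (anyNA(idx))
    stop("samples missing from sample sheet: ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
  ph <- sheet$phenotype[idx]
  if (length(unique(ph)) < 2)
    stop("both phenotype classes must be non-empty")
  ph
}

#' Read a CpG annotation table
#'
#' Expects columns `cpg_id`, `gene`, `tss_distance` (signed base pairs,
#' positive = downstream of the TSS), `chromosome`, `position` (1-based).
#'
#' @param path file path
#' @param sep field separator
#' @param uppercase_genes upper-case gene symbols on load
#' @return data.frame
#' @export
read_cpg_annotation <- function(path, sep = "\t", uppercase_genes = FALSE) {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cpg_id", "gene", "tss_distance", "chromosome", "position")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  df$cpg_id <- as.character(df$cpg_id)
  df$gene <- as.character(df$gene)
  if (uppercase_genes) df$gene <- toupper(df$gene)
  if (anyDuplicated(df$cpg_id)) stop("duplicate cpg_id in annotation")
  if (!is.numeric(df$tss_distance) || any(!is.finite(df$tss_distance)))
    stop("tss_distance must be finite numeric")
  df$tss_distance <- as.numeric(df$tss_distance)
  df[, need]
}

#' Read an undirected interactome
#'
#' Reads a protein-interaction network over gene symbols from a two-column
#' edge-list TSV or a GraphML file. Self-loops are dropped with a warning and
#' duplicate edges are collapsed; the node set is the union of all endpoint
#' symbols.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"edgelist"` or `"graphml"`
#' @param uppercase_genes upper-case gene symbols on load (interactomes and
#'   annotations often disagree on case)
#' @return an undirected simple [igraph::igraph] object
#' @export
read_interactome <- function(path, format = c("auto", "edgelist", "graphml"),
                             uppercase_genes = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE))
      "graphml" else "edgelist"
  }
  if (format == "edgelist") {
    if (file.size(path) == 0) stop("empty interactome file")
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (nrow(df) == 0) stop("empty interactome file")
    if (ncol(df) < 2) stop("malformed edge list: need two columns")
    a <- trimws(df[[1]]); b <- trimws(df[[2]])
    if (any(a == "" | b == "" | is.na(a) | is.na(b)))
      stop("malformed edge list line(s): empty endpoint")
    if (uppercase_genes) { a <- toupper(a); b <- toupper(b) }
    g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    if (uppercase_genes) igraph::V(g)$name <- toupper(igraph::V(g)$name)
  }
  n_loop <- sum(igraph::which_loop(g))
  if (n_loop > 0)
    warning(sprintf("dropped %d self-loop(s) from interactome", n_loop))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an interactome as a two-column edge list
#'
#' @param graph igraph object
#' @param path output file
#' @export
write_interactome <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Duplicate members within a set are collapsed; duplicate set names are an
#' error.
#'
#' @param path file path
#' @return named list of character vectors; descriptions kept in
#'   `attr(, "description")`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]))
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(
    vapply(fields, `[[`, character(1), 2), nm)
  sets
}

#' Read a gene expression matrix
#'
#' Genes in rows (first column gene symbols), samples in columns. Values are
#' assumed to be on a log-like scale; no range restriction is applied.
#'
#' @param path file path
#' @param sep field separator
#' @param uppercase_genes upper-case gene symbols on load
#' @return numeric matrix with gene rownames
#' @export
read_expression_matrix <- function(path, sep = "\t", uppercase_genes = FALSE) {
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "NaN", ""))
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty expression matrix")
  genes <- as.character(df[[1]])
  if (uppercase_genes) genes <- toupper(genes)
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  vals <- df[, -1, drop = FALSE]
  numok <- vapply(vals, is.numeric, logical(1))
  if (!all(numok)) stop("non-numeric expression values")
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' Write a generic matrix with an id column
#' @param m matrix with rownames
#' @param path output file
#' @param id_col name of the identifier column
#' @export
write_id_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
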