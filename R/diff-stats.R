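#' Logistic-regression likelihood-ratio test for one CpG
#'
#' Regresses the binary phenotype on the beta-value of a single CpG
#' (phenotype ~ intercept + beta) and tests the beta coefficient with a
#' likelihood ratio test against the intercept-only model
#' (`lrt_stat = 2 * (loglik_full - loglik_null)`, chi-square with 1 df).
#' The effect size is the median beta difference (case minus control).
#'
#' Complete or quasi-complete separation is detected when the fitted slope
#' exceeds `cap` in absolute value; the slope is then pinned at the cap, the
#' intercept re-profiled, and the result flagged. This keeps the statistic
#' (and therefore the CpG ranking) finite.
#'
#' @param beta_row per-sample beta values for one CpG
#' @param phenotype 0/1 labels aligned to `beta_row`
#' @param cap absolute bound on the logistic slope (separation guard)
#' @return list with `delta`, `lrt_stat`, `p`, `z`, `separated`, `n_used`
#' @examples
#' fit_cpg_logistic(c(0.2, 0.3, 0.7, 0.8), c(0, 0, 1, 1))
#' @export
fit_cpg_logistic <- function(beta_row, phenotype, cap = 50) {
  ok <- !is.na(beta_row) & !is.na(phenotype)
  x <- as.numeric(beta_row[ok])
  y <- as.integer(phenotype[ok])
  if (length(y) == 0 || length(unique(y)) < 2)
    stop("phenotype is constant (or empty) after missing-value removal")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 samples per class after missing-value removal")
  delta <- stats::median(x[y == 1]) - stats::median(x[y == 0])

  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  pbar <- mean(y)
  ll0 <- sum(y) * log(pbar) + (length(y) - sum(y)) * log(1 - pbar)

  if (stats::var(x) == 0) {
    return(list(delta = 0, lrt_stat = 0, p = 1, z = 0,
                separated = FALSE, n_used = length(y)))
  }

  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                         family = stats::binomial()))
  b <- fit$coefficients[2]
  separated <- !is.finite(b) || abs(b) > cap
  if (separated) {
    bsign <- if (is.finite(b) && b != 0) sign(b) else sign(sum((x - mean(x)) * y))
    if (bsign == 0) bsign <- 1
    bcap <- bsign * cap
    lim <- cap * max(abs(x)) + 25
    opt <- stats::optimize(function(a) -loglik(a, bcap),
                           interval = c(-lim, lim), tol = 1e-10)
    ll1 <- -opt$objective
  } else {
    ll1 <- -fit$deviance / 2  # binomial 0/1: saturated loglik is 0
  }
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- .floor_p(stats::pchisq(lrt, df = 1, lower.tail = FALSE))
  list(delta = delta, lrt_stat = lrt, p = p,
       z = signed_zstat(p, delta), separated = separated,
       n_used = length(y))
}

#' Per-CpG differential methylation statistics with FDR
#'
#' Applies [fit_cpg_logistic()] to every CpG of a beta matrix (missing
#' values handled pairwise-complete per CpG), then attaches Storey q-values.
#' CpGs for which the model cannot be fitted (fewer than two samples per
#' class after missing-value removal) get `NA` statistics.
#'
#' @param beta beta matrix (CpG rows, sample columns)
#' @param samples sample sheet with `sample_id`, `phenotype`
#' @param cap separation guard passed to [fit_cpg_logistic()]
#' @return data.frame: `cpg_id`, `delta`, `lrt_stat`, `p`, `q`, `z`,
#'   `separated`
#' @export
dmc_stats <- function(beta, samples, cap = 50) {
  beta <- validate_beta_matrix(beta)
  ph <- align_phenotype(samples, colnames(beta))
  res <- vector("list", nrow(beta))
  for (i in seq_len(nrow(beta))) {
    res[[i]] <- tryCatch(fit_cpg_logistic(beta[i, ], ph, cap = cap),
                         error = function(e)
                           list(delta = NA_real_, lrt_stat = NA_real_,
                                p = NA_real_, z = NA_real_,
                                separated = NA, n_used = NA_integer_))
  }
  out <- data.frame(
    cpg_id = rownames(beta),
    delta = vapply(res, `[[`, numeric(1), "delta"),
    lrt_stat = vapply(res, `[[`, numeric(1), "lrt_stat"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$q <- NA_real_
  okp <- !is.na(out$p)
  if (any(okp)) out$q[okp] <- storey_qvalues(out$p[okp])
  out$z <- vapply(res, `[[`, numeric(1), "z")
  out$separated <- vapply(res, function(r)
    as.logical(r$separated), logical(1))
  out
}

#' Call differentially methylated CpGs at a q-value threshold
#'
#' Splits significant CpGs into hypermethylated (`delta > 0`) and
#' hypomethylated (`delta < 0`) lists, each ordered by increasing p.
#'
#' @param stats data.frame from [dmc_stats()]
#' @param q_threshold q-value (FDR) cutoff, default 0.1
#' @return list with data.frames `hyper` and `hypo`
#' @export
call_dmcs <- function(stats, q_threshold = 0.1) {
  stopifnot(is.data.frame(stats), all(c("q", "delta", "p") %in% names(stats)))
  sig <- !is.na(stats$q) & stats$q < q_threshold
  hyper <- stats[sig & stats$delta > 0, , drop = FALSE]
  hypo <- stats[sig & stats$delta < 0, , drop = FALSE]
  list(hyper = hyper[order(hyper$p), , drop = FALSE],
       hypo = hypo[order(hypo$p), , drop = FALSE])
}

#' Principal component summary of a beta matrix
#'
#' Singular value decomposition of the row-centred matrix. Returns the
#' fraction of variance explained per component and the per-sample weights
#' (right singular vectors), which can be tested against the phenotype with
#' e.g. a Wilcoxon rank-sum test.
#'
#' @param beta beta matrix (CpG rows, sample columns)
#' @param n_components number of components to return
#' @param impute mean-impute missing values per CpG before the SVD
#' @return list: `var_explained`, `sample_weights` (samples x components),
#'   `imputed` flag
#' @export
pca_summary <- function(beta, n_components = 2, impute = TRUE) {
  beta <- validate_beta_matrix(beta)
  if (n_components > ncol(beta))
    stop("fewer samples than components requested")
  imputed <- FALSE
  if (anyNA(beta)) {
    if (!impute) stop("beta matrix has missing values; set impute = TRUE")
    imputed <- TRUE
    rm_ <- rowMeans(beta, na.rm = TRUE)
    idx <- which(is.na(beta), arr.ind = TRUE)
    beta[idx] <- rm_[idx[, 1]]
  }
  x <- beta - rowMeans(beta)
  sv <- svd(x, nu = 0, nv = n_components)
  varfrac <- sv$d^2 / sum(sv$d^2)
  w <- sv$v
  rownames(w) <- colnames(beta)
  colnames(w) <- paste0("PC", seq_len(ncol(w)))
  list(var_explained = varfrac[seq_len(n_components)],
       sample_weights = w, imputed = imputed)
}
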