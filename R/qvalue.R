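#' Estimate the proportion of true nulls (pi0) by the smoother method
#'
#' Computes `pi0(lambda) = #{p > lambda} / (m * (1 - lambda))` over a lambda
#' grid and extrapolates with a cubic smoothing spline to the largest lambda.
#' The spline is precision-weighted (weight `1 - lambda`, the
#' inverse-variance scale of the per-lambda estimate), which stabilises its
#' noisy high-lambda end. Falls back to 1 when the input is too small for a
#' stable estimate or when the estimate leaves (0, 1].
#'
#' @param p p-values in (0, 1]
#' @param lambda grid of tuning values
#' @param min_m smallest input size for which the smoother is attempted
#' @return pi0 estimate in (0, 1]
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05), min_m = 100) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (m < min_m) return(1)
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  est <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0_lambda, w = 1 - lambda, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (!is.finite(est) || est > 1 || est <= 0) return(1)
  max(est, 1 / m)
}

#' Storey q-values
#'
#' FDR-controlling q-values: `q_i = min over p_(j) >= p_(i) of
#' pi0 * m * p_(j) / j`, capped at 1. With `pi0 = 1` this reduces exactly to
#' the Benjamini-Hochberg adjusted p-values.
#'
#' @param p p-values in (0, 1]
#' @param pi0 proportion of true nulls; estimated by [storey_pi0()] when NULL
#' @return q-values in input order
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(pi0)) pi0 <- storey_pi0(p)
  stopifnot(is.numeric(pi0), length(pi0) == 1, pi0 > 0, pi0 <= 1)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # arithmetic mirrors stats::p.adjust(..., "BH") so pi0 = 1 matches exactly
  q <- pmin(1, cummin(pi0 * (m / (m:1)) * p[o]))[ro]
  q
}
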