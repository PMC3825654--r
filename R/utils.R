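#' Signed normal-scale statistic from a two-sided p-value
#'
#' Converts a two-sided p-value and an effect direction into a signed
#' standard-normal-scale statistic `sign(delta) * qnorm(1 - p/2)`. This is the
#' node statistic carried onto the network: it preserves the ranking by p and
#' gives hyper- and hypomethylation opposite signs. A zero effect maps to 0.
#'
#' @param p two-sided p-values in (0, 1]
#' @param delta signed effect sizes (their sign is used)
#' @return numeric vector of signed z statistics
#' @examples
#' signed_zstat(0.05, 1)
#' signed_zstat(0.05, -1)
#' @export
signed_zstat <- function(p, delta) {
  stopifnot(length(p) == length(delta))
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad)) stop("p-values must lie in (0, 1]")
  # lower.tail = FALSE keeps precision for very small p
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  sign(delta) * z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp p away from exact zero so invariants p in (0,1] hold after underflow
.floor_p <- function(p) pmax(p, 1e-300)

.assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer", name))
  invisible(as.integer(x))
}
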