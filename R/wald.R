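#' Wald confidence interval
#'
#' Symmetric normal-theory interval `point +/- z * se`. Endpoints are
#' deliberately not truncated to \[0, 1\]: on small samples the interval for an
#' AUC can overshoot 1 (or undershoot 0), and the overshoot is informative
#' about the adequacy of the normal approximation.
#'
#' @param point point estimate.
#' @param se standard error, `>= 0`.
#' @param level confidence level in (0, 1); default 0.95.
#'
#' @return Named numeric vector `c(low =, high =)`.
#' @examples
#' wald_ci(0.85, 0.05)
#' @export
wald_ci <- function(point, se, level = 0.95) {
  if (!is.finite(se) || se < 0) {
    stop("'se' must be a nonnegative finite number", call. = FALSE)
  }
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("'level' must lie strictly inside (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = point - z * se, high = point + z * se)
}
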