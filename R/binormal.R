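#' Area under the binormal ROC curve
#'
#' Under the binormal model the ROC curve is
#' `ROC(t) = Phi(a + b * Phi^{-1}(t))` with intercept `a = (mu1 - mu0)/sigma1`
#' and slope `b = sigma0/sigma1`; its area is `Phi(a / sqrt(1 + b^2))`.
#'
#' @param a binormal intercept (separation in diseased-SD units).
#' @param b binormal slope (ratio of nondiseased to diseased SD), `> 0`.
#' @return AUC in (0, 1).
#' @examples
#' binormal_auc(1.4, 0.9)
#' @export
binormal_auc <- function(a, b) {
  if (any(!is.finite(b)) || any(b <= 0)) {
    stop("'b' must be positive and finite", call. = FALSE)
  }
  stats::pnorm(a / sqrt(1 + b^2))
}

#' Large-sample variances of the binormal parameter estimates
#'
#' Moment-based variances of the plug-in estimates of `a` and `b`:
#' `V(a) = [n1 (a^2 + 2) + 2 n0 b^2] / (2 n0 n1)` and
#' `V(b) = (n1 + n0) b^2 / (2 n0 n1)`.
#'
#' @param a,b binormal parameters.
#' @param n1,n0 diseased / nondiseased group sizes.
#' @return List with `var_a` and `var_b`.
#' @export
binormal_param_var <- function(a, b, n1, n0) {
  list(
    var_a = (n1 * (a^2 + 2) + 2 * n0 * b^2) / (2 * n0 * n1),
    var_b = (n1 + n0) * b^2 / (2 * n0 * n1)
  )
}

#' Delta-method standard error of the binormal AUC
#'
#' Propagates the variances of `(a, b)` through `AUC = Phi(a / sqrt(1 + b^2))`.
#' The gradient is `g_a = 1/sqrt(1 + b^2)` and
#' `g_b = -a b / (1 + b^2)^{3/2}`, so
#' `SE = phi(a / sqrt(1 + b^2)) * sqrt(g_a^2 V(a) + g_b^2 V(b) + 2 g_a g_b C(a,b))`.
#'
#' @param a,b binormal parameters.
#' @param var_a,var_b variances of the parameter estimates, `>= 0`.
#' @param cov_ab covariance of the estimates; defaults to 0.
#' @return Nonnegative standard error.
#' @export
binormal_auc_se <- function(a, b, var_a, var_b, cov_ab = 0) {
  if (var_a < 0 || var_b < 0) {
    stop("variances must be nonnegative", call. = FALSE)
  }
  s <- sqrt(1 + b^2)
  g_a <- 1 / s
  g_b <- -a * b / s^3
  v <- g_a^2 * var_a + g_b^2 * var_b + 2 * g_a * g_b * cov_ab
  stats::dnorm(a / s) * sqrt(max(v, 0))
}

#' Fit the binormal (parametric) ROC model
#'
#' Assumes the test results are normal in each group,
#' `Y1 ~ N(mu1, sigma1^2)` and `Y0 ~ N(mu0, sigma0^2)`, and plugs the sample
#' means and sample SDs (denominator n-1) into
#' `a = (mu1 - mu0)/sigma1`, `b = sigma0/sigma1`,
#' `AUC = Phi(a/sqrt(1 + b^2))`. Parameter variances come from
#' [binormal_param_var()]; the AUC standard error is the delta-method value of
#' [binormal_auc_se()] with `cov(a, b) = a b / (2 n1)` (both estimates share
#' the diseased-group SD in their denominator). The confidence interval is an
#' untruncated Wald interval.
#'
#' @param sample a [sample_data()] object; both groups need `n >= 2` and
#'   positive sample variance.
#' @param ci_level confidence level, default 0.95.
#'
#' @return Object of class `"binormal_roc"`: list with `mu1`, `mu0`, `sigma1`,
#'   `sigma0`, `a_hat`, `b_hat`, `var_a`, `var_b`, `auc`, `se_auc`, `ci_low`,
#'   `ci_high`, `n1`, `n0`, `ci_level`.
#'
#' @examples
#' s <- sample_data(rnorm(50, 1.4 / 0.9, 1 / 0.9), rnorm(50))
#' fit_binormal(s)
#' @export
fit_binormal <- function(sample, ci_level = 0.95) {
  stopifnot(inherits(sample, "sample_data"))
  check_min_group_sizes(sample)
  mu1 <- mean(sample$diseased)
  mu0 <- mean(sample$nondiseased)
  sigma1 <- stats::sd(sample$diseased)
  sigma0 <- stats::sd(sample$nondiseased)
  if (sigma1 == 0 || sigma0 == 0) {
    stop("a group has zero variance: the binormal slope b is unidentifiable",
         call. = FALSE)
  }
  a_hat <- (mu1 - mu0) / sigma1
  b_hat <- sigma0 / sigma1
  v <- binormal_param_var(a_hat, b_hat, sample$n1, sample$n0)
  auc <- binormal_auc(a_hat, b_hat)
  cov_ab <- a_hat * b_hat / (2 * sample$n1)
  se_auc <- binormal_auc_se(a_hat, b_hat, v$var_a, v$var_b, cov_ab)
  ci <- wald_ci(auc, se_auc, ci_level)
  structure(
    list(
      mu1 = mu1, mu0 = mu0, sigma1 = sigma1, sigma0 = sigma0,
      a_hat = a_hat, b_hat = b_hat,
      var_a = v$var_a, var_b = v$var_b,
      auc = auc, se_auc = se_auc,
      ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
      n1 = sample$n1, n0 = sample$n0, ci_level = ci_level
    ),
    class = "binormal_roc"
  )
}

#' @export
print.binormal_roc <- function(x, ...) {
  cat("Binormal ROC fit (n1 =", x$n1, ", n0 =", x$n0, ")\n")
  cat(sprintf("  a = %.3f (SE %.3f), b = %.3f (SE %.3f)\n",
              x$a_hat, sqrt(x$var_a), x$b_hat, sqrt(x$var_b)))
  cat(sprintf("  AUC = %.3f (SE %.3f), %g%% CI %.3f-%.3f\n",
              x$auc, x$se_auc, 100 * x$ci_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Smooth binormal ROC coordinates
#'
#' Evaluates `ROC(t) = Phi(a + b * Phi^{-1}(t))` on a grid of false-positive
#' rates, for plotting or export.
#'
#' @param a,b binormal parameters (also used for the semiparametric
#'   coefficients, which parameterize the same curve family).
#' @param t grid of false-positive rates strictly inside (0, 1).
#' @return `data.frame` with columns `t` and `roc`.
#' @export
binormal_roc_points <- function(a, b, t = seq(0.001, 0.999, by = 0.001)) {
  if (any(t <= 0) || any(t >= 1)) {
    stop("'t' must lie strictly inside (0, 1)", call. = FALSE)
  }
  data.frame(t = t, roc = stats::pnorm(a + b * stats::qnorm(t)))
}
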