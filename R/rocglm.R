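#' Pairwise indicator design for the semiparametric ROC-GLM
#'
#' For every diseased/nondiseased pair the binary outcome is
#' `U_ij = I[Y_i1 >= Y_j0]` (ties score 1, matching the >= positivity
#' convention) and the regressor is the placement value
#' `t_j = FP(Y_j0) = #(Y_k0 >= Y_j0) / n0`, the false-positive rate attained
#' at the nondiseased subject's own value. The minimum nondiseased value has
#' `t = 1`, whose probit is infinite; those rows are flagged and excluded from
#' the regression.
#'
#' The design always carries an exact aggregated representation — binomial
#' successes and trials per distinct retained placement value — which is what
#' [fit_semiparametric()] consumes (the likelihood is identical to the
#' per-pair Bernoulli one). The per-pair vectors `u`, `t`, `keep` are
#' materialized only when `n1 * n0 <= max_pairs`.
#'
#' @param sample a [sample_data()] object.
#' @param max_pairs materialize per-pair vectors only up to this many pairs.
#' @return Object of class `"pair_design"`: list with `agg` (data frame with
#'   `t`, `probit_t`, `successes`, `trials` per distinct retained placement
#'   value), `n_dropped` (pairs excluded because `t = 1`), `n_pairs`, `n1`,
#'   `n0`, `auc_all_pairs` (mean of U over all pairs, dropped rows included),
#'   and, when materialized, `u`, `t`, `keep` of length `n1 * n0` ordered with
#'   the diseased index varying fastest.
#' @examples
#' build_pair_design(sample_data(c(3, 5), c(1, 4)))
#' @export
build_pair_design <- function(sample, max_pairs = 1e6) {
  stopifnot(inherits(sample, "sample_data"))
  d <- sample$diseased
  nd <- sample$nondiseased
  n1 <- sample$n1
  n0 <- sample$n0

  t_j <- vapply(nd, function(y) sum(nd >= y), numeric(1)) / n0
  exceed <- vapply(nd, function(y) sum(d >= y), numeric(1))  # #(Y1 >= Y_j0)
  keep_j <- t_j < 1

  auc_all <- sum(exceed) / (n1 * n0)
  if (!any(keep_j)) {
    stop("no usable design rows: every nondiseased value attains t = 1",
         call. = FALSE)
  }

  kept <- which(keep_j)
  t_lev <- sort(unique(t_j[kept]))
  agg <- data.frame(
    t = t_lev,
    probit_t = stats::qnorm(t_lev),
    successes = vapply(t_lev, function(tv) sum(exceed[kept][t_j[kept] == tv]),
                       numeric(1)),
    trials = vapply(t_lev, function(tv) n1 * sum(t_j[kept] == tv),
                    numeric(1))
  )

  out <- list(
    agg = agg,
    n_dropped = n1 * sum(!keep_j),
    n_pairs = n1 * n0,
    n1 = n1, n0 = n0,
    auc_all_pairs = auc_all
  )
  if (n1 * n0 <= max_pairs) {
    out$u <- as.vector(outer(d, nd, ">=")) * 1
    out$t <- rep(t_j, each = n1)
    out$keep <- rep(keep_j, each = n1)
  }
  class(out) <- "pair_design"
  out
}

#' @export
print.pair_design <- function(x, ...) {
  cat("ROC-GLM pair design:", x$n_pairs, "pairs,", x$n_dropped,
      "dropped at t = 1,", nrow(x$agg), "distinct placement values\n")
  invisible(x)
}

#' Fit the semiparametric ROC-GLM by probit regression
#'
#' Maximum-likelihood probit regression of the pairwise indicators on
#' `(1, Phi^{-1}(t))`, i.e. the model `E(U_ij) = Phi(beta1 + beta2 *
#' Phi^{-1}(t_j))`, fitted by iteratively reweighted least squares (deviance
#' criterion 1e-12 — coefficient changes at convergence are well below 1e-8 —
#' at most 100 iterations) under working independence: the pairs share
#' subjects, the fit ignores that, and all inference is delegated to the
#' subject-level bootstrap of [bootstrap_semiparametric()]. `beta1` and
#' `beta2` play the roles of the binormal `a` and `b`.
#'
#' A (quasi-)separated design drives fitted probabilities to the 0/1
#' boundary; the IRLS still stabilizes and the boundary estimates (typically
#' a very large slope or intercept) are returned with `separated = TRUE`.
#'
#' @param design a [build_pair_design()] object with at least 2 distinct
#'   retained placement values and both outcome classes present.
#' @return List with `beta1`, `beta2`, `converged` (IRLS criterion met;
#'   estimates are returned at the last iterate either way) and `separated`
#'   (fitted probabilities numerically 0 or 1 occurred).
#' @export
fit_semiparametric <- function(design) {
  stopifnot(inherits(design, "pair_design"))
  agg <- design$agg
  if (nrow(agg) < 2L) {
    stop("need at least 2 distinct placement values to fit the ROC-GLM",
         call. = FALSE)
  }
  succ <- sum(agg$successes)
  if (succ == 0 || succ == sum(agg$trials)) {
    stop("pairwise outcomes are all ", as.integer(succ > 0),
         ": cannot fit a binary regression", call. = FALSE)
  }
  x <- cbind(intercept = 1, probit_t = agg$probit_t)
  boundary <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(
      x, agg$successes / agg$trials, weights = agg$trials,
      family = stats::binomial(link = "probit"),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        boundary <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  list(
    beta1 = unname(fit$coefficients[1]),
    beta2 = unname(fit$coefficients[2]),
    converged = isTRUE(fit$converged),
    separated = boundary
  )
}

#' AUC implied by the semiparametric ROC-GLM coefficients
#'
#' Same functional as the binormal AUC: `Phi(beta1 / sqrt(1 + beta2^2))`.
#' No sign restriction is placed on `beta2`; a negative fitted slope signals
#' a degenerate fit and is passed through unchanged.
#'
#' @param beta1,beta2 fitted ROC-GLM coefficients.
#' @return AUC value.
#' @examples
#' semiparametric_auc(1.310, 1.018)  # 0.821
#' @export
semiparametric_auc <- function(beta1, beta2) {
  stats::pnorm(beta1 / sqrt(1 + beta2^2))
}

#' Semiparametric ROC estimate with bootstrap inference
#'
#' Point fit of the ROC-GLM on the full sample, plus a stratified
#' nonparametric bootstrap for the standard errors: subjects are resampled
#' with replacement within each disease group (preserving `n1` and `n0`; the
#' pairs are derived quantities, not sampling units), the design is rebuilt
#' and the model refitted per resample, and the SEs are the SDs of the
#' bootstrap replicates. The confidence interval is a Wald interval around
#' the original-sample AUC. Resamples whose fit errors (a single outcome
#' class or a single placement value) or whose IRLS does not converge are
#' dropped and counted; more than 10 percent failures is an error. Separated
#' resamples that still stabilize are kept: their extreme boundary estimates
#' are precisely what inflates the bootstrap SE on small skewed samples, and
#' discarding them would understate the uncertainty.
#'
#' @param sample a [sample_data()] object.
#' @param n_boot number of bootstrap resamples, `>= 2`; default 200.
#' @param seed integer seed making the resampling deterministic.
#' @param ci_level confidence level, default 0.95.
#' @return Object of class `"rocglm"`: list with `beta1`, `beta2`, `auc`,
#'   `se_beta1`, `se_beta2`, `se_auc`, `ci_low`, `ci_high`, `n_boot`,
#'   `n_failed`, `converged`, `n1`, `n0`, `ci_level`.
#' @examples
#' s <- sample_data(rnorm(30, 1.5), rnorm(30))
#' bootstrap_semiparametric(s, n_boot = 50, seed = 1)
#' @export
bootstrap_semiparametric <- function(sample, n_boot = 200, seed = 1,
                                     ci_level = 0.95) {
  stopifnot(inherits(sample, "sample_data"))
  if (n_boot < 2) stop("'n_boot' must be at least 2", call. = FALSE)
  point <- fit_semiparametric(build_pair_design(sample))
  auc <- semiparametric_auc(point$beta1, point$beta2)

  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("beta1", "beta2", "auc")))
  for (b in seq_len(n_boot)) {
    bs <- sample_data(
      sample(sample$diseased, sample$n1, replace = TRUE),
      sample(sample$nondiseased, sample$n0, replace = TRUE)
    )
    res <- tryCatch({
      f <- fit_semiparametric(build_pair_design(bs))
      if (!f$converged) stop("nonconvergent resample")
      c(f$beta1, f$beta2, semiparametric_auc(f$beta1, f$beta2))
    }, error = function(e) NULL)
    if (!is.null(res)) reps[b, ] <- res
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed / n_boot > 0.10) {
    stop("bootstrap failed: ", n_failed, " of ", n_boot,
         " resamples did not yield a converged fit", call. = FALSE)
  }
  se <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
  ci <- wald_ci(auc, unname(se["auc"]), ci_level)
  structure(
    list(
      beta1 = point$beta1, beta2 = point$beta2, auc = auc,
      se_beta1 = unname(se["beta1"]), se_beta2 = unname(se["beta2"]),
      se_auc = unname(se["auc"]),
      ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
      n_boot = n_boot, n_failed = n_failed,
      converged = point$converged, separated = point$separated,
      n1 = sample$n1, n0 = sample$n0, ci_level = ci_level
    ),
    class = "rocglm"
  )
}

#' @export
print.rocglm <- function(x, ...) {
  cat("Semiparametric ROC-GLM fit (n1 =", x$n1, ", n0 =", x$n0, ")\n")
  cat(sprintf("  beta1 = %.3f (SE %.3f), beta2 = %.3f (SE %.3f)\n",
              x$beta1, x$se_beta1, x$beta2, x$se_beta2))
  cat(sprintf("  AUC = %.3f (SE %.3f), %g%% CI %.3f-%.3f  [%d bootstraps, %d failed]\n",
              x$auc, x$se_auc, 100 * x$ci_level, x$ci_low, x$ci_high,
              x$n_boot, x$n_failed))
  invisible(x)
}
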