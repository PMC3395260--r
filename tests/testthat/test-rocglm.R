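test_that("pair design enumerates indicators and placement values", {
  des <- build_pair_design(sample_data(c(3, 5), c(1, 4)))
  # Y0 = 1 attains t = 1 and is dropped; Y0 = 4 has t = 1/2
  expect_equal(des$n_dropped, 2)
  expect_equal(des$n_pairs, 4)
  expect_equal(des$agg$t, 0.5)
  expect_equal(des$agg$successes, 1)  # only 5 >= 4
  expect_equal(des$agg$trials, 2)
  # materialized per-pair rows, diseased index fastest
  expect_equal(des$u, c(1, 1, 0, 1))
  expect_equal(des$t, c(1, 1, 0.5, 0.5))
  expect_equal(des$keep, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("a single nondiseased value leaves no usable rows", {
  expect_error(build_pair_design(sample_data(c(1, 2), 5)), "no usable")
})

test_that("separated groups yield all-one retained outcomes", {
  des <- build_pair_design(sample_data(c(10, 11, 12), c(1, 2, 3)))
  expect_true(all(des$u[des$keep] == 1))
  # ... and a single-class regression is refused
  expect_error(fit_semiparametric(des), "all 1")
})

test_that("mean indicator over all pairs equals the empirical AUC (tie-free)", {
  set.seed(31)
  for (i in 1:30) {
    s <- sample_data(rnorm(sample(3:10, 1)), rnorm(sample(3:10, 1)))
    des <- build_pair_design(s)
    expect_equal(des$auc_all_pairs, empirical_auc(s), tolerance = 1e-12)
    expect_equal(mean(des$u), empirical_auc(s), tolerance = 1e-12)
  }
})

test_that("aggregated counts are an exact regrouping of the pair rows", {
  set.seed(32)
  for (i in 1:20) {
    s <- random_tied_sample()
    if (length(unique(s$nondiseased)) < 2) next  # no retained rows
    des <- build_pair_design(s)
    kept_t <- des$t[des$keep]
    kept_u <- des$u[des$keep]
    expect_equal(sum(des$agg$trials), length(kept_t))
    expect_equal(sum(des$agg$successes), sum(kept_u))
    for (k in seq_len(nrow(des$agg))) {
      expect_equal(des$agg$trials[k], sum(kept_t == des$agg$t[k]))
      expect_equal(des$agg$successes[k], sum(kept_u[kept_t == des$agg$t[k]]))
    }
  }
})

test_that("probit fit matches an independent Newton ML oracle", {
  # fixed tiny fixture, n1 = n0 = 5
  s <- sample_data(c(1.2, 2.5, 0.8, 3.1, 1.9), c(0.4, 1.5, 0.9, 2.2, 0.1))
  des <- build_pair_design(s)
  fit <- fit_semiparametric(des)
  keep <- des$keep
  X <- cbind(1, qnorm(des$t[keep]))
  beta <- oracle_probit_ml(X, des$u[keep])
  expect_equal(fit$beta1, beta[1], tolerance = 1e-8)
  expect_equal(fit$beta2, beta[2], tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("a two-point design reproduces the closed-form probit solution", {
  # distinct retained t values 2/3 and 1/3 with success rates 3/4 and 1/2:
  # two parameters, two equations, solvable exactly
  s <- sample_data(c(1, 2, 3, 4), c(0, 1.5, 2.5))
  fit <- fit_semiparametric(build_pair_design(s))
  b2 <- (qnorm(3 / 4) - qnorm(1 / 2)) / (qnorm(2 / 3) - qnorm(1 / 3))
  b1 <- qnorm(3 / 4) - b2 * qnorm(2 / 3)
  expect_equal(fit$beta1, b1, tolerance = 1e-6)
  expect_equal(fit$beta2, b2, tolerance = 1e-6)
})

test_that("fewer than two distinct placement values is an error", {
  expect_error(fit_semiparametric(build_pair_design(sample_data(c(1, 3), c(0, 2)))),
               "distinct placement")
})

test_that("null data drive the coefficients to the chance diagonal", {
  set.seed(33)
  s <- sample_data(rnorm(1500), rnorm(1500))
  fit <- fit_semiparametric(build_pair_design(s))
  expect_lt(abs(fit$beta1), 0.1)
  expect_lt(abs(fit$beta2 - 1), 0.1)
  expect_lt(abs(semiparametric_auc(fit$beta1, fit$beta2) - 0.5), 0.05)
})

test_that("coefficients are consistent for the binormal truth at large n", {
  spec <- scenario_spec("normal", n1 = 1e4, n0 = 1e4, seed = 34)
  fit <- fit_semiparametric(build_pair_design(generate_sample(spec, 34)))
  expect_lt(abs(fit$beta1 - 1.4), 0.05)
  expect_lt(abs(fit$beta2 - 0.9), 0.05)
})

test_that("semiparametric AUC uses the binormal functional", {
  expect_equal(round(semiparametric_auc(1.310, 1.018), 3), 0.821)
  expect_equal(round(semiparametric_auc(1.4, 0.9), 3), 0.851)
  expect_equal(semiparametric_auc(0, 2.3), 0.5)
  # negative slope is passed through, not rejected
  expect_equal(semiparametric_auc(1, -1), pnorm(1 / sqrt(2)))
})

test_that("fitted smooth ROC is monotone when the slope is nonnegative", {
  set.seed(35)
  s <- sample_data(rnorm(80, 1.2), rnorm(80))
  fit <- fit_semiparametric(build_pair_design(s))
  expect_gte(fit$beta2, 0)
  pts <- binormal_roc_points(fit$beta1, fit$beta2)
  expect_true(all(diff(pts$roc) >= 0))
})

test_that("swapping group labels approximately inverts the fitted curve", {
  spec <- scenario_spec("normal", n1 = 500, n0 = 500, seed = 36)
  for (r in 1:5) {
    s <- generate_sample(spec, replicate_seed(36, r))
    f <- fit_semiparametric(build_pair_design(s))
    g <- fit_semiparametric(build_pair_design(sample_data(s$nondiseased, s$diseased)))
    expect_lt(abs(g$beta1 - (-f$beta1 / f$beta2)), 0.05 * max(1, abs(f$beta1)))
    expect_lt(abs(g$beta2 - 1 / f$beta2), 0.05 * max(1, 1 / f$beta2))
    expect_lt(abs(semiparametric_auc(g$beta1, g$beta2) -
                    (1 - semiparametric_auc(f$beta1, f$beta2))), 0.05)
  }
})

test_that("two-resample bootstrap SE equals the two-point SD identity", {
  set.seed(37)
  s <- sample_data(rnorm(20, 1.5), rnorm(20))
  est <- bootstrap_semiparametric(s, n_boot = 2, seed = 99)
  # recompute the two replicates by hand with the same stream
  set.seed(99)
  reps <- sapply(1:2, function(b) {
    bs <- sample_data(sample(s$diseased, 20, replace = TRUE),
                      sample(s$nondiseased, 20, replace = TRUE))
    f <- fit_semiparametric(build_pair_design(bs))
    semiparametric_auc(f$beta1, f$beta2)
  })
  expect_equal(est$se_auc, abs(reps[1] - reps[2]) / sqrt(2), tolerance = 1e-12)
})

test_that("bootstrap is deterministic given a seed and validates inputs", {
  set.seed(38)
  s <- sample_data(rnorm(25, 1.5), rnorm(25))
  e1 <- bootstrap_semiparametric(s, n_boot = 30, seed = 7)
  e2 <- bootstrap_semiparametric(s, n_boot = 30, seed = 7)
  expect_identical(e1, e2)
  expect_error(bootstrap_semiparametric(s, n_boot = 1, seed = 7), "at least 2")
})

test_that("excess resample failures abort the bootstrap", {
  # near-separated sample: resamples that lose the one nondiseased value
  # above the diseased minimum are single-class and fail
  frail <- sample_data(c(5, 6, 7), c(1, 2, 6.5))
  expect_error(bootstrap_semiparametric(frail, n_boot = 10, seed = 7),
               "bootstrap failed")
})

test_that("separation is flagged but boundary estimates are returned", {
  # outcome flips from all-0 to all-1 between the two placement values
  des <- build_pair_design(sample_data(c(5, 6, 7), c(1, 2, 100)))
  fit <- fit_semiparametric(des)
  expect_true(fit$separated)
  expect_true(is.finite(fit$beta1) && is.finite(fit$beta2))
  expect_gt(fit$beta2, 5)  # boundary slope blows up
})

test_that("bootstrap SE tracks the sampling SD of the point estimator", {
  # Monte-Carlo oracle: SD of point AUC estimates over fresh n=25 samples
  spec <- scenario_spec("normal", n1 = 25, n0 = 25, seed = 39)
  mc <- vapply(1:400, function(r) {
    f <- fit_semiparametric(build_pair_design(generate_sample(spec, replicate_seed(39, r))))
    semiparametric_auc(f$beta1, f$beta2)
  }, numeric(1))
  est <- bootstrap_semiparametric(generate_sample(spec, replicate_seed(39, 1001)),
                                  n_boot = 200, seed = 40)
  expect_lt(abs(est$se_auc - sd(mc)) / sd(mc), 0.30)
})

test_that("skewed small samples inflate the bootstrap SE above the sampling SD", {
  # heavy-tailed resamples occasionally near-separate, blowing up the
  # coefficient spread: the bootstrap SE exceeds the across-sample SD
  spec <- scenario_spec("lognormal", n1 = 15, n0 = 15, seed = 41)
  mc <- vapply(1:200, function(r) {
    f <- fit_semiparametric(build_pair_design(generate_sample(spec, replicate_seed(41, r))))
    semiparametric_auc(f$beta1, f$beta2)
  }, numeric(1))
  est <- bootstrap_semiparametric(generate_sample(spec, replicate_seed(41, 1)),
                                  n_boot = 200, seed = 42)
  expect_gt(est$se_auc, sd(mc))
})
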