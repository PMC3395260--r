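#' Monte-Carlo scenario specification
#'
#' Defines one benchmark scenario: the generating family, the true binormal
#' parameters on the latent scale, the group sizes and the number of
#' replicates. All three families are calibrated so the diseased group has
#' mean `a/b` and SD `1/b` and the nondiseased group mean 0 and SD 1 (on the
#' log scale for the lognormal family):
#'
#' * `normal`: `Y1 ~ N(a/b, (1/b)^2)`, `Y0 ~ N(0, 1)`.
#' * `lognormal`: exponentials of the normal draws (location `a/b`, scale
#'   `1/b` on the log scale) — a strongly right-skewed family whose ranks
#'   match the normal family exactly.
#' * `uniform`: `Y1 ~ U(a/b - sqrt(12)/(2b), a/b + sqrt(12)/(2b))`,
#'   `Y0 ~ U(-sqrt(3), sqrt(3))` — same means and SDs, monotone density.
#'   `uniform_literal = TRUE` swaps the nondiseased law for `U(-3, 3)`
#'   (SD sqrt(3)), kept for sensitivity analysis.
#'
#' The nominal AUC used as the bias reference in every family is the binormal
#' value `Phi(a / sqrt(1 + b^2))`, including the uniform family (where the
#' true exceedance probability, [uniform_pair_auc()], is slightly lower).
#'
#' @param family `"normal"`, `"lognormal"` or `"uniform"`.
#' @param a,b true binormal parameters; defaults 1.400 and 0.900.
#' @param n1,n0 group sizes.
#' @param n_reps number of Monte-Carlo replicates, default 1000.
#' @param seed integer study seed.
#' @param uniform_literal use the `U(-3, 3)` nondiseased law (see above).
#' @return Object of class `"scenario_spec"`, a list of the arguments plus
#'   `nominal_auc`.
#' @examples
#' scenario_spec("normal", n1 = 100, n0 = 100)
#' @export
scenario_spec <- function(family = c("normal", "lognormal", "uniform"),
                          a = 1.4, b = 0.9, n1, n0, n_reps = 1000,
                          seed = 1, uniform_literal = FALSE) {
  family <- match.arg(family)
  stopifnot(b > 0, n1 >= 1, n0 >= 1, n_reps >= 1)
  structure(
    list(
      family = family, a = a, b = b, n1 = n1, n0 = n0,
      n_reps = n_reps, seed = as.integer(seed),
      uniform_literal = uniform_literal,
      nominal_auc = binormal_auc(a, b)
    ),
    class = "scenario_spec"
  )
}

#' Deterministic per-replicate seed
#'
#' Counter-based splitting of a study seed so that replicates are independent
#' streams, studies are reproducible, and the derived seed stays below 2^31.
#' Scenarios sharing a study seed share per-replicate seeds — by construction
#' the lognormal draws are then the exponentials of the normal draws.
#'
#' @param seed study seed.
#' @param rep replicate index (1-based).
#' @return Integer seed.
#' @export
replicate_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) * 1000003 + rep) %% 2147483647)
}

#' Draw one sample from a scenario
#'
#' @param spec a [scenario_spec()].
#' @param rep_seed integer seed for this draw (see [replicate_seed()]).
#' @return A [sample_data()] object.
#' @examples
#' generate_sample(scenario_spec("lognormal", n1 = 25, n0 = 25), 42)
#' @export
generate_sample <- function(spec, rep_seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(rep_seed)
  m1 <- spec$a / spec$b
  s1 <- 1 / spec$b
  switch(spec$family,
    normal = sample_data(
      stats::rnorm(spec$n1, m1, s1),
      stats::rnorm(spec$n0, 0, 1)
    ),
    lognormal = sample_data(
      exp(stats::rnorm(spec$n1, m1, s1)),
      exp(stats::rnorm(spec$n0, 0, 1))
    ),
    uniform = {
      half1 <- sqrt(12) / (2 * spec$b)
      if (spec$uniform_literal) {
        l0 <- -3; r0 <- 3
      } else {
        l0 <- -sqrt(3); r0 <- sqrt(3)
      }
      sample_data(
        stats::runif(spec$n1, m1 - half1, m1 + half1),
        stats::runif(spec$n0, l0, r0)
      )
    }
  )
}

#' Exact exceedance probability for two independent uniforms
#'
#' Closed-form `P(Y1 > Y0)` for `Y1 ~ U(l1, r1)` and `Y0 ~ U(l0, r0)`,
#' obtained by piecewise integration of the nondiseased CDF over the diseased
#' support: the true AUC of the uniform scenario.
#'
#' @param l1,r1 diseased support endpoints, `l1 < r1`.
#' @param l0,r0 nondiseased support endpoints, `l0 < r0`.
#' @return Probability in \[0, 1\].
#' @examples
#' # the default uniform scenario at a = 1.4, b = 0.9
#' uniform_pair_auc(14 / 9 - sqrt(12) / 1.8, 14 / 9 + sqrt(12) / 1.8,
#'                  -sqrt(3), sqrt(3))
#' @export
uniform_pair_auc <- function(l1, r1, l0, r0) {
  stopifnot(l1 < r1, l0 < r0)
  w1 <- r1 - l1
  w0 <- r0 - l0
  # integral of clamp((y - l0)/w0, 0, 1) over [l1, r1]
  lo <- min(max(l1, l0), r1)
  hi <- min(max(l1, r0), r1)
  ramp <- ((hi - l0)^2 - (lo - l0)^2) / (2 * w0)
  flat <- max(0, r1 - max(l1, r0))
  (ramp + flat) / w1
}

#' True AUC of a scenario
#'
#' The actual exceedance probability `P(Y1 > Y0)` under the generating
#' distributions: the binormal value for the normal and lognormal families
#' (ranks are shared), the exact piecewise integral for the uniform family.
#'
#' @param spec a [scenario_spec()].
#' @return Probability in (0, 1).
#' @export
scenario_true_auc <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$family != "uniform") return(spec$nominal_auc)
  m1 <- spec$a / spec$b
  half1 <- sqrt(12) / (2 * spec$b)
  if (spec$uniform_literal) {
    uniform_pair_auc(m1 - half1, m1 + half1, -3, 3)
  } else {
    uniform_pair_auc(m1 - half1, m1 + half1, -sqrt(3), sqrt(3))
  }
}
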