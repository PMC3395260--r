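---
title: "Three routes to the ROC curve: binormal, empirical, and probit ROC-GLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three routes to the ROC curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roctrio)
```

## The problem

A continuous diagnostic test (a serum biomarker, say) is read against a
cutoff $c$: subjects with $Y \ge c$ are called positive. Sweeping $c$ traces
the ROC curve, the plot of the true-positive rate against the false-positive
rate, and the area under it (AUC) equals $P(Y_1 > Y_0)$ — the probability
that a random diseased subject scores above a random nondiseased one.

roctrio implements three estimators of that curve and area, chosen as the
canonical representative of each broad family, and a Monte-Carlo engine for
comparing them:

* **Parametric (P)** — the binormal model: $Y_1 \sim N(\mu_1, \sigma_1^2)$,
  $Y_0 \sim N(\mu_0, \sigma_0^2)$, giving the smooth curve
  $ROC(t) = \Phi(a + b\,\Phi^{-1}(t))$ with $a = (\mu_1-\mu_0)/\sigma_1$,
  $b = \sigma_0/\sigma_1$ and $AUC = \Phi(a/\sqrt{1+b^2})$.
* **Nonparametric (N)** — the empirical step curve and the Mann–Whitney
  AUC, the mean of the kernel scoring 1 / ½ / 0 for exceedance / tie /
  shortfall over all $n_1 n_0$ pairs.
* **Semiparametric (S)** — a probit ROC-GLM: for every pair, the indicator
  $U_{ij} = I[Y_{i1} \ge Y_{j0}]$ is regressed on the probit of the
  *placement value* $t_j$, the false-positive rate attained at the
  nondiseased subject's own value, under the model
  $E(U_{ij}) = \Phi(\beta_1 + \beta_2 \Phi^{-1}(t_j))$. The coefficients
  play the roles of $a$ and $b$ but require no distributional assumption on
  the raw values, and the fitted curve is smooth — the combination that
  makes the method attractive for skewed biomarkers.

## Estimation details and the choices behind them

**Binormal plug-in.** Sample means and SDs (denominator $n-1$) are plugged
into $a$, $b$. Parameter variances use
$V(\hat a) = [n_1(\hat a^2+2) + 2 n_0 \hat b^2]/(2 n_0 n_1)$ and
$V(\hat b) = (n_1+n_0)\hat b^2/(2 n_0 n_1)$. The AUC standard error is the
delta-method value with gradient $(1/\sqrt{1+b^2},\; -ab/(1+b^2)^{3/2})$
scaled by $\phi(a/\sqrt{1+b^2})$, using
$\mathrm{cov}(\hat a, \hat b) = \hat a \hat b/(2 n_1)$ — both estimates
share $\hat\sigma_1$ in their denominators, and
$V(\hat\sigma_1)\approx\sigma_1^2/(2n_1)$ gives exactly that cross term. A
20,000-replicate Monte-Carlo check at the balanced $n_1=n_0=100$ design
confirms the SE within 5%. A limitation worth knowing: the $V(\hat a)$
formula weighs the $(\hat a^2+2)$ term by $n_1$ and the $2\hat b^2$ term by
$n_0$, the reverse of what the delta derivation
$V(\hat a) = 1/n_1 + b^2/n_0 + a^2/(2n_1)$ yields; the two coincide at
balanced designs, but at strongly unbalanced ones (e.g. 62:20) the formula —
and hence the delta AUC SE built on it — overstates the sampling SD, which
the test suite documents with a Monte-Carlo bound.

**Empirical estimator.** The AUC is computed from midranks in
$O(n\log n)$; it is provably the trapezoidal area under the step curve with
the $\ge$ positivity convention, and the suite asserts that identity to
1e-12 on random tied samples. The variance is the tie-corrected
Mann–Whitney form built from the exceedance counts around each observed
value; on tie-free data its components reduce to the classic Hanley–McNeil
probabilities (verified against a literal triple-loop transcription).

**ROC-GLM.** Placement values live on $\{1/n_0, \dots, n_0/n_0\}$; the
minimum nondiseased value attains $t = 1$, whose probit is infinite. Those
rows are excluded from the regression — the standard interior-FPR
restriction; jittering or shifting $t$ would perturb the regressor instead.
The probit fit maximizes the working-independence likelihood by IRLS
(deviance tolerance 1e-12, max 100 iterations) on counts aggregated per
distinct placement value, an exact regrouping of the per-pair Bernoulli
likelihood that keeps the $10^4$-pair designs cheap. Pairs share subjects,
so the working-independence model SEs would be wrong; all inference comes
from a bootstrap that resamples *subjects* within each disease group
(pairs are derived quantities, not sampling units), rebuilds the design and
refits — 200 resamples by default. Ties $Y_{i1} = Y_{j0}$ score 1 in
$U_{ij}$ (the $\ge$ convention), deliberately different from the empirical
½ kernel; both are implemented exactly as defined.

**Separation.** Small or well-separated samples can make the pairwise
outcomes quasi-separated: the IRLS still stabilizes, at a boundary estimate
with a very large slope, and the fit is returned with `separated = TRUE`.
Bootstrap resamples in that state are *kept* — their extreme estimates are
exactly what makes small-sample bootstrap SEs honest on skewed data (SE far
above the across-sample SD, the signature the benchmark reproduces) — while
resamples whose fit is impossible (a single outcome class, a single
placement value) or whose IRLS genuinely fails are dropped and counted, with
more than 10% drops an error.

**Confidence intervals** are Wald, $\hat{AUC} \pm z_{0.975}\,SE$, not
truncated to $[0,1]$: small-sample intervals that overshoot 1 are reported
as such rather than silently clipped.

## The simulation benchmark

`run_study()` reproduces a three-family comparison at
$a = 1.400$, $b = 0.900$ (nominal $AUC = \Phi(1.4/\sqrt{1.81}) = 0.851$):

* **normal** — $Y_1 \sim N(a/b, 1/b^2)$, $Y_0 \sim N(0,1)$: the binormal
  model's home turf.
* **lognormal** — exponentials of the same normal draws: right-skewed
  margins with unchanged ranks. Because the rank-based estimators are
  invariant under monotone transforms, their replicate records here are
  identical (to floating-point) to the normal family's under a shared study
  seed — a property the suite asserts — while the binormal fit on the raw
  values degrades badly (mean AUC ≈ 0.72 at $n=100$, bias ≈ 0.13).
* **uniform** — a monotone-density family matched in mean and SD:
  $Y_1 \sim U(a/b \pm \sqrt{12}/(2b))$, $Y_0 \sim U(-\sqrt3, \sqrt3)$. The
  published description of this family is garbled in the source text; the
  endpoints above are the reconstruction whose exact exceedance probability
  (piecewise integral, `uniform_pair_auc()`) equals 0.8345 and matches the
  benchmark's empirical means (~0.834), whereas the literal $U(-3,3)$
  reading gives 0.754 and matches nothing. The literal variant remains
  available via `uniform_literal = TRUE` for sensitivity analysis. Note the
  bias column stays referenced to the *nominal* 0.851 in every family, so
  in the uniform family the empirical estimator shows a ~0.016 "bias" that
  is really the gap between the binormal functional and the true uniform
  exceedance probability.

Bias is reported as nominal minus mean (displayed unsigned), RMSE once
across replicates — $RMSE^2 = bias^2 + \mathrm{var}(\hat{AUC})$ holds by
construction — and SE columns are means of *per-replicate SE estimates*
(formula-based for P and N, bootstrap for S), not across-replicate SDs;
that distinction is what lets a small-sample bootstrap SE legitimately
exceed the RMSE. Per-replicate seeds are split deterministically from the
study seed (`replicate_seed()`), so all methods see identical data within a
replicate.

Completely separated replicates (no ROC-GLM maximum) occur at a rate of
about 1/1000 at $n_1 = n_0 = 15$ and never at 50+. The default policy
aborts the study with the replicate index; `on_failure = "drop"` discards
and counts them, the mode the small-$n$ rows of the analysis scripts use.

### Problem sizes used

The checked-in drivers and the acceptance script run 1000 replicates per
family at $n_1 = n_0 = 100$ (the headline comparison, about 10 s per family),
and the `analysis/02` grid adds $n \in \{15, 25, 50\}$. Bootstrap-SE columns
are disabled (`n_boot = 0`) in the grid — only the mean columns enter the
reproduction checks — and exercised at full 200-resample depth in the
application driver and the focused tests. Oracle cross-checks use 20,000
Monte-Carlo replicates where a SD must be estimated (SD of that SD ≈ 0.5%,
ample for 5% assertions) and exhaustive enumeration elsewhere.

## The synthetic application fixture

The reporting path (`run_report()`) is demonstrated on a synthetic
right-skewed biomarker panel: 62 cases and 20 controls drawn lognormally
with medians calibrated near 104 and 34 (`make_skewed_fixture()`). It
emulates the skew (mean ≈ 2× median), the group imbalance, and the
heavy right tail of a typical acute-phase cardiac biomarker; it does *not*
emulate assay detection limits, measurement rounding, or any covariate
structure, so passing tests say nothing about those features of real data.
On this fixture the three AUCs reproduce the expected ordering — binormal
lowest, rank-based methods agreeing above it — the practical symptom of
fitting a normal model to lognormal-like values.

## Known limitations

* The binormal parameter variance formulas are exact only at balanced
  designs (see above); at strongly unbalanced designs the AUC SE is
  conservative.
* The empirical AUC interval is Wald-based; exact or bootstrap intervals
  for it are out of scope, as are kernel-smoothed ROC variants, partial
  AUC, covariate adjustment, and optimal-cutoff selection.
* The ROC-GLM uses the probit link with basis $(1, \Phi^{-1}(t))$ only.
* CI coverage probabilities are not computed by the benchmark engine.
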