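# roctrio

Three estimators of the ROC curve and its area (AUC) for a continuous
diagnostic test, plus a Monte-Carlo engine that benchmarks them against each
other:

* **Parametric** — the binormal model `ROC(t) = Φ(a + b Φ⁻¹(t))` with
  `a = (μ₁−μ₀)/σ₁`, `b = σ₀/σ₁`, `AUC = Φ(a/√(1+b²))`, moment plug-in
  estimation, formula-based parameter variances and a delta-method AUC SE.
* **Nonparametric** — the empirical step curve and Mann–Whitney AUC
  (ties scored ½) with the tie-corrected Hanley–McNeil-type variance.
* **Semiparametric** — a probit ROC-GLM: pairwise indicators
  `U_ij = I[Y_i1 ≥ Y_j0]` regressed on the probit of placement values
  (`E(U) = Φ(β₁ + β₂Φ⁻¹(t))`), with stratified subject-level bootstrap SEs.
  Same smooth curve family as the binormal model, no normality assumption.

The package exists for the comparison the three make together: on normal
data all three agree; on skewed (lognormal) data the binormal fit collapses
while the two rank-based methods hold; on monotone (uniform) data the
binormal fit is surprisingly robust. `run_study()` quantifies all of this
with bias, SE, and RMSE tables; `run_report()` applies all three methods to
a user dataset at once.

Audience: biostatisticians and methodologists evaluating continuous
diagnostic markers, and anyone needing a smooth ROC curve from skewed
biomarker data without transforming it first.

## Worked example

A synthetic right-skewed biomarker panel (62 cases, 20 controls, lognormal,
medians calibrated near 104 and 34 — a stand-in for a typical acute-phase
cardiac marker):

```r
library(roctrio)
dataset <- make_skewed_fixture(n1 = 62, n0 = 20, seed = 2026)
run_report(dataset, n_boot = 200, seed = 2026)
```

```
ROC method report (n1:n0 = 62:20 )

Group descriptives:
   group  n    mean      sd median    min    max
    case 62 141.305 146.117 89.245 8.1459 700.98
 control 20  52.839  54.839 31.252 6.7191 229.74

Estimates:
         method     a  se_a     b  se_b   auc se_auc          ci
     Parametric 0.605 0.248 0.375 0.068 0.715  0.078 0.561–0.868
 Semiparametric 1.056 0.391 1.213 0.367 0.749  0.067 0.618–0.880
  Nonparametric     —     —     —     — 0.774  0.063 0.651–0.897
```

Reading it: both groups are heavily skewed (means roughly double the
medians), so the binormal fit on the raw values lands lowest (AUC 0.715),
while the two rank-based estimators agree above it (0.749 and 0.774) — the
classic symptom of a normality assumption failing. The semiparametric row
provides what the empirical one cannot: a smooth curve (exported by
`export_report()`) from which a unique cutoff can be read.

The benchmark itself:

```r
study <- run_study(scenario_spec("lognormal", n1 = 100, n0 = 100,
                                 n_reps = 1000, seed = 2026))
study$summary[, c("method", "mean_auc", "bias", "rmse")]
#   method  mean_auc         bias       rmse
# 1      P 0.7203221  0.130649985 0.13582628
# 2      S 0.8474995  0.003472652 0.02684568
# 3      N 0.8520078 -0.001035675 0.02654802
```

With the true smooth-model AUC at 0.851, the binormal estimator is biased by
0.13 on skewed data; the semiparametric and empirical estimators are not.

## The analysis workflow

Numbered drivers under `analysis/` re-run the package's full program and
write their tables under `results/`:

1. `analysis/01_closed_form_checks.R` — closed-form AUC and SE identities.
2. `analysis/02_simulation_study.R` — the three-family benchmark grid
   (n = 15, 25, 50, 100; 1000 replicates each), one TSV table per family.
3. `analysis/03_biomarker_application.R` — the three-method report and ROC
   curve coordinates for the synthetic skewed biomarker dataset.

```sh
Rscript analysis/01_closed_form_checks.R
Rscript analysis/02_simulation_study.R      # ~1 min
Rscript analysis/03_biomarker_application.R
```

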