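#!/usr/bin/env Rscript
# Applies all three ROC estimators to a right-skewed biomarker dataset of 62
# cases vs 20 controls. The values are a synthetic lognormal stand-in
# (make_skewed_fixture) calibrated to the skew of a cardiac-biomarker panel:
# group medians near 104 and 34 with means roughly double the medians.
# Writes the dataset, a method report (markdown + JSON) and the three ROC
# curves under results/application/.

suppressPackageStartupMessages(library(roctrio))

seed <- 2026
out <- "results/application"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dataset <- make_skewed_fixture(n1 = 62, n0 = 20, seed = seed)
write_labeled_csv(dataset, file.path(out, "synthetic_biomarker.csv"))

report <- run_report(dataset, n_boot = 200, seed = seed)
print(report)
export_report(report, out)

est <- report$estimates
cat("\nReading the report:\n")
cat(sprintf(
  " - the binormal fit on the raw skewed values lands at AUC %.3f,\n",
  est$auc[est$method == "P"]))
cat(sprintf(
  " - while the rank-based semiparametric (%.3f) and empirical (%.3f)\n",
  est$auc[est$method == "S"], est$auc[est$method == "N"]))
cat("   estimators agree with each other: the familiar signature of a\n")
cat("   normality assumption failing on lognormal-like data. The smooth\n")
cat("   semiparametric curve (curve_semiparametric.tsv) is the one a\n")
cat("   practitioner would read a cutoff from.\n")
cat("\nOutputs in", out, "\n")
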