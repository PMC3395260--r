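#!/usr/bin/env Rscript
# Monte-Carlo benchmark of the three ROC estimators (parametric binormal P,
# semiparametric probit ROC-GLM S, empirical Mann-Whitney N) under the
# normal, lognormal and uniform scenario families at group sizes 15, 25, 50
# and 100 with 1000 replicates each. Writes one formatted table per family
# (results/table_<family>.tsv) plus a machine-readable JSON of all summaries.
#
# Bootstrap SEs for the S rows are expensive (one refit per resample per
# replicate); set n_boot > 0 below to fill those columns. With the default
# n_boot = 0 the S rows report point-estimate means only, which is all the
# mean/bias/RMSE comparison needs.

suppressPackageStartupMessages(library(roctrio))

seed <- 2026
n_reps <- 1000
n_boot <- 0
sizes <- c(15, 25, 50, 100)
families <- c("normal", "lognormal", "uniform")

dir.create("results", showWarnings = FALSE)
all_summaries <- list()

for (family in families) {
  blocks <- list()
  for (n in sizes) {
    spec <- scenario_spec(family, n1 = n, n0 = n, n_reps = n_reps, seed = seed)
    study <- run_study(spec, n_boot = n_boot, on_failure = "drop")
    if (study$n_failed > 0) {
      cat(sprintf("%-9s n=%3d  NOTE: %d separated replicate(s) dropped\n",
                  family, n, study$n_failed))
    }
    summ <- study$summary
    summ$n1 <- n
    summ$n0 <- n
    blocks[[as.character(n)]] <- summ
    cat(sprintf("%-9s n=%3d  P %.3f  S %.3f  N %.3f (mean AUC)\n", family, n,
                summ$mean_auc[summ$method == "P"],
                summ$mean_auc[summ$method == "S"],
                summ$mean_auc[summ$method == "N"]))
  }
  stacked <- do.call(rbind, blocks)
  all_summaries[[family]] <- stacked
  tab <- cbind(n1_n0 = paste0(stacked$n1, ":", stacked$n0),
               render_table(stacked))
  utils::write.table(tab, file.path("results", paste0("table_", family, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

jsonlite::write_json(all_summaries, "results/simulation_summaries.json",
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")

cat("\nHeadline patterns:\n")
ln100 <- all_summaries$lognormal
p100 <- ln100[ln100$n1 == 100 & ln100$method == "P", ]
s100 <- ln100[ln100$n1 == 100 & ln100$method == "S", ]
cat(sprintf(" - skewed data break the binormal fit: mean AUC %.3f (bias %.3f)\n",
            p100$mean_auc, p100$bias))
cat(sprintf(" - the rank-based ROC-GLM stays close to the truth: %.3f (bias %.3f)\n",
            s100$mean_auc, s100$bias))
un <- all_summaries$uniform
cat(sprintf(" - uniform data: nonparametric mean AUC %.3f tracks the exact exceedance %.4f,\n",
            un[un$n1 == 100 & un$method == "N", "mean_auc"],
            scenario_true_auc(scenario_spec("uniform", n1 = 2, n0 = 2))))
cat("   while bias columns are judged against the smooth-model nominal 0.851.\n")
cat("\nTables written to results/table_{normal,lognormal,uniform}.tsv\n")
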