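#!/usr/bin/env Rscript
# Stage 4 — statistics.
#
# Assembles the cohort table (scores + derived transduced connection-area
# fractions) and runs the headline battery: age-adjusted partial Spearman
# of the 6M motor score against the prefrontal (and other motor-system)
# transduced fractions, one-sample t tests of the fractions against 0%
# with Holm adjustment, and paired t tests of AIMS across timepoints.

suppressPackageStartupMessages(library(putaparc))

cfg <- validate_config(list(
  output_dir = "results/run",
  master_seed = 20260927,
  n_patients = 8,
  stages = list(simulate = FALSE, petquant = FALSE, parcellate = FALSE,
                analyze = TRUE)
))
run_pipeline(cfg)

res <- read.csv("results/run/results.csv")
sp <- res[res$test == "partial_spearman", c("unit", "n", "statistic", "p")]
cat("age-adjusted partial Spearman, 6M motor score vs transduced fraction:\n")
print(sp, row.names = FALSE, digits = 3)
cat("\nfull results: results/run/results.csv\n")
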