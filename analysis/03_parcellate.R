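#!/usr/bin/env Rscript
# Stage 3 — connectivity-based parcellation.
#
# Winner-take-all classification of every putamen voxel from its streamline
# counts toward the cortical targets, volume fractions per target summed
# into the seven cortical networks and the structural regions
# (PFC/PMC/SMA/M1), and the transduced variants using the pairing scheme:
# baseline parcellation masked by the 6M supra-max area, 2Y parcellation
# masked by the 2Y area.

suppressPackageStartupMessages(library(putaparc))

cfg <- validate_config(list(
  output_dir = "results/run",
  master_seed = 20260927,
  n_patients = 8,
  stages = list(simulate = FALSE, petquant = FALSE, parcellate = TRUE,
                analyze = FALSE)
))
run_pipeline(cfg)

prof <- read.csv("results/run/profiles.csv")
tr <- prof[prof$flag == "transduced" & prof$timepoint == "6M" &
             prof$level == "region", ]
agg <- aggregate(percent ~ unit, tr, mean)
cat("mean transduced connection-area fraction at 6M by structural region:\n")
print(agg[order(-agg$percent), ], row.names = FALSE)
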