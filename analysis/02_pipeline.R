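#!/usr/bin/env Rscript
# Step 2 — run the full detection pipeline over the simulated trial ledger.
#
# Reads the ledger written by 01_simulate.R and processes every trial with
# the default configuration: beat detection + arrest metrics + AV delay for
# cardiac trials, bout detection + trial classification for tail trials.
# Outputs land in results/pipeline/ with the config hash stamped in each CSV.

library(optophysio)

ledger <- read.csv("results/tables/trial_ledger.csv")
cfg <- default_config()
out <- run_pipeline(ledger, cfg, "results/pipeline")

cat(sprintf(
  "cardiac: %d trials, %d ok, %d arrested\n",
  nrow(out$cardiac), sum(out$cardiac$status == "ok"),
  sum(out$cardiac$arrested, na.rm = TRUE)
))
cat(sprintf(
  "locomotion: %d trials, %d induced, %d pre-stimulus-active\n",
  nrow(out$locomotion), sum(out$locomotion$induced, na.rm = TRUE),
  sum(out$locomotion$pre_stimulus_active, na.rm = TRUE)
))
cat("config hash:", config_hash(cfg), "\n")
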