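#!/usr/bin/env Rscript
# Step 1 — simulate the study's cohorts with known ground truth.
#
# Three cardiac regimes (green-activated/slow-adapting, blue-activated/
# faster-adapting, and violet-on/blue-off switchable), each 4 larvae x 6
# one-second pulse trials at 0.5 mW/mm^2, plus a 12-larva x 6-trial
# locomotion cohort. Traces are written as CSV under results/data/ together
# with a trial ledger and the planted ground truth, so the later steps can
# run the pipeline exactly as they would on exported video measurements.

library(optophysio)

seed <- 20260926
out_data <- "results/data"
out_tab <- "results/tables"
dir.create(out_data, recursive = TRUE, showWarnings = FALSE)
dir.create(out_tab, recursive = TRUE, showWarnings = FALSE)

regimes <- c("mosopn3_like", "puftmt_like", "lampp_like")
ledger <- NULL
truth_all <- NULL

for (r in seq_along(regimes)) {
  reg <- regimes[r]
  co <- simulate_heart_cohort(reg, n_larvae = 4, n_trials = 6, seed = seed + r)
  for (i in seq_along(co$trials)) {
    tt <- co$truth[i, ]
    stem <- sprintf("%s_l%02d_t%02d", reg, tt$larva_id, tt$trial)
    a_path <- file.path(out_data, paste0(stem, "_atrium.csv"))
    v_path <- file.path(out_data, paste0(stem, "_ventricle.csv"))
    write_trace_csv(co$trials[[i]]$atrium, a_path)
    write_trace_csv(co$trials[[i]]$ventricle, v_path)
    ledger <- rbind(ledger, data.frame(
      larva_id = paste0(reg, "_", tt$larva_id), trial = tt$trial,
      kind = "heart", stim_onset_s = tt$stim_onset_s,
      atrium_csv = a_path, ventricle_csv = v_path, tail_csv = NA
    ))
  }
  truth_all <- rbind(truth_all, cbind(regime = reg, co$truth))
}

loc <- simulate_locomotion_cohort(n_larvae = 12, n_trials = 6, seed = seed + 10)
for (i in seq_along(loc$trials)) {
  tt <- loc$truth[i, ]
  t_path <- file.path(
    out_data, sprintf("tail_l%02d_t%02d.csv", tt$larva_id, tt$trial)
  )
  write_trace_csv(loc$trials[[i]]$tail, t_path)
  ledger <- rbind(ledger, data.frame(
    larva_id = paste0("loc_", tt$larva_id), trial = tt$trial,
    kind = "tail", stim_onset_s = tt$stim_onset_s,
    atrium_csv = NA, ventricle_csv = NA, tail_csv = t_path
  ))
}

write.csv(ledger, file.path(out_tab, "trial_ledger.csv"), row.names = FALSE)
write.csv(truth_all, file.path(out_tab, "ground_truth_cardiac.csv"),
  row.names = FALSE
)
write.csv(loc$truth, file.path(out_tab, "ground_truth_locomotion.csv"),
  row.names = FALSE
)

cat(sprintf(
  "simulated %d cardiac trials (%d regimes) and %d tail trials\n",
  sum(ledger$kind == "heart"), length(regimes), sum(ledger$kind == "tail")
))
cat(sprintf(
  "planted cardiac arrest in %.0f%% of trials; mean latency %.3f s, mean resumption %.2f s\n",
  100 * mean(truth_all$arrested),
  mean(truth_all$latency_to_arrest_s, na.rm = TRUE),
  mean(truth_all$time_to_resumption_s, na.rm = TRUE)
))
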