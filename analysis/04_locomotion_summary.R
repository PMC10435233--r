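#!/usr/bin/env Rscript
# Step 4 — locomotion rates and metrics, with a control-group comparison.
#
# Per-larva locomotion rate, latency, duration and strength from the
# pipeline's tail results; a simulated non-expressing control cohort (the
# same assay, spontaneous induction only) is compared with the expressing
# cohort by Wilcoxon rank-sum, and trial 1 vs trial 6 is checked for
# habituation.

library(optophysio)

loc <- read_result_csv("results/pipeline/locomotion_results.csv")
loc$larva <- as.integer(sub("^loc_", "", loc$larva_id))

per_rate <- do.call(rbind, lapply(split(loc, loc$larva), function(d) {
  data.frame(larva_id = d$larva[1], rate = locomotion_rate(d))
}))
per_metrics <- per_larva_average(
  data.frame(
    larva_id = loc$larva,
    latency_s = ifelse(loc$induced, loc$latency_s, NA),
    duration_s = ifelse(loc$induced, loc$duration_s, NA),
    strength = ifelse(loc$induced, loc$strength, NA)
  ),
  metrics = c("latency_s", "duration_s", "strength")
)

gs <- rbind(
  group_summary(per_rate$rate, "locomotion_rate_pct")[1:4],
  group_summary(per_metrics$latency_s, "latency_s")[1:4],
  group_summary(per_metrics$duration_s, "duration_s")[1:4],
  group_summary(per_metrics$strength, "strength")[1:4]
)
write.csv(gs, "results/tables/locomotion_group_summary.csv", row.names = FALSE)
for (i in seq_len(nrow(gs))) {
  cat(sprintf(
    "%-20s %.4g +- %.3g (n=%d)\n", gs$group[i], gs$mean[i], gs$sem[i], gs$n[i]
  ))
}

# sibling-control cohort: same assay, only spontaneous movement
ctrl <- simulate_locomotion_cohort(
  n_larvae = 8, n_trials = 6, seed = 20260940,
  induced_prob = 0.15, latency_mean_s = 4, latency_sd_s = 2
)
ctrl_cls <- do.call(rbind, lapply(seq_along(ctrl$trials), function(i) {
  cbind(
    larva_id = ctrl$truth$larva_id[i],
    classify_trial(detect_bouts(ctrl$trials[[i]]$tail), 10)
  )
}))
ctrl_rate <- do.call(rbind, lapply(split(ctrl_cls, ctrl_cls$larva_id),
  function(d) data.frame(rate = locomotion_rate(d))
))
rs <- rank_sum_test(per_rate$rate, ctrl_rate$rate,
  label_a = "expressing", label_b = "control"
)
write.csv(rs, "results/tables/locomotion_ranksum.csv", row.names = FALSE)
cat(sprintf(
  "\nexpressing %.1f%% vs control %.1f%%: rank-sum p = %.3g (%s)\n",
  mean(per_rate$rate), mean(ctrl_rate$rate), rs$p_value, rs$method
))

# habituation check: trial 1 vs trial 6 induction
loc$induced_num <- as.numeric(loc$induced)
te <- trial_effect_table(
  data.frame(larva_id = loc$larva, trial = loc$trial, induced = loc$induced_num),
  metric = "induced"
)
write.csv(te$pairs, "results/tables/trial1_vs_trial6.csv", row.names = FALSE)
cat(sprintf(
  "trial 1 vs 6 induction: median paired difference %.2f, p = %s\n",
  median(te$pairs$difference),
  format(te$test$p_value, digits = 3)
))
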