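test_that("noise-only traces produce no bouts", {
  tr <- simulate_tail_trial(tail_sim_params(noise_sd = 0.005), 5, 10, seed = 2)
  bouts <- detect_bouts(tr$tail)
  expect_equal(nrow(bouts), 0)
})

test_that("a planted bout is recovered within frames and percent bounds", {
  tp <- tail_sim_params(13.2, 4.4, 0.3)
  tr <- simulate_tail_trial(tp, 10, 25, seed = 6)
  bouts <- detect_bouts(tr$tail)
  expect_equal(nrow(bouts), 1)
  expect_lte(abs(bouts$start_s - 13.2), 2 / 67)
  expect_lte(abs(bouts$end_s - 17.6), 4 / 67)
  expect_lte(abs(bouts$peak_displacement - 0.3) / 0.3, 0.1)
})

test_that("bouts closer than the merge gap are fused", {
  t <- seq(0, 10, by = 1 / 67)
  v <- numeric(length(t))
  v[t >= 2 & t <= 3] <- 0.2 * sin(2 * pi * 20 * (t[t >= 2 & t <= 3] - 2))
  v[t >= 3.05 & t <= 4] <- 0.2 * sin(2 * pi * 20 * (t[t >= 3.05 & t <= 4] - 3.05))
  bouts <- detect_bouts(time_series(t, v), min_gap_s = 0.1)
  expect_equal(nrow(bouts), 1)
  expect_error(detect_bouts(time_series(t, v), threshold = 0), "threshold")
})

test_that("trial classification matches the rules on constructed bout lists", {
  b <- data.frame(start_s = 13.2, end_s = 17.6, peak_displacement = 0.3)
  cls <- classify_trial(b, 10)
  expect_true(cls$induced)
  expect_false(cls$pre_stimulus_active)
  expect_equal(cls$latency_s, 3.2)
  expect_equal(cls$duration_s, 4.4)
  expect_equal(cls$strength, 0.3)

  # 8 s induction bound: a bout at onset + 9 s is not induced
  late <- data.frame(start_s = 19, end_s = 20, peak_displacement = 0.2)
  expect_false(classify_trial(late, 10)$induced)

  # a pre-stimulus bout flags the trial
  pre <- data.frame(start_s = 9, end_s = 9.5, peak_displacement = 0.2)
  expect_true(classify_trial(pre, 10)$pre_stimulus_active)
})

test_that("classification is pure and idempotent", {
  withr::with_seed(14, b <- random_bouts(4))
  r1 <- classify_trial(b, 10)
  r2 <- classify_trial(b, 10)
  expect_identical(r1, r2)
})

test_that("locomotion rate follows the exclusion arithmetic", {
  # onsets {0.5, none, 2, 9, pre-stim, 1} relative to stimulus: 3 of 5 counted
  trials <- data.frame(
    induced = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    pre_stimulus_active = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  expect_equal(locomotion_rate(trials), 60)
  expect_equal(locomotion_rate(data.frame(
    induced = rep(TRUE, 6), pre_stimulus_active = FALSE
  )), 100)
  expect_equal(locomotion_rate(data.frame(
    induced = rep(FALSE, 6), pre_stimulus_active = FALSE
  )), 0)
  expect_error(locomotion_rate(data.frame(
    induced = TRUE, pre_stimulus_active = TRUE
  )), "excluded")
})

test_that("locomotion rate is invariant under trial reordering", {
  withr::with_seed(9, {
    trials <- data.frame(
      induced = sample(c(TRUE, FALSE), 20, replace = TRUE),
      pre_stimulus_active = sample(c(TRUE, FALSE), 20, TRUE, prob = c(.2, .8))
    )
    trials$pre_stimulus_active[1] <- FALSE # keep at least one counted
    r <- locomotion_rate(trials)
    expect_gte(r, 0)
    expect_lte(r, 100)
    expect_equal(locomotion_rate(trials[sample(20), ]), r)
  })
})

test_that("inhibition trials are those whose ongoing bout stops within 1 s", {
  mk <- function(end) list(
    bouts = data.frame(start_s = 9, end_s = end, peak_displacement = 0.2),
    stim_onset_s = 10
  )
  expect_equal(inhibition_rate(list(mk(10.4), mk(12))), 50)
  expect_equal(inhibition_rate(list(
    mk(10.4), mk(10.9), mk(10.2), mk(12), mk(13), mk(11.5)
  )), 50)
  expect_warning(
    r <- inhibition_rate(list(
      mk(10.4),
      list(
        bouts = data.frame(
          start_s = 12, end_s = 13,
          peak_displacement = 0.1
        ),
        stim_onset_s = 10
      )
    )),
    "excluded"
  )
  expect_equal(r, 100)
})

test_that("classification agrees with the brute-force oracle on random cases", {
  withr::with_seed(123, {
    for (i in 1:200) {
      b <- random_bouts(sample(0:5, 1))
      onset <- runif(1, 2, 20)
      got <- classify_trial(b, onset)
      want <- oracle_classify(b, onset)
      expect_identical(got$induced, want$induced)
      expect_identical(got$pre_stimulus_active, want$pre)
      expect_equal(got$latency_s, want$latency)
      expect_equal(got$duration_s, want$duration)
      expect_equal(got$strength, want$strength)
    }
  })
})

test_that("cohort-level parameter recovery meets the frame-level bounds", {
  co <- simulate_locomotion_cohort(n_larvae = 6, n_trials = 4, seed = 31)
  err <- t(mapply(function(tr, i) {
    b <- detect_bouts(tr$tail)
    cls <- classify_trial(b, 10)
    gt <- co$truth[i, ]
    c(
      lat = abs(cls$latency_s - gt$latency_s),
      dur = abs(cls$duration_s - gt$duration_s),
      str = abs(cls$strength - gt$strength) / gt$strength
    )
  }, co$trials, seq_along(co$trials)))
  ok <- co$truth$induced & !co$truth$pre_stimulus_active
  expect_lte(stats::median(err[ok, "lat"], na.rm = TRUE), 2 / 67)
  expect_lte(stats::median(err[ok, "dur"], na.rm = TRUE), 4 / 67)
  expect_lte(stats::median(err[ok, "str"], na.rm = TRUE), 0.05)
})
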