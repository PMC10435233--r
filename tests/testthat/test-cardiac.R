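test_that("beat detection recovers a noiseless pulse train exactly", {
  tr <- simulate_heart_trial(
    heart_sim_params(noise_sd = 0), zero_activity(20), 20,
    seed = 1
  )
  beats <- detect_beats(tr$atrium)
  planted <- tr$ground_truth$beat_times_s
  expect_length(beats$beat_times_s, 50)
  expect_lte(max(abs(beats$beat_times_s - planted)), 1 / 67 + 1e-9)
})

test_that("a constant trace yields zero beats, not an error", {
  t <- seq(0, 10, by = 1 / 67)
  beats <- detect_beats(time_series(t, rep(3, length(t))))
  expect_length(beats$beat_times_s, 0)
})

test_that("beat detection input contracts hold", {
  t <- seq(0, 10, by = 1 / 67)
  tr <- time_series(t, sin(t))
  expect_error(detect_beats(tr, min_ibi_s = 0), "min_ibi_s")
  expect_error(detect_beats(time_series(seq(0, 1, 0.1), rnorm(11))), "2 s")
})

test_that("relative frequency self-normalizes, zeroes in arrest, halves on a rate step", {
  # constant train
  beats <- beat_series(seq(0.4, 40, by = 0.4))
  fr <- relative_hb_frequency(beats, baseline_window = c(0, 5),
    record_span = c(0, 40))
  quant <- (1 / (2 * 0.5)) / attr(fr, "baseline_freq_hz")
  inner <- fr$rel_freq[!is.na(fr$rel_freq)]
  expect_true(all(abs(inner - 1) <= quant + 1e-9))

  # full arrest: interior of the gap is exactly zero
  bt <- c(seq(0.4, 10, by = 0.4), seq(20, 30, by = 0.4))
  fr2 <- relative_hb_frequency(beat_series(bt), baseline_window = c(0, 5),
    record_span = c(0, 30))
  gap <- fr2$t > 10.5 & fr2$t < 19.5
  expect_true(all(fr2$rel_freq[gap] == 0))

  # planted step to half rate
  bt3 <- c(seq(0.4, 20, by = 0.4), seq(20.8, 40, by = 0.8))
  fr3 <- relative_hb_frequency(beat_series(bt3), baseline_window = c(0, 10),
    record_span = c(0, 40))
  plateau <- fr3$rel_freq[fr3$t >= 25 & fr3$t <= 35]
  quant3 <- (1 / (2 * 0.5)) / attr(fr3, "baseline_freq_hz")
  expect_true(all(abs(plateau - 0.5) <= quant3 + 1e-9))
  expect_equal(mean(plateau), 0.5, tolerance = 0.05)
})

test_that("relative frequency marks out-of-record windows NA and validates input", {
  beats <- beat_series(seq(0.4, 10, by = 0.4))
  fr <- relative_hb_frequency(beats, c(0, 5), record_span = c(0, 10))
  expect_true(is.na(fr$rel_freq[1]))
  expect_error(
    relative_hb_frequency(beat_series(c(1, 9)), c(2, 3)),
    "at least 2 beats"
  )
})

test_that("arrest detection recovers planted latency and resumption", {
  # noiseless: within one frame
  tr <- arrest_trial(seed = 5, noise_sd = 0)
  gt <- tr$ground_truth$arrest
  det <- detect_arrest(detect_beats(tr$atrium), 10, record_end_s = 40)
  expect_true(det$arrested)
  expect_lte(abs(det$latency_to_arrest_s - gt$latency_to_arrest_s), 1 / 67 + 1e-9)
  expect_lte(
    abs(det$time_to_resumption_s - gt$time_to_resumption_s),
    1 / 67 + 1e-9
  )

  # 10% amplitude noise: within 50 ms, over seeds
  withr::with_seed(77, {
    for (s in 1:15) {
      tr <- arrest_trial(seed = s, noise_sd = 0.1, phase0 = runif(1))
      gt <- tr$ground_truth$arrest
      det <- detect_arrest(detect_beats(tr$atrium), 10, record_end_s = 40)
      expect_true(det$arrested)
      expect_lte(abs(det$latency_to_arrest_s - gt$latency_to_arrest_s), 0.05)
      expect_lte(
        abs(det$time_to_resumption_s - gt$time_to_resumption_s), 0.05
      )
    }
  })
})

test_that("an unchanged rate is not classified as arrest", {
  tr <- simulate_heart_trial(heart_sim_params(), zero_activity(30), 30,
    seed = 2, stim_onset_s = 10
  )
  det <- detect_arrest(detect_beats(tr$atrium), 10, record_end_s = 30)
  expect_false(det$arrested)
})

test_that("arrest detection requires pre-stimulus beats", {
  beats <- beat_series(seq(11, 20, by = 0.4))
  expect_error(detect_arrest(beats, 10), "pre-stimulus")
})

test_that("arrest-time ratios follow their defining arithmetic", {
  mk <- function(durs) {
    data.frame(arrested = durs > 0, arrest_duration_s = ifelse(durs > 0, durs, NA))
  }
  expect_equal(arrest_time_ratio(mk(c(10, 5, 0))), c(1, 0.5, 0))
  expect_equal(arrest_time_ratio(mk(c(4, 4, 4))), c(1, 1, 1))
  expect_error(arrest_time_ratio(mk(c(0, 5))), "trial 1")
})

test_that("av matching follows the nearest-subsequent rule with 0.5 s exclusion", {
  # hand-enumerated example: third pair exceeds the bound
  av <- av_delay(
    beat_series(c(1.0, 2.0, 3.0)),
    beat_series(c(1.1, 2.1, 3.6))
  )
  expect_equal(av$delay_s, c(0.1, 0.1))
  expect_equal(attr(av, "n_excluded"), 1L)

  # noiseless planted delay recovered on every retained pair
  tr <- simulate_heart_trial(
    heart_sim_params(noise_sd = 0, av_delay_s = 0.08),
    zero_activity(20), 20,
    seed = 1
  )
  av2 <- av_delay(detect_beats(tr$atrium), detect_beats(tr$ventricle))
  expect_gt(nrow(av2), 40)
  expect_true(all(abs(av2$delay_s - 0.08) <= 1 / 67 + 1e-9))
  expect_true(all(av2$delay_s > 0 & av2$delay_s <= 0.5))

  # no ventricular matches
  av3 <- av_delay(beat_series(c(1, 2)), beat_series(c(0.5)))
  expect_equal(nrow(av3), 0)

  # matching is order-preserving (non-crossing)
  withr::with_seed(8, {
    at <- sort(runif(30, 0, 30))
    vt <- sort(runif(40, 0, 30))
    av4 <- av_delay(beat_series(at), beat_series(vt))
    if (nrow(av4) > 1) {
      expect_true(all(diff(av4$atrial_peak_s) > 0))
      expect_true(all(diff(av4$ventricular_peak_s) > 0))
    }
    expect_true(all(av4$delay_s <= 0.5))
  })
})

test_that("per-larva arrest rates are trial fractions", {
  trials <- data.frame(
    larva_id = rep(1:2, each = 6),
    arrested = c(rep(TRUE, 6), rep(FALSE, 6))
  )
  r <- cardiac_arrest_rate(trials)
  expect_equal(r$arrest_rate, c(1, 0))
  expect_error(
    cardiac_arrest_rate(data.frame(larva_id = 1, arrested = NA)),
    "no valid trials"
  )
})

test_that("a simulated cohort at full irradiance arrests in every trial", {
  co <- simulate_heart_cohort("mosopn3_like",
    n_larvae = 2, n_trials = 3,
    seed = 21, duration_s = 25
  )
  res <- analyze_heart_cohort(co)
  rates <- cardiac_arrest_rate(
    data.frame(larva_id = res$larva_id, arrested = res$det_arrested)
  )
  expect_true(all(rates$arrest_rate == 1))
})
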