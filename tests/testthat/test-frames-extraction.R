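test_that("roi luminosity of uniform frames is the uniform value", {
  frames <- array(7, dim = c(40, 40, 5)) / 10 # keep within [0,1]
  st <- frame_stack(frames, fps = 10)
  roi <- matrix(TRUE, 40, 40)
  ts <- extract_roi_luminosity(st, roi)
  expect_true(all(ts$v == 0.7))
  expect_equal(ts$t, (0:4) / 10)
})

test_that("a one-pixel roi returns that pixel's series", {
  withr::with_seed(1, frames <- array(runif(30 * 30 * 8), dim = c(30, 30, 8)))
  st <- frame_stack(frames, fps = 5)
  roi <- matrix(FALSE, 30, 30)
  roi[12, 20] <- TRUE
  ts <- extract_roi_luminosity(st, roi)
  expect_equal(ts$v, frames[12, 20, ])
})

test_that("roi extraction is linear in pixel intensities", {
  withr::with_seed(2, frames <- array(runif(32 * 32 * 6), dim = c(32, 32, 6)))
  roi <- matrix(FALSE, 32, 32)
  roi[5:20, 8:25] <- TRUE
  v1 <- extract_roi_luminosity(frame_stack(frames, 10), roi)$v
  v2 <- extract_roi_luminosity(frame_stack(frames * 0.37, 10), roi)$v
  expect_equal(v2, 0.37 * v1, tolerance = 1e-12)
})

test_that("rendered frames round-trip through roi extraction", {
  tr <- simulate_heart_trial(
    heart_sim_params(noise_sd = 0), zero_activity(10), 10,
    seed = 1
  )
  rf <- render_heart_frames(tr$atrium, tr$ventricle, 64, seed = 1)
  expect_equal(dim(rf$stack$frames)[3], length(tr$atrium$t))
  lum_a <- extract_roi_luminosity(rf$stack, rf$rois$atrium)
  lum_v <- extract_roi_luminosity(rf$stack, rf$rois$ventricle)
  expect_gt(stats::cor(lum_a$v, tr$atrium$v), 0.99)
  expect_gt(stats::cor(lum_v$v, tr$ventricle$v), 0.99)
  # the beat-detection oracle sees the planted beats through the pixels
  beats <- detect_beats(lum_a)
  expect_equal(
    length(beats$beat_times_s),
    length(tr$ground_truth$beat_times_s)
  )
})

test_that("constant traces render identical frames", {
  t <- seq(0, 1, by = 0.1)
  ts <- time_series(t, rep(5, length(t)))
  rf <- render_heart_frames(ts, ts, 48, seed = 1)
  for (f in 2:dim(rf$stack$frames)[3]) {
    expect_identical(rf$stack$frames[, , f], rf$stack$frames[, , 1])
  }
})

test_that("polygon rois rasterize to the expected pixels", {
  # half-integer vertices keep pixel centers strictly inside or outside
  m <- roi_from_polygon(c(2.5, 10.5, 10.5, 2.5), c(3.5, 3.5, 8.5, 8.5),
    dim = c(16, 16)
  )
  expect_true(m[5, 5])
  expect_false(m[12, 12])
  expect_equal(sum(m), sum(outer(1:16, 1:16, function(r, c) {
    r > 3.5 & r < 8.5 & c > 2.5 & c < 10.5
  })))
})

test_that("dff conventions reproduce their defining identities", {
  t <- seq(0, 20, by = 0.2)
  # constant trace: dff identically zero
  f_const <- time_series(t, rep(50, length(t)))
  d0 <- compute_dff(f_const, "stim_onset", stim = 5)
  expect_true(all(d0$dff == 0))
  expect_equal(attr(d0, "F0"), 50)

  # doubling from baseline gives dff = 1 at that sample
  v <- rep(50, length(t))
  v[t >= 10 & t < 11] <- 100
  d1 <- compute_dff(time_series(t, v), "stim_onset", stim = 5)
  expect_equal(max(d1$dff), 1)
  # the baseline sample itself is exactly 0
  expect_equal(d1$dff[which.min(abs(t - 5))], 0)

  # pre-stimulus and steady-state baselines
  d2 <- compute_dff(time_series(t, v), "pre_stimulus",
    stim = 5,
    baseline_window_s = 2
  )
  expect_equal(attr(d2, "F0"), 50)
  d3 <- compute_dff(time_series(t, v), "steady_state",
    steady_window = c(15, 20)
  )
  expect_equal(attr(d3, "F0"), 50)
  expect_error(compute_dff(time_series(t, v), "steady_state"), "steady_window")
  expect_error(
    compute_dff(time_series(t, v - 50), "stim_onset", stim = 5),
    "F0"
  )
})

test_that("synthetic arrest trials yield negative dff during arrest", {
  reg <- opsin_regime("mosopn3_like")
  a <- simulate_photostate(
    reg$photostate, std_pulse(10, reg$stim_wavelength_nm), 40, 1 / 9
  )
  g <- simulate_gcamp_trial(100, 5, a, heart_sim_params(), 40, seed = 2)
  d <- compute_dff(g$fluor, "stim_onset", stim = 10)
  expect_lt(min(d$dff), -0.05)
})

test_that("heart area ratio tracks a planted area step within 2 percent", {
  tr <- simulate_heart_trial(
    heart_sim_params(noise_sd = 0), zero_activity(6), 6,
    seed = 1
  )
  n <- length(tr$atrium$t)
  scale <- c(rep(1, n %/% 2), rep(1.1, n - n %/% 2))
  rf <- render_heart_frames(tr$atrium, tr$ventricle, 96,
    seed = 1,
    area_scale = scale
  )
  ar <- measure_heart_area(rf$stack, t0_arrest_s = 0.5)
  expect_equal(ar$v[which.min(abs(ar$t))], 1) # exactly 1 at the reference
  late <- mean(ar$v[seq(n - 50, n)])
  expect_equal(late, 1.10, tolerance = 0.02)
})

test_that("a shrinking heart yields ratios bounded by 1", {
  t <- seq(0, 3, by = 0.1)
  ts <- time_series(t, rep(5, length(t)))
  scale <- seq(1, 0.7, length.out = length(t))
  rf <- render_heart_frames(ts, ts, 96, seed = 1, area_scale = scale)
  ar <- measure_heart_area(rf$stack, t0_arrest_s = 0, smooth_frames = 1)
  expect_true(all(ar$v <= 1 + 1e-9))
  expect_lt(ar$v[length(ar$v)], 0.8)
})

test_that("degenerate extraction inputs are rejected", {
  st <- frame_stack(array(0.5, dim = c(32, 32, 3)), fps = 10)
  expect_error(extract_roi_luminosity(st, matrix(FALSE, 32, 32)), "empty")
  expect_error(extract_roi_luminosity(st, matrix(TRUE, 16, 16)), "dimensions")
  expect_error(measure_heart_area(st, t0_arrest_s = 99), "within")
})
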