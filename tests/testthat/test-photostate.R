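test_that("no light means no activation", {
  p <- photostate_params(k_act = 3, k_rev = 1, k_adapt = 0.2)
  a <- simulate_photostate(p, darkness(), duration_s = 10, dt_s = 0.05)
  expect_true(all(a$v == 0))
})

test_that("integrator matches the closed-form rise under constant light", {
  # pure activation: a(t) = 1 - exp(-k_act * sigma * I * t)
  p <- photostate_params(
    k_act = 2, k_rev = 0, k_adapt = 0,
    act_peak_nm = 520, act_width_nm = 50
  )
  irr <- 0.8
  lam <- 470
  sch <- light_schedule(0, 10, lam, irr)
  a <- simulate_photostate(p, sch, duration_s = 10, dt_s = 1 / 67)
  k <- 2 * spectral_efficiency(470, 520, 50) * irr
  ref <- 1 - exp(-k * a$t)
  rel_err <- abs(a$v - ref) / pmax(ref, 1e-12)
  expect_lt(max(rel_err[-1]), 1e-6)
})

test_that("constant light converges to the analytic two-state equilibrium", {
  withr::with_seed(101, {
    for (i in 1:20) {
      p <- photostate_params(
        k_act = runif(1, 0.2, 5), k_rev = runif(1, 0, 5),
        k_adapt = runif(1, 0, 1),
        act_peak_nm = runif(1, 380, 650), act_width_nm = runif(1, 20, 80),
        rev_peak_nm = runif(1, 380, 650), rev_width_nm = runif(1, 20, 80)
      )
      lam <- runif(1, 380, 650)
      irr <- runif(1, 0.05, 1)
      on <- p$k_act * spectral_efficiency(lam, p$act_peak_nm, p$act_width_nm) * irr
      off <- p$k_rev * spectral_efficiency(lam, p$rev_peak_nm, p$rev_width_nm) *
        irr + p$k_adapt
      dur <- 30 / max(on + off, 0.3) # several equilibration time constants
      a <- simulate_photostate(
        p, light_schedule(0, dur, lam, irr), dur, dur / 500
      )
      a_eq <- on / (on + off)
      ref <- a_eq * (1 - exp(-(on + off) * a$t))
      expect_lt(max(abs(a$v - ref)), 1e-9)
    }
  })
})

test_that("active fraction stays within [0, 1] for randomized schedules", {
  withr::with_seed(202, {
    for (i in 1:25) {
      p <- photostate_params(
        k_act = runif(1, 0, 10), k_rev = runif(1, 0, 10),
        k_adapt = runif(1, 0, 2)
      )
      n_seg <- sample(1:4, 1)
      bounds <- sort(runif(2 * n_seg, 0, 20))
      sch <- light_schedule(
        bounds[seq(1, 2 * n_seg, 2)], bounds[seq(2, 2 * n_seg, 2)],
        runif(n_seg, 350, 700), runif(n_seg, 0, 2)
      )
      a <- simulate_photostate(p, sch, 20, runif(1, 0.005, 0.1))
      expect_true(all(a$v >= 0 & a$v <= 1))
    }
  })
})

test_that("photoreversal accelerates decay monotonically in irradiance", {
  # reversal light outside the activation band: pure off-pathway
  p <- photostate_params(
    k_act = 3, k_rev = 4, k_adapt = 0.05,
    act_peak_nm = 405, act_width_nm = 25, rev_peak_nm = 560
  )
  terminal <- vapply(c(0, 0.1, 0.3, 0.6), function(irr) {
    segs <- if (irr > 0) {
      light_schedule(c(0, 2), c(1, 12), c(405, 560), c(0.5, irr))
    } else {
      light_schedule(0, 1, 405, 0.5)
    }
    a <- simulate_photostate(p, segs, 12, 0.02)
    a$v[length(a$v)]
  }, numeric(1))
  expect_true(all(diff(terminal) < 0))
})

test_that("a violet pulse then sustained blue light switches the opsin off", {
  # switchable regime: activation peaked at 405 nm, reversal near 470-520 nm
  reg <- opsin_regime("lampp_like")
  sch <- light_schedule(
    c(1, 2), c(2, 30), c(405, 470), c(0.5, 0.5)
  )
  a <- simulate_photostate(reg$photostate, sch, 30, 0.01)
  peak <- max(a$v[a$t <= 2.5])
  expect_lt(a$v[length(a$v)], 0.1 * peak)
})

test_that("invalid schedules and parameters are rejected", {
  p <- photostate_params(k_act = 1)
  expect_error(
    simulate_photostate(p, light_schedule(0, 30, 520, 0.5), 10, 0.01),
    "beyond"
  )
  expect_error(simulate_photostate(p, darkness(), 10, 0), "dt_s")
  expect_error(light_schedule(5, 4, 520, 0.5), "start_s < end_s")
  expect_error(light_schedule(0, 1, 520, -1), "irradiance")
  expect_error(light_schedule(0, 1, 900, 0.5), "wavelength")
  expect_error(light_schedule(c(0, 1), c(2, 3), c(520, 470), c(0.5, 0.5)),
    "overlap")
  expect_error(photostate_params(k_act = -1), "rates")
})
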