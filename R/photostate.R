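#' Light stimulation schedule
#'
#' A piecewise-constant illumination protocol: non-overlapping segments of
#' monochromatic light, each with a wavelength and an irradiance. Outside all
#' segments the preparation is in darkness.
#'
#' @param start_s,end_s Numeric vectors of segment start/end times (seconds).
#' @param wavelength_nm Wavelength per segment, in nanometers (350-700).
#' @param irradiance_mw_mm2 Irradiance per segment in mW/mm^2 (>= 0).
#' @return An object of class `"LightSchedule"` (a data.frame of segments).
#' @examples
#' # 1 s green pulse at 0.5 mW/mm^2 starting at t = 5 s
#' light_schedule(5, 6, 520, 0.5)
#' @export
light_schedule <- function(start_s = numeric(), end_s = numeric(),
                           wavelength_nm = numeric(),
                           irradiance_mw_mm2 = numeric()) {
  seg <- data.frame(
    start_s = as.numeric(start_s), end_s = as.numeric(end_s),
    wavelength_nm = as.numeric(wavelength_nm),
    irradiance_mw_mm2 = as.numeric(irradiance_mw_mm2)
  )
  if (nrow(seg) > 0) {
    if (any(seg$end_s <= seg$start_s)) {
      stop("each segment needs start_s < end_s", call. = FALSE)
    }
    if (any(seg$irradiance_mw_mm2 < 0)) {
      stop("irradiance must be >= 0", call. = FALSE)
    }
    if (any(seg$wavelength_nm < 350 | seg$wavelength_nm > 700)) {
      stop("wavelength must lie in [350, 700] nm", call. = FALSE)
    }
    seg <- seg[order(seg$start_s), , drop = FALSE]
    if (nrow(seg) > 1 &&
      any(seg$start_s[-1] < seg$end_s[-nrow(seg)] - 1e-12)) {
      stop("light schedule segments must not overlap", call. = FALSE)
    }
  }
  structure(seg, class = c("LightSchedule", "data.frame"))
}

#' Bistable opsin photostate parameters
#'
#' Kinetic constants of the two-state photocycle used by the simulator. The
#' opsin is either in its dark (inactive) state or in the active photoproduct
#' state; light converts dark to active (activation) and active back to dark
#' (photoreversal), and a light-independent adaptation pathway also returns
#' the active state to rest. Spectral efficiency of each photo-transition is
#' a unit-height Gaussian bump over wavelength.
#'
#' @param k_act Activation rate per (mW/mm^2) per second at the activation
#'   peak wavelength.
#' @param k_rev Photoreversal rate per (mW/mm^2) per second at the reversal
#'   peak wavelength.
#' @param k_adapt Light-independent inactivation (adaptation) rate, 1/s.
#' @param act_peak_nm,act_width_nm Center and Gaussian width (sd, nm) of the
#'   activation spectrum.
#' @param rev_peak_nm,rev_width_nm Center and width of the reversal spectrum.
#' @return An object of class `"PhotostateParams"`.
#' @export
photostate_params <- function(k_act, k_rev = 0, k_adapt = 0,
                              act_peak_nm = 520, act_width_nm = 50,
                              rev_peak_nm = 470, rev_width_nm = 50) {
  if (any(c(k_act, k_rev, k_adapt) < 0)) {
    stop("photostate rates must be >= 0", call. = FALSE)
  }
  if (act_width_nm <= 0 || rev_width_nm <= 0) {
    stop("spectral widths must be > 0", call. = FALSE)
  }
  structure(
    list(
      k_act = k_act, k_rev = k_rev, k_adapt = k_adapt,
      act_peak_nm = act_peak_nm, act_width_nm = act_width_nm,
      rev_peak_nm = rev_peak_nm, rev_width_nm = rev_width_nm
    ),
    class = "PhotostateParams"
  )
}

#' Spectral efficiency of a photo-transition
#'
#' Unit-height Gaussian bump, bounded in \[0, 1\].
#'
#' @param wavelength_nm Wavelength(s) in nm.
#' @param peak_nm Center of the bump.
#' @param width_nm Gaussian width (standard deviation, nm).
#' @return Efficiency in \[0, 1\].
#' @export
spectral_efficiency <- function(wavelength_nm, peak_nm, width_nm) {
  exp(-((wavelength_nm - peak_nm)^2) / (2 * width_nm^2))
}

# Per-segment first-order coefficients of da/dt = on*(1-a) - off*a.
photostate_rates <- function(params, wavelength_nm, irradiance) {
  if (irradiance <= 0) {
    return(c(on = 0, off = params$k_adapt))
  }
  s_act <- spectral_efficiency(
    wavelength_nm, params$act_peak_nm, params$act_width_nm
  )
  s_rev <- spectral_efficiency(
    wavelength_nm, params$rev_peak_nm, params$rev_width_nm
  )
  c(
    on = params$k_act * s_act * irradiance,
    off = params$k_rev * s_rev * irradiance + params$k_adapt
  )
}

#' Simulate the opsin active-state fraction under a light schedule
#'
#' Integrates the linear two-state photocycle
#' `da/dt = k_act * sigma_act(lambda) * I * (1 - a) -
#'  (k_rev * sigma_rev(lambda) * I + k_adapt) * a`
#' over a piecewise-constant light schedule. Within each constant-light
#' interval the equation is linear with constant coefficients, so the
#' integrator advances with the exact exponential update between samples and
#' splits steps at segment boundaries; the active fraction is therefore
#' bounded in \[0, 1\] by construction and free of step-size error.
#'
#' @param params A [photostate_params()] object.
#' @param schedule A [light_schedule()] object.
#' @param duration_s Total simulated duration (s); must cover the schedule.
#' @param dt_s Output sampling interval (s), > 0.
#' @param a0 Initial active fraction, default 0 (fully dark-adapted).
#' @return A [time_series()] of the active fraction `a(t)` on the grid
#'   `seq(0, duration_s, by = dt_s)`.
#' @examples
#' p <- photostate_params(k_act = 2, k_rev = 4, k_adapt = 0.1,
#'                        act_peak_nm = 405, rev_peak_nm = 500)
#' sch <- light_schedule(c(5, 6), c(6, 30), c(405, 470), c(0.5, 0.5))
#' a <- simulate_photostate(p, sch, duration_s = 30, dt_s = 1 / 67)
#' @export
simulate_photostate <- function(params, schedule, duration_s, dt_s, a0 = 0) {
  stopifnot(inherits(params, "PhotostateParams"))
  stopifnot(inherits(schedule, "LightSchedule"))
  if (dt_s <= 0) stop("dt_s must be > 0", call. = FALSE)
  if (a0 < 0 || a0 > 1) stop("a0 must lie in [0, 1]", call. = FALSE)
  if (nrow(schedule) > 0 && max(schedule$end_s) > duration_s + 1e-12) {
    stop("light schedule extends beyond the simulated duration", call. = FALSE)
  }

  t_out <- seq(0, duration_s, by = dt_s)
  n <- length(t_out)
  a <- numeric(n)
  a[1] <- a0

  # breakpoints where the coefficients change
  brk <- sort(unique(c(schedule$start_s, schedule$end_s)))

  seg_rates <- function(time) {
    # rates in force on the open interval starting at `time`
    if (nrow(schedule) > 0) {
      hit <- which(schedule$start_s <= time + 1e-12 &
        schedule$end_s > time + 1e-12)
      if (length(hit) > 0) {
        return(photostate_rates(
          params,
          schedule$wavelength_nm[hit[1]],
          schedule$irradiance_mw_mm2[hit[1]]
        ))
      }
    }
    c(on = 0, off = params$k_adapt)
  }

  advance <- function(a_cur, rates, h) {
    # exact solution of the constant-coefficient linear ODE over step h
    lam <- rates[["on"]] + rates[["off"]]
    if (lam == 0) {
      return(a_cur)
    }
    a_eq <- rates[["on"]] / lam
    a_eq + (a_cur - a_eq) * exp(-lam * h)
  }

  cur <- a0
  for (i in seq_len(n - 1)) {
    t0 <- t_out[i]
    t1 <- t_out[i + 1]
    cuts <- brk[brk > t0 + 1e-12 & brk < t1 - 1e-12]
    pts <- c(t0, cuts, t1)
    for (j in seq_len(length(pts) - 1)) {
      cur <- advance(cur, seg_rates(pts[j]), pts[j + 1] - pts[j])
    }
    a[i + 1] <- cur
  }
  time_series(t_out, pmin(pmax(a, 0), 1), label = "active_fraction")
}
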