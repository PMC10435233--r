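#' Heart-trial simulation parameters
#'
#' @param base_rate_bpm Baseline beat rate in beats per minute.
#' @param av_delay_s Atrium-to-ventricle conduction lag in seconds.
#' @param arrest_threshold Active-fraction level at and above which beating is
#'   fully suppressed; below it the instantaneous rate is scaled by
#'   `1 - (a / arrest_threshold)^gate_exponent`. Must lie in (0, 1].
#' @param gate_exponent Sharpness of the suppression gate (>= 1). With 1 the
#'   rate declines linearly in the active fraction; the default 4 keeps the
#'   rate near baseline until the active fraction approaches the threshold,
#'   so arrest is abrupt (within about one beat) while recovery stays graded.
#' @param recovery_tau_s Time constant (s) of the first-order relaxation of
#'   the beat rate back toward baseline after the active fraction falls below
#'   the arrest threshold.
#' @param beat_waveform_amp Luminosity excursion per beat (AU).
#' @param beat_width_s Width of the raised-cosine beat pulse (s).
#' @param baseline_lum Constant luminosity offset (AU).
#' @param noise_sd Additive Gaussian noise SD on each sample (AU).
#' @param fps Frames per second of the rendered traces (default 67, the
#'   frame rate of the infrared camera the assay was designed around).
#' @return An object of class `"HeartSimParams"`.
#' @export
heart_sim_params <- function(base_rate_bpm = 150, av_delay_s = 0.08,
                             arrest_threshold = 0.5, gate_exponent = 4,
                             recovery_tau_s = 3,
                             beat_waveform_amp = 1, beat_width_s = 0.12,
                             baseline_lum = 100, noise_sd = 0.1, fps = 67) {
  if (base_rate_bpm <= 0) stop("base_rate_bpm must be > 0", call. = FALSE)
  if (av_delay_s < 0) stop("av_delay_s must be >= 0", call. = FALSE)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (recovery_tau_s <= 0) stop("recovery_tau_s must be > 0", call. = FALSE)
  if (arrest_threshold <= 0 || arrest_threshold > 1) {
    stop("arrest_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (gate_exponent < 1) stop("gate_exponent must be >= 1", call. = FALSE)
  structure(
    list(
      base_rate_bpm = base_rate_bpm, av_delay_s = av_delay_s,
      arrest_threshold = arrest_threshold, gate_exponent = gate_exponent,
      recovery_tau_s = recovery_tau_s,
      beat_waveform_amp = beat_waveform_amp, beat_width_s = beat_width_s,
      baseline_lum = baseline_lum, noise_sd = noise_sd, fps = fps
    ),
    class = "HeartSimParams"
  )
}

# Instantaneous planted beat rate (bpm) on the frame grid, given the active
# fraction. Beating is gated off at a >= threshold; below threshold the rate
# target is base * (1 - (a/threshold)^gate_exponent); after each suppressed
# episode the effective rate relaxes first-order (recovery_tau_s) toward the
# target.
planted_rate_profile <- function(hparams, a_grid, t_grid) {
  th <- hparams$arrest_threshold
  p <- hparams$gate_exponent
  target <- ifelse(
    a_grid >= th, 0,
    hparams$base_rate_bpm * (1 - pmin(a_grid / th, 1)^p)
  )
  n <- length(t_grid)
  rate <- numeric(n)
  release_t <- -Inf
  had_arrest <- FALSE
  in_arrest <- FALSE
  for (i in seq_len(n)) {
    if (target[i] <= 0) {
      in_arrest <- TRUE
      had_arrest <- TRUE
      rate[i] <- 0
    } else {
      if (in_arrest) {
        release_t <- t_grid[i]
        in_arrest <- FALSE
      }
      recov <- if (had_arrest) {
        1 - exp(-(t_grid[i] - release_t) / hparams$recovery_tau_s)
      } else {
        1
      }
      rate[i] <- target[i] * recov
    }
  }
  rate
}

# Continuous beat times from a rate profile sampled on t_grid (bpm):
# trapezoidal phase accumulation, a beat at every integer phase crossing.
beats_from_rate <- function(rate_bpm, t_grid, phase0 = 0) {
  hz <- rate_bpm / 60
  dt <- diff(t_grid)
  inc <- (hz[-length(hz)] + hz[-1]) / 2 * dt
  phase <- c(phase0, phase0 + cumsum(inc))
  n_beats <- floor(phase[length(phase)] + 1e-9)
  if (n_beats < 1) {
    return(numeric(0))
  }
  targets <- seq_len(n_beats)
  idx <- findInterval(targets - 1e-12, phase)
  # linear interpolation within the bracketing grid cell
  t0 <- t_grid[idx]
  p0 <- phase[idx]
  slope <- (phase[idx + 1] - p0) / (t_grid[idx + 1] - t0)
  beat <- t0 + (targets - p0) / pmax(slope, .Machine$double.eps)
  pmin(beat, t_grid[length(t_grid)])
}

# Sum of raised-cosine pulses centered at beat times, evaluated on t_grid.
render_pulse_train <- function(t_grid, beat_times, amp, width) {
  v <- numeric(length(t_grid))
  if (length(beat_times) == 0) {
    return(v)
  }
  half <- width / 2
  dt <- t_grid[2] - t_grid[1]
  for (b in beat_times) {
    i0 <- max(1L, ceiling((b - half - t_grid[1]) / dt) + 1L)
    i1 <- min(length(t_grid), floor((b + half - t_grid[1]) / dt) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    tau <- t_grid[idx] - b
    v[idx] <- v[idx] + amp * 0.5 * (1 + cos(pi * tau / half))
  }
  v
}

#' Simulate one cardiac luminosity trial
#'
#' Renders paired atrial and ventricular ROI-luminosity traces whose beats are
#' gated by an opsin active-fraction trace. Beats are raised-cosine luminosity
#' pulses; the ventricular pulse train is the atrial train shifted by the
#' atrioventricular conduction delay. The returned ground truth records the
#' planted beat times and the arrest metrics implied by them (computed with
#' [arrest_metrics_from_beats()], the same definition the detector estimates),
#' so recovery can be scored exactly.
#'
#' @param hparams A [heart_sim_params()] object.
#' @param a Active-fraction [time_series()] (values in \[0, 1\]) covering the
#'   trial; it is linearly interpolated onto the frame grid.
#' @param duration_s Trial duration (s).
#' @param seed Integer random seed (mandatory; recorded in the ground truth).
#' @param stim_onset_s Stimulus onset used for the planted arrest metrics
#'   (`NA` to skip them).
#' @param phase0 Initial beat phase in \[0, 1); 0 puts the first beat exactly
#'   one inter-beat interval after t = 0.
#' @return A list with `atrium` and `ventricle` [time_series()] traces and
#'   `ground_truth`: beat times (atrial), `av_delay_s`, planted arrest
#'   metrics, the planted rate profile, `seed`, and `phase0`.
#' @examples
#' hp <- heart_sim_params(noise_sd = 0)
#' dark <- light_schedule()
#' a <- simulate_photostate(photostate_params(1), dark, 20, 1 / 67)
#' tr <- simulate_heart_trial(hp, a, 20, seed = 1)
#' length(tr$ground_truth$beat_times_s) # 50 beats at 150 bpm over 20 s
#' @export
simulate_heart_trial <- function(hparams, a, duration_s, seed,
                                 stim_onset_s = NA, phase0 = 0) {
  stopifnot(inherits(hparams, "HeartSimParams"), is_time_series(a))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (a$t[length(a$t)] < duration_s - 1e-9) {
    stop("active-fraction trace must cover the trial duration", call. = FALSE)
  }

  dt <- 1 / hparams$fps
  t_grid <- seq(0, duration_s, by = dt)
  a_grid <- stats::approx(a$t, a$v, xout = t_grid, rule = 2)$y
  rate <- planted_rate_profile(hparams, a_grid, t_grid)
  beats <- beats_from_rate(rate, t_grid, phase0 = phase0)

  atrium_v <- hparams$baseline_lum +
    render_pulse_train(t_grid, beats, hparams$beat_waveform_amp,
      width = hparams$beat_width_s
    )
  ventricle_v <- hparams$baseline_lum +
    render_pulse_train(t_grid, beats + hparams$av_delay_s,
      hparams$beat_waveform_amp,
      width = hparams$beat_width_s
    )
  if (hparams$noise_sd > 0) {
    withr::with_seed(seed, {
      atrium_v <- atrium_v + stats::rnorm(length(t_grid), 0, hparams$noise_sd)
      ventricle_v <- ventricle_v +
        stats::rnorm(length(t_grid), 0, hparams$noise_sd)
    })
  }

  arrest <- NULL
  if (!is.na(stim_onset_s)) {
    arrest <- arrest_metrics_from_beats(
      beats,
      stim_onset_s = stim_onset_s,
      baseline_ibi_s = 60 / hparams$base_rate_bpm,
      record_end_s = duration_s
    )
  }

  list(
    atrium = time_series(t_grid, atrium_v, label = "atrium"),
    ventricle = time_series(t_grid, ventricle_v, label = "ventricle"),
    ground_truth = list(
      beat_times_s = beats,
      av_delay_s = hparams$av_delay_s,
      arrest = arrest,
      rate_bpm = time_series(t_grid, rate, label = "planted_rate"),
      stim_onset_s = stim_onset_s,
      seed = seed,
      phase0 = phase0
    )
  )
}

#' Opsin regime presets for the simulator
#'
#' Bundled photostate parameter sets emulating the qualitative behaviour of
#' the three Gi/o-coupled tools the assay was built for, together with the
#' stimulation and reversal wavelengths used with each. The kinetic constants
#' are free generator parameters chosen so that under the standard protocol
#' (1 s pulse at 0.5 mW/mm^2) the planted arrest latency and resumption land
#' near the values reported for each tool; only their qualitative ordering
#' and the spectral separation of activation and reversal are meaningful.
#'
#' * `"mosopn3_like"`: green-activated, reversal spectrum overlapping the
#'   activation band, slow adaptation — blue light does not switch it off.
#' * `"puftmt_like"`: blue-activated, fast adaptation (quick resumption).
#' * `"lampp_like"`: violet-activated with a well-separated green/blue
#'   reversal band — switchable on (405 nm) and off (470 nm).
#'
#' @param name One of `"mosopn3_like"`, `"puftmt_like"`, `"lampp_like"`.
#' @return A list with `photostate` ([photostate_params()]),
#'   `stim_wavelength_nm`, and `reversal_wavelength_nm`.
#' @export
opsin_regime <- function(name = c("mosopn3_like", "puftmt_like",
                                  "lampp_like")) {
  name <- match.arg(name)
  switch(name,
    mosopn3_like = list(
      photostate = photostate_params(
        k_act = 1.85, k_rev = 0.15, k_adapt = 0.035,
        act_peak_nm = 520, act_width_nm = 60,
        rev_peak_nm = 470, rev_width_nm = 40
      ),
      stim_wavelength_nm = 520,
      reversal_wavelength_nm = 470
    ),
    puftmt_like = list(
      photostate = photostate_params(
        k_act = 1.6, k_rev = 0.15, k_adapt = 0.035,
        act_peak_nm = 470, act_width_nm = 50,
        rev_peak_nm = 480, rev_width_nm = 40
      ),
      stim_wavelength_nm = 470,
      reversal_wavelength_nm = 470
    ),
    lampp_like = list(
      photostate = photostate_params(
        k_act = 1.75, k_rev = 5, k_adapt = 0.02,
        act_peak_nm = 405, act_width_nm = 30,
        rev_peak_nm = 500, rev_width_nm = 40
      ),
      stim_wavelength_nm = 405,
      reversal_wavelength_nm = 470
    )
  )
}
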