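#' Tail-trial simulation parameters
#'
#' Bouts are rendered as constant-amplitude sinusoidal lateral displacement
#' (in body lengths) at the tail-beat frequency, zero outside bouts, plus
#' additive Gaussian noise. A flat within-bout envelope with instantaneous
#' attack keeps the planted onset sharp, which is what the latency metric
#' needs.
#'
#' @param bout_onsets_s Bout start times (s), strictly increasing.
#' @param bout_durations_s Bout durations (s), same length.
#' @param bout_amplitudes Peak lateral displacement per bout, as a fraction
#'   of body length (>= 0), same length.
#' @param tail_beat_freq_hz Within-bout oscillation frequency (default 20 Hz,
#'   a typical larval tail-beat rate).
#' @param noise_sd Displacement noise SD (body lengths).
#' @param fps Sampling rate (default 67).
#' @return An object of class `"TailSimParams"`.
#' @export
tail_sim_params <- function(bout_onsets_s = numeric(),
                            bout_durations_s = numeric(),
                            bout_amplitudes = numeric(),
                            tail_beat_freq_hz = 20,
                            noise_sd = 0.005, fps = 67) {
  n <- length(bout_onsets_s)
  if (length(bout_durations_s) != n || length(bout_amplitudes) != n) {
    stop("bout onset/duration/amplitude lists must have equal length",
      call. = FALSE
    )
  }
  if (n > 1 && is.unsorted(bout_onsets_s, strictly = TRUE)) {
    stop("bout onsets must be strictly increasing", call. = FALSE)
  }
  if (any(bout_amplitudes < 0)) {
    stop("bout amplitudes must be >= 0", call. = FALSE)
  }
  if (n > 1) {
    ends <- bout_onsets_s + bout_durations_s
    if (any(bout_onsets_s[-1] < ends[-n])) {
      stop("bouts must not overlap", call. = FALSE)
    }
  }
  structure(
    list(
      bout_onsets_s = as.numeric(bout_onsets_s),
      bout_durations_s = as.numeric(bout_durations_s),
      bout_amplitudes = as.numeric(bout_amplitudes),
      tail_beat_freq_hz = tail_beat_freq_hz,
      noise_sd = noise_sd, fps = fps
    ),
    class = "TailSimParams"
  )
}

#' Simulate one tail-displacement trial
#'
#' @param tparams A [tail_sim_params()] object.
#' @param stim_onset_s Stimulus onset (s); used only for the ground-truth
#'   trial classification.
#' @param duration_s Trial duration (s); all bouts must end within it.
#' @param seed Integer random seed (mandatory).
#' @return A list with `tail` (a [time_series()] of lateral displacement in
#'   body lengths) and `ground_truth`: planted bout table, `stim_onset_s`,
#'   `pre_stimulus_active` flag, and the planted latency/duration/strength of
#'   the first post-stimulus bout (`NA` if none).
#' @export
simulate_tail_trial <- function(tparams, stim_onset_s, duration_s, seed) {
  stopifnot(inherits(tparams, "TailSimParams"))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  ends <- tparams$bout_onsets_s + tparams$bout_durations_s
  if (length(ends) > 0 && max(ends) > duration_s + 1e-9) {
    stop("bouts must fall within the trial duration", call. = FALSE)
  }

  t_grid <- seq(0, duration_s, by = 1 / tparams$fps)
  v <- numeric(length(t_grid))
  for (i in seq_along(tparams$bout_onsets_s)) {
    on <- tparams$bout_onsets_s[i]
    off <- on + tparams$bout_durations_s[i]
    idx <- which(t_grid >= on & t_grid <= off)
    v[idx] <- v[idx] + tparams$bout_amplitudes[i] *
      sin(2 * pi * tparams$tail_beat_freq_hz * (t_grid[idx] - on))
  }
  if (tparams$noise_sd > 0) {
    withr::with_seed(seed, {
      v <- v + stats::rnorm(length(v), 0, tparams$noise_sd)
    })
  }

  bouts <- data.frame(
    start_s = tparams$bout_onsets_s,
    end_s = ends,
    peak_displacement = tparams$bout_amplitudes
  )
  post <- bouts[bouts$start_s >= stim_onset_s, , drop = FALSE]
  first <- if (nrow(post) > 0) post[1, ] else NULL
  list(
    tail = time_series(t_grid, v, label = "tail"),
    ground_truth = list(
      bouts = bouts,
      stim_onset_s = stim_onset_s,
      pre_stimulus_active = any(bouts$start_s < stim_onset_s),
      latency_s = if (is.null(first)) NA_real_ else first$start_s - stim_onset_s,
      duration_s = if (is.null(first)) NA_real_ else first$end_s - first$start_s,
      strength = if (is.null(first)) NA_real_ else first$peak_displacement,
      seed = seed
    )
  )
}

#' Simulate one cardiac GCaMP fluorescence trial
#'
#' Fluorescence is a positive baseline plus a beat-coupled transient (one
#' exponential-decay kernel per beat, unit peak, scaled by `beat_coupling`)
#' minus an arrest-coupled dip that relaxes first-order toward `dip_frac *
#' baseline_F` while the active fraction is above the arrest threshold and
#' back to zero when it is not.
#'
#' @param baseline_F Baseline fluorescence (AU), must be > 0.
#' @param beat_coupling Peak amplitude (AU) of the per-beat transient.
#' @param a Active-fraction [time_series()] gating the heart.
#' @param hparams A [heart_sim_params()] object (beat rate, threshold,
#'   recovery); `hparams$fps` is overridden by `fps` below for the
#'   fluorescence channel.
#' @param duration_s Trial duration (s).
#' @param seed Integer random seed (mandatory).
#' @param fps Fluorescence sampling rate (default 9, a typical slow CCD rate).
#' @param decay_tau_s Decay time constant of the per-beat kernel (s).
#' @param dip_frac Depth of the arrest dip as a fraction of baseline (< 1).
#' @param dip_tau_s Relaxation time constant of the dip (s).
#' @param noise_sd Additive Gaussian noise SD (AU).
#' @param phase0 Initial beat phase, as in [simulate_heart_trial()].
#' @return A list with `fluor` (a [time_series()]) and `ground_truth` (beat
#'   times, arrest interval of the dip, parameters, seed).
#' @export
simulate_gcamp_trial <- function(baseline_F, beat_coupling, a, hparams,
                                 duration_s, seed, fps = 9,
                                 decay_tau_s = 0.25, dip_frac = 0.3,
                                 dip_tau_s = 2, noise_sd = 0, phase0 = 0) {
  if (baseline_F <= 0) stop("baseline_F must be > 0", call. = FALSE)
  if (dip_frac >= 1 || dip_frac < 0) {
    stop("dip_frac must lie in [0, 1)", call. = FALSE)
  }
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(is_time_series(a), inherits(hparams, "HeartSimParams"))

  t_grid <- seq(0, duration_s, by = 1 / fps)
  a_grid <- stats::approx(a$t, a$v, xout = t_grid, rule = 2)$y
  rate <- planted_rate_profile(hparams, a_grid, t_grid)
  beats <- beats_from_rate(rate, t_grid, phase0 = phase0)

  # beat-coupled transients: instant rise, exponential decay; the kernel is
  # anchored to the first sample at/after the beat so its sampled peak is
  # exactly beat_coupling
  trans <- numeric(length(t_grid))
  for (b in beats) {
    idx <- which(t_grid >= b)
    if (length(idx) == 0) next
    trans[idx] <- trans[idx] + exp(-(t_grid[idx] - t_grid[idx[1]]) / decay_tau_s)
  }

  # arrest-coupled dip: first-order relaxation toward dip_frac * baseline
  suppressed <- a_grid >= hparams$arrest_threshold
  dip <- numeric(length(t_grid))
  dt <- 1 / fps
  for (i in seq_len(length(t_grid) - 1)) {
    target <- if (suppressed[i]) dip_frac * baseline_F else 0
    dip[i + 1] <- dip[i] + (target - dip[i]) * (1 - exp(-dt / dip_tau_s))
  }

  v <- baseline_F + beat_coupling * trans - dip
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      v <- v + stats::rnorm(length(v), 0, noise_sd)
    })
  }
  v <- pmax(v, .Machine$double.eps) # fluorescence is strictly positive

  list(
    fluor = time_series(t_grid, v, label = "gcamp"),
    ground_truth = list(
      beat_times_s = beats,
      suppressed = time_series(t_grid, as.numeric(suppressed)),
      baseline_F = baseline_F, beat_coupling = beat_coupling,
      dip_frac = dip_frac, seed = seed
    )
  )
}
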