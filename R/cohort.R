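#' Simulate a heart-trial cohort for one opsin regime
#'
#' Runs the standard stimulation protocol over a cohort of larvae: each larva
#' receives `n_trials` consecutive trials of a 1 s light pulse at its regime's
#' activation wavelength; under `protocol = "pulse_reversal"` the pulse is
#' followed by sustained reversal-wavelength light until the end of the
#' trial. Biological variability is modeled as a per-larva lognormal
#' sensitivity multiplier on irradiance (expression-level differences) plus a
#' smaller per-trial jitter, and a random beat phase per trial.
#'
#' @param regime Regime name accepted by [opsin_regime()], or a regime list.
#' @param n_larvae,n_trials Cohort shape (defaults 4 larvae x 6 trials, the
#'   standard design).
#' @param seed Integer master seed; all randomness derives from it.
#' @param protocol `"pulse"` (1 s pulse, darkness after) or
#'   `"pulse_reversal"` (pulse then sustained reversal light).
#' @param duration_s Trial length (s).
#' @param stim_onset_s Pulse onset (s); leaves a pre-stimulus baseline.
#' @param pulse_s Pulse duration (s).
#' @param irradiance Nominal irradiance (mW/mm^2), default 0.5.
#' @param hparams [heart_sim_params()] shared by all trials.
#' @param larva_sens_sdlog,trial_sens_sdlog Lognormal SDs of the per-larva
#'   and per-trial sensitivity multipliers.
#' @param sens_scale Extra multiplier on every trial's sensitivity (used by
#'   the pharmacological-blockade simulation).
#' @return A list with `trials` (list of [simulate_heart_trial()] outputs),
#'   and `truth`: a data.frame with one row per trial — ids, seed,
#'   sensitivity, and the planted arrest metrics.
#' @export
simulate_heart_cohort <- function(regime, n_larvae = 4, n_trials = 6, seed,
                                  protocol = c("pulse", "pulse_reversal"),
                                  duration_s = 40, stim_onset_s = 10,
                                  pulse_s = 1, irradiance = 0.5,
                                  hparams = heart_sim_params(),
                                  larva_sens_sdlog = 0.15,
                                  trial_sens_sdlog = 0.05,
                                  sens_scale = 1) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  protocol <- match.arg(protocol)
  if (is.character(regime)) regime <- opsin_regime(regime)

  draws <- withr::with_seed(seed, {
    list(
      larva_sens = stats::rlnorm(n_larvae, 0, larva_sens_sdlog),
      trial_sens = matrix(
        stats::rlnorm(n_larvae * n_trials, 0, trial_sens_sdlog),
        n_larvae, n_trials
      ),
      phase0 = matrix(stats::runif(n_larvae * n_trials), n_larvae, n_trials),
      trial_seed = matrix(
        sample.int(.Machine$integer.max, n_larvae * n_trials),
        n_larvae, n_trials
      )
    )
  })

  trials <- list()
  truth <- NULL
  dt <- 1 / hparams$fps
  for (l in seq_len(n_larvae)) {
    for (k in seq_len(n_trials)) {
      sens <- draws$larva_sens[l] * draws$trial_sens[l, k] * sens_scale
      sch <- if (protocol == "pulse") {
        light_schedule(
          stim_onset_s, stim_onset_s + pulse_s,
          regime$stim_wavelength_nm, irradiance * sens
        )
      } else {
        light_schedule(
          c(stim_onset_s, stim_onset_s + pulse_s),
          c(stim_onset_s + pulse_s, duration_s),
          c(regime$stim_wavelength_nm, regime$reversal_wavelength_nm),
          c(irradiance * sens, irradiance)
        )
      }
      a <- simulate_photostate(regime$photostate, sch, duration_s, dt)
      tr <- simulate_heart_trial(
        hparams, a, duration_s,
        seed = draws$trial_seed[l, k],
        stim_onset_s = stim_onset_s, phase0 = draws$phase0[l, k]
      )
      trials[[length(trials) + 1]] <- tr
      gt <- tr$ground_truth$arrest
      truth <- rbind(truth, data.frame(
        larva_id = l, trial = k, seed = draws$trial_seed[l, k],
        sensitivity = sens, stim_onset_s = stim_onset_s,
        arrested = gt$arrested,
        latency_to_arrest_s = gt$latency_to_arrest_s,
        time_to_resumption_s = gt$time_to_resumption_s,
        arrest_duration_s = gt$arrest_duration_s
      ))
    }
  }
  list(trials = trials, truth = truth, protocol = protocol, regime = regime)
}

#' Detected cardiac metrics for one simulated or recorded trial
#'
#' The per-trial cardiac pipeline: beat detection on the atrial trace,
#' arrest metrics, and (when a ventricular trace is given) the AV conduction
#' delay summary.
#'
#' @param atrium Atrial luminosity [time_series()].
#' @param stim_onset_s Stimulus onset (s).
#' @param ventricle Optional ventricular [time_series()].
#' @param min_ibi_s,prominence_frac Passed to [detect_beats()].
#' @param gap_factor,search_window_s Passed to [detect_arrest()].
#' @param max_av_delay_s Passed to [av_delay()].
#' @return A one-row data.frame: arrest metrics plus `n_beats`,
#'   `mean_av_delay_s` and `n_av_excluded` (NA without a ventricle trace).
#' @export
heart_trial_metrics <- function(atrium, stim_onset_s, ventricle = NULL,
                                min_ibi_s = 0.25, prominence_frac = 0.5,
                                gap_factor = 2, search_window_s = 8,
                                max_av_delay_s = 0.5) {
  beats <- detect_beats(atrium,
    min_ibi_s = min_ibi_s,
    prominence_frac = prominence_frac
  )
  arrest <- detect_arrest(beats, stim_onset_s,
    gap_factor = gap_factor,
    search_window_s = search_window_s,
    record_end_s = atrium$t[length(atrium$t)]
  )
  av_mean <- NA_real_
  av_excl <- NA_integer_
  if (!is.null(ventricle)) {
    vbeats <- detect_beats(ventricle,
      min_ibi_s = min_ibi_s,
      prominence_frac = prominence_frac
    )
    av <- av_delay(beats, vbeats, max_delay_s = max_av_delay_s)
    av_mean <- if (nrow(av) > 0) mean(av$delay_s) else NA_real_
    av_excl <- attr(av, "n_excluded")
  }
  cbind(
    as.data.frame(arrest),
    data.frame(
      n_beats = length(beats$beat_times_s),
      mean_av_delay_s = av_mean, n_av_excluded = av_excl
    )
  )
}

#' Run the cardiac pipeline over a simulated cohort
#'
#' @param cohort Output of [simulate_heart_cohort()].
#' @param ... Passed to [heart_trial_metrics()].
#' @return The cohort's truth table with detected-metric columns appended
#'   (prefixed `det_`).
#' @export
analyze_heart_cohort <- function(cohort, ...) {
  res <- lapply(cohort$trials, function(tr) {
    heart_trial_metrics(
      tr$atrium,
      stim_onset_s = tr$ground_truth$stim_onset_s,
      ventricle = tr$ventricle, ...
    )
  })
  det <- do.call(rbind, res)
  names(det) <- paste0("det_", names(det))
  cbind(cohort$truth, det)
}

#' Simulate a pharmacological-blockade cohort
#'
#' The blockade design: each larva runs `n_pre` trials, is then (in the
#' treated arm) exposed to a Gi/o-pathway blocker, and runs `n_post` further
#' trials. Blockade is modeled as a multiplicative loss of effective light
#' sensitivity in the post-treatment trials (`block_factor` close to 0 means
#' near-complete block: the photostate barely rises, so arrest is absent or
#' brief); the untreated arm keeps full sensitivity throughout.
#'
#' @param regime Regime name or list, as in [simulate_heart_cohort()].
#' @param n_larvae Larvae per arm.
#' @param n_pre,n_post Trials before/after treatment.
#' @param block_factor Post-treatment sensitivity multiplier in the treated
#'   arm (default 0.02).
#' @param seed Master seed.
#' @param ... Passed to [simulate_heart_cohort()].
#' @return A list with elements `treated` and `control`, each a cohort as
#'   returned by [simulate_heart_cohort()] with trials ordered pre then post
#'   (trial index runs 1..n_pre+n_post).
#' @export
simulate_blockade_cohort <- function(regime, n_larvae = 4, n_pre = 3,
                                     n_post = 3, block_factor = 0.02, seed,
                                     ...) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 4))
  combine <- function(pre, post) {
    post$truth$trial <- post$truth$trial + max(pre$truth$trial)
    ord <- order(
      c(pre$truth$larva_id, post$truth$larva_id),
      c(pre$truth$trial, post$truth$trial)
    )
    list(
      trials = c(pre$trials, post$trials)[ord],
      truth = rbind(pre$truth, post$truth)[ord, ],
      protocol = pre$protocol, regime = pre$regime
    )
  }
  treated <- combine(
    simulate_heart_cohort(regime, n_larvae, n_pre, seed = seeds[1], ...),
    simulate_heart_cohort(regime, n_larvae, n_post,
      seed = seeds[2],
      sens_scale = block_factor, ...
    )
  )
  control <- combine(
    simulate_heart_cohort(regime, n_larvae, n_pre, seed = seeds[3], ...),
    simulate_heart_cohort(regime, n_larvae, n_post, seed = seeds[4], ...)
  )
  list(treated = treated, control = control)
}

#' Simulate a locomotion cohort
#'
#' Trial-structured tail-displacement traces with per-trial planted bouts:
#' each trial is induced with probability `induced_prob`, in which case one
#' bout is planted at a latency drawn within the induction window;
#' occasionally (probability `pre_stim_prob`) a spontaneous pre-stimulus bout
#' is planted, which marks the trial for exclusion. Defaults emulate a
#' strongly responsive Gq line (induction in roughly nine trials out of ten,
#' latencies around 3 s, durations around 4 s, strength around 0.3 body
#' lengths).
#'
#' @param n_larvae,n_trials Cohort shape (defaults 12 x 6).
#' @param seed Master seed.
#' @param stim_onset_s Stimulus onset (s).
#' @param duration_s Trial duration (s).
#' @param induced_prob Probability a trial is induced.
#' @param pre_stim_prob Probability of a spontaneous pre-stimulus bout.
#' @param latency_mean_s,latency_sd_s Planted latency distribution
#'   (truncated to \[0.3, induction window\]).
#' @param duration_mean_s,duration_sd_s Planted bout duration (truncated at
#'   0.5 s).
#' @param strength_mean,strength_sd Planted peak displacement (truncated at
#'   0.05).
#' @param induction_window_s Induction window (s).
#' @param tparams_base Baseline [tail_sim_params()] supplying the tail-beat
#'   frequency, noise and fps.
#' @return A list with `trials` (list of [simulate_tail_trial()] outputs) and
#'   `truth` (one row per trial: ids, planted classification and metrics).
#' @export
simulate_locomotion_cohort <- function(n_larvae = 12, n_trials = 6, seed,
                                       stim_onset_s = 10, duration_s = 25,
                                       induced_prob = 0.89,
                                       pre_stim_prob = 0.05,
                                       latency_mean_s = 3.23,
                                       latency_sd_s = 1.0,
                                       duration_mean_s = 4.37,
                                       duration_sd_s = 1.5,
                                       strength_mean = 0.3,
                                       strength_sd = 0.05,
                                       induction_window_s = 8,
                                       tparams_base = tail_sim_params()) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  n <- n_larvae * n_trials
  draws <- withr::with_seed(seed, {
    list(
      induced = stats::runif(n) < induced_prob,
      pre_stim = stats::runif(n) < pre_stim_prob,
      latency = pmin(
        pmax(stats::rnorm(n, latency_mean_s, latency_sd_s), 0.3),
        induction_window_s - 0.2
      ),
      dur = pmax(stats::rnorm(n, duration_mean_s, duration_sd_s), 0.5),
      amp = pmax(stats::rnorm(n, strength_mean, strength_sd), 0.05),
      pre_onset = stats::runif(n, 1, stim_onset_s - 3),
      pre_dur = stats::runif(n, 0.5, 2),
      trial_seed = sample.int(.Machine$integer.max, n)
    )
  })

  trials <- list()
  truth <- NULL
  i <- 0
  for (l in seq_len(n_larvae)) {
    for (k in seq_len(n_trials)) {
      i <- i + 1
      onsets <- numeric(0)
      durs <- numeric(0)
      amps <- numeric(0)
      if (draws$pre_stim[i]) {
        onsets <- draws$pre_onset[i]
        durs <- draws$pre_dur[i]
        amps <- 0.2
      }
      if (draws$induced[i]) {
        onsets <- c(onsets, stim_onset_s + draws$latency[i])
        durs <- c(durs, min(draws$dur[i], duration_s - utils::tail(onsets, 1) - 0.5))
        amps <- c(amps, draws$amp[i])
      }
      tp <- tail_sim_params(
        bout_onsets_s = onsets, bout_durations_s = durs,
        bout_amplitudes = amps,
        tail_beat_freq_hz = tparams_base$tail_beat_freq_hz,
        noise_sd = tparams_base$noise_sd, fps = tparams_base$fps
      )
      tr <- simulate_tail_trial(tp, stim_onset_s, duration_s,
        seed = draws$trial_seed[i]
      )
      trials[[length(trials) + 1]] <- tr
      gt <- tr$ground_truth
      truth <- rbind(truth, data.frame(
        larva_id = l, trial = k, seed = draws$trial_seed[i],
        stim_onset_s = stim_onset_s,
        pre_stimulus_active = gt$pre_stimulus_active,
        induced = draws$induced[i],
        latency_s = gt$latency_s, duration_s = gt$duration_s,
        strength = gt$strength
      ))
    }
  }
  list(trials = trials, truth = truth)
}
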