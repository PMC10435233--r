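#' Detect heartbeats in an ROI luminosity trace
#'
#' Peak detection on a detrended trace. The trace is detrended with a running
#' median (window about one second) and lightly smoothed with a short running
#' mean; peaks must be separated by at least `min_ibi_s` and exceed a
#' prominence floor that combines a fraction of the robust beat amplitude
#' (98th percentile of the absolute detrended signal) with a noise floor of
#' four robust noise SDs (median absolute deviation of first differences).
#'
#' @param trace A [time_series()] luminosity trace, at least 2 s long.
#' @param min_ibi_s Minimum inter-beat interval (s); peaks closer than this
#'   are suppressed (strongest wins). Must be > 0.
#' @param prominence_frac Fraction of the robust beat amplitude a peak must
#'   reach (default 0.5).
#' @param smooth_s Width of the pre-detection running-mean smoother (s).
#' @return An object of class `"BeatSeries"`: list with `beat_times_s`
#'   (strictly increasing), `source` (the trace label), and the detector
#'   parameters used. A flat trace yields an empty series, not an error.
#' @export
detect_beats <- function(trace, min_ibi_s = 0.25, prominence_frac = 0.5,
                         smooth_s = 0.06) {
  stopifnot(is_time_series(trace))
  if (min_ibi_s <= 0) stop("min_ibi_s must be > 0", call. = FALSE)
  if ((trace$t[length(trace$t)] - trace$t[1]) < 2) {
    stop("trace must span at least 2 s", call. = FALSE)
  }

  v <- trace$v
  fps <- trace$fps
  # robust detrend: running median over ~1 s; "constant" endrule keeps the
  # edge baseline at the nearest full-window median so that beats truncated
  # at the record boundaries are not absorbed into the baseline
  k_med <- max(3L, 2L * floor(fps / 2) + 1L)
  base <- stats::runmed(v, k_med, endrule = "constant")
  x <- v - base
  # short centered running mean (partial windows at the edges); symmetric,
  # so peak positions do not shift
  k_sm <- max(1L, 2L * floor(smooth_s * fps / 2) + 1L)
  if (k_sm >= 3) {
    x <- zoo::rollapply(x, k_sm, mean, partial = TRUE, align = "center")
  }

  amp <- stats::quantile(abs(x), 0.98, names = FALSE)
  # noise floor of the smoothed signal, estimated from its quiet half
  # (MAD over samples below the median magnitude; beats do not contaminate it)
  quiet <- x[abs(x) <= stats::median(abs(x))]
  noise_sd <- stats::mad(quiet, center = 0)
  floor_h <- max(prominence_frac * amp, 4 * noise_sd, .Machine$double.eps)

  beat_times <- numeric(0)
  if (max(x) >= floor_h) {
    # pad below the signal floor so beats truncated at the record edges
    # still register as local maxima
    pad <- min(x) - 1
    xp <- c(pad, x, pad)
    pk <- pracma::findpeaks(xp,
      minpeakheight = floor_h,
      minpeakdistance = max(1L, round(min_ibi_s * fps))
    )
    if (!is.null(pk)) {
      idx <- pk[, 2] - 1L
      idx <- idx[idx >= 1 & idx <= length(x)]
      beat_times <- sort(trace$t[idx])
    }
  }
  structure(
    list(
      beat_times_s = beat_times,
      source = trace$label,
      params = list(
        min_ibi_s = min_ibi_s, prominence_frac = prominence_frac,
        smooth_s = smooth_s
      )
    ),
    class = "BeatSeries"
  )
}

#' Construct a beat series from known beat times
#'
#' @param beat_times_s Strictly increasing numeric vector of beat times (s).
#' @param source Optional source label.
#' @return A `"BeatSeries"` object.
#' @export
beat_series <- function(beat_times_s, source = NULL) {
  beat_times_s <- as.numeric(beat_times_s)
  if (is.unsorted(beat_times_s, strictly = TRUE)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(beat_times_s = beat_times_s, source = source, params = list()),
    class = "BeatSeries"
  )
}

#' @export
print.BeatSeries <- function(x, ...) {
  cat(sprintf(
    "<BeatSeries: %d beats%s>\n", length(x$beat_times_s),
    if (is.null(x$source)) "" else paste0(" from '", x$source, "'")
  ))
  invisible(x)
}

#' Relative heartbeat frequency trace
#'
#' Raw frequency at each time point is the beat count in the closed window
#' `[t - h, t + h]` divided by `2h`; the relative frequency divides by the
#' mean raw frequency over a pre-stimulus baseline window. Points whose
#' window extends beyond the record are `NA`.
#'
#' @param beats A `"BeatSeries"`.
#' @param baseline_window Numeric `c(start_s, end_s)` of the pre-stimulus
#'   baseline; must contain at least 2 beats.
#' @param window_halfwidth_s Half-width `h` of the counting window (s). The
#'   default 0.5 follows the assay's 500 ms convention; 1.0 reproduces its
#'   alternative one-second reading.
#' @param t_eval Evaluation times; defaults to a grid at `eval_dt_s` spacing
#'   over the beat-series span extended by the record limits.
#' @param record_span Numeric `c(start_s, end_s)` of the underlying record;
#'   defaults to the span of the beat times.
#' @param eval_dt_s Spacing of the default evaluation grid (s).
#' @return A data.frame with columns `t`, `raw_freq_hz`, `rel_freq`, plus
#'   attributes `baseline_freq_hz` and `window_halfwidth_s`.
#' @export
relative_hb_frequency <- function(beats, baseline_window,
                                  window_halfwidth_s = 0.5,
                                  t_eval = NULL, record_span = NULL,
                                  eval_dt_s = 0.1) {
  stopifnot(inherits(beats, "BeatSeries"))
  bt <- beats$beat_times_s
  if (length(baseline_window) != 2 ||
    baseline_window[2] <= baseline_window[1]) {
    stop("baseline_window must be c(start_s, end_s)", call. = FALSE)
  }
  n_base <- sum(bt >= baseline_window[1] & bt <= baseline_window[2])
  if (n_base < 2) {
    stop("baseline window must contain at least 2 beats", call. = FALSE)
  }
  if (is.null(record_span)) record_span <- range(bt)
  if (is.null(t_eval)) {
    t_eval <- seq(record_span[1], record_span[2], by = eval_dt_s)
  }

  h <- window_halfwidth_s
  count_in <- function(t) {
    # closed-closed window: a beat on the boundary counts once
    sum(bt >= t - h & bt <= t + h)
  }
  raw <- vapply(t_eval, count_in, numeric(1)) / (2 * h)
  out_of_record <- (t_eval - h < record_span[1] - 1e-9) |
    (t_eval + h > record_span[2] + 1e-9)
  raw[out_of_record] <- NA_real_

  base_t <- t_eval[t_eval >= baseline_window[1] + h &
    t_eval <= baseline_window[2] - h]
  if (length(base_t) == 0) {
    base_t <- mean(baseline_window)
  }
  base_raw <- vapply(base_t, count_in, numeric(1)) / (2 * h)
  baseline_freq <- mean(base_raw)
  if (baseline_freq <= 0) {
    stop("baseline frequency is zero; cannot normalize", call. = FALSE)
  }

  out <- data.frame(t = t_eval, raw_freq_hz = raw, rel_freq = raw / baseline_freq)
  attr(out, "baseline_freq_hz") <- baseline_freq
  attr(out, "window_halfwidth_s") <- h
  out
}

#' Arrest metrics from beat times
#'
#' The reproducible arrest definition shared by the detector and the
#' synthetic generator's ground truth: the arrest-triggering event is the
#' first post-stimulus inter-beat gap longer than `gap_factor` baseline
#' inter-beat intervals; arrest onset is the last beat preceding that gap
#' plus one baseline interval (the first missed expected beat). A trial is
#' arrested only if that onset falls within `search_window_s` of the
#' stimulus onset. The gap from the final beat to the end of the record also
#' counts (resumption is then `NA`).
#'
#' @param beat_times_s Numeric vector of beat times (s).
#' @param stim_onset_s Stimulus onset (s).
#' @param baseline_ibi_s Baseline inter-beat interval (s).
#' @param gap_factor Gap threshold in baseline intervals (default 2).
#' @param search_window_s Window after stimulus onset within which the arrest
#'   onset must fall (default 8 s).
#' @param record_end_s End of the record (s); defaults to the last beat.
#' @return A one-row data.frame (class `"ArrestResult"`): `arrested`,
#'   `latency_to_arrest_s`, `time_to_resumption_s`, `arrest_duration_s`,
#'   `onset_s`, `resumed_at_s` (all `NA` when not arrested).
#' @export
arrest_metrics_from_beats <- function(beat_times_s, stim_onset_s,
                                      baseline_ibi_s, gap_factor = 2,
                                      search_window_s = 8,
                                      record_end_s = NULL) {
  bt <- sort(beat_times_s)
  if (is.null(record_end_s)) record_end_s <- if (length(bt)) max(bt) else 0
  empty <- data.frame(
    arrested = FALSE, latency_to_arrest_s = NA_real_,
    time_to_resumption_s = NA_real_, arrest_duration_s = NA_real_,
    onset_s = NA_real_, resumed_at_s = NA_real_
  )
  class(empty) <- c("ArrestResult", "data.frame")
  if (length(bt) == 0) {
    return(empty)
  }

  gap_start <- bt
  gap_end <- c(bt[-1], record_end_s)
  gap_len <- gap_end - gap_start
  thresh <- gap_factor * baseline_ibi_s
  onset_cand <- gap_start + baseline_ibi_s
  hit <- which(gap_len > thresh &
    onset_cand > stim_onset_s &
    onset_cand <= stim_onset_s + search_window_s)
  if (length(hit) == 0) {
    return(empty)
  }
  k <- hit[1]
  onset <- onset_cand[k]
  resumed_at <- if (k < length(bt)) bt[k + 1] else NA_real_
  res <- data.frame(
    arrested = TRUE,
    latency_to_arrest_s = onset - stim_onset_s,
    time_to_resumption_s = if (is.na(resumed_at)) NA_real_ else resumed_at - onset,
    arrest_duration_s = if (is.na(resumed_at)) NA_real_ else resumed_at - onset,
    onset_s = onset, resumed_at_s = resumed_at
  )
  class(res) <- c("ArrestResult", "data.frame")
  res
}

#' Detect cardiac arrest in a trial
#'
#' Estimates the baseline inter-beat interval as the median interval between
#' pre-stimulus beats, then applies the gap rule of
#' [arrest_metrics_from_beats()].
#'
#' @param beats A `"BeatSeries"`.
#' @param stim A [light_schedule()] with at least one segment, or a single
#'   numeric stimulus-onset time (s).
#' @param gap_factor Gap threshold in baseline inter-beat intervals.
#' @param search_window_s Post-stimulus search window (s).
#' @param record_end_s End of the record (s); defaults to the last beat time.
#' @return An `"ArrestResult"` one-row data.frame; the estimated
#'   `baseline_ibi_s` is attached as an attribute.
#' @export
detect_arrest <- function(beats, stim, gap_factor = 2, search_window_s = 8,
                          record_end_s = NULL) {
  stopifnot(inherits(beats, "BeatSeries"))
  onset <- if (inherits(stim, "LightSchedule")) {
    if (nrow(stim) == 0) stop("stimulus schedule is empty", call. = FALSE)
    min(stim$start_s)
  } else {
    as.numeric(stim)[1]
  }
  pre <- beats$beat_times_s[beats$beat_times_s < onset]
  if (length(pre) < 2) {
    stop("need at least 2 pre-stimulus beats to estimate the baseline IBI",
      call. = FALSE
    )
  }
  ibi <- stats::median(diff(pre))
  res <- arrest_metrics_from_beats(
    beats$beat_times_s,
    stim_onset_s = onset, baseline_ibi_s = ibi,
    gap_factor = gap_factor, search_window_s = search_window_s,
    record_end_s = record_end_s
  )
  attr(res, "baseline_ibi_s") <- ibi
  res
}

#' Arrest-time ratios across consecutive trials
#'
#' Each trial's arrest duration divided by the arrest duration of trial 1 —
#' the pharmacological-blockade readout. Trials that did not arrest
#' contribute a duration of 0.
#'
#' @param results A list of `"ArrestResult"` rows (ordered by trial index) or
#'   a data.frame with columns `arrested` and `arrest_duration_s`.
#' @return Numeric vector of ratios; the first element is exactly 1.
#' @export
arrest_time_ratio <- function(results) {
  if (is.data.frame(results)) {
    dur <- ifelse(results$arrested, results$arrest_duration_s, 0)
  } else {
    dur <- vapply(results, function(r) {
      if (isTRUE(r$arrested)) r$arrest_duration_s else 0
    }, numeric(1))
  }
  dur[is.na(dur)] <- 0
  if (length(dur) == 0) stop("no trials supplied", call. = FALSE)
  if (dur[1] <= 0) {
    stop("trial 1 must be arrested with positive arrest duration",
      call. = FALSE
    )
  }
  ratios <- dur / dur[1]
  ratios[1] <- 1
  ratios
}

#' Per-larva cardiac arrest rate
#'
#' Fraction of valid trials per larva in which arrest was detected.
#'
#' @param trials A data.frame with columns `larva_id` and `arrested`
#'   (logical); rows with `NA` in `arrested` are dropped.
#' @return A data.frame with `larva_id`, `n_trials`, `arrest_rate` in \[0,1\].
#' @export
cardiac_arrest_rate <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("larva_id", "arrested") %in%
    names(trials)))
  trials <- trials[!is.na(trials$arrested), , drop = FALSE]
  if (nrow(trials) == 0) stop("no valid trials", call. = FALSE)
  agg <- stats::aggregate(arrested ~ larva_id, data = trials, FUN = mean)
  n <- stats::aggregate(arrested ~ larva_id, data = trials, FUN = length)
  data.frame(
    larva_id = agg$larva_id, n_trials = n$arrested,
    arrest_rate = agg$arrested
  )
}

#' Atrioventricular conduction delay
#'
#' Matches each atrial peak to the earliest ventricular peak strictly after
#' it and before the next atrial peak (one-to-one, non-crossing). Pairs with
#' delay exceeding `max_delay_s` are counted as undetected and excluded;
#' unmatched atrial peaks are dropped.
#'
#' @param atrial,ventricular `"BeatSeries"` objects.
#' @param max_delay_s Exclusion bound on the delay (s); default 0.5.
#' @return An object of class `"AvDelaySeries"`: data.frame of retained pairs
#'   (`atrial_peak_s`, `ventricular_peak_s`, `delay_s`) with attribute
#'   `n_excluded`.
#' @export
av_delay <- function(atrial, ventricular, max_delay_s = 0.5) {
  stopifnot(inherits(atrial, "BeatSeries"), inherits(ventricular, "BeatSeries"))
  at <- atrial$beat_times_s
  vt <- sort(ventricular$beat_times_s)
  pairs <- data.frame(
    atrial_peak_s = numeric(0), ventricular_peak_s = numeric(0),
    delay_s = numeric(0)
  )
  n_excluded <- 0L
  vi <- 1L
  for (i in seq_along(at)) {
    upper <- if (i < length(at)) at[i + 1] else Inf
    while (vi <= length(vt) && vt[vi] <= at[i]) vi <- vi + 1L
    if (vi > length(vt) || vt[vi] >= upper) next # unmatched atrial peak
    d <- vt[vi] - at[i]
    if (d > max_delay_s) {
      n_excluded <- n_excluded + 1L
    } else {
      pairs <- rbind(pairs, data.frame(
        atrial_peak_s = at[i], ventricular_peak_s = vt[vi], delay_s = d
      ))
    }
    vi <- vi + 1L
  }
  structure(pairs,
    n_excluded = n_excluded,
    class = c("AvDelaySeries", "data.frame")
  )
}
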