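#' Detect tail-movement bouts
#'
#' A bout is a maximal interval where the envelope of the absolute lateral
#' displacement exceeds a threshold. The envelope is a centered rolling
#' maximum of `|displacement|` over `envelope_s` so the within-bout tail-beat
#' oscillation does not fragment a bout; intervals separated by less than
#' `min_gap_s` are merged; finally the start and end of each bout are refined
#' to the first and last raw threshold crossings inside the interval (the
#' rolling maximum alone would bias onsets early by half its window).
#'
#' @param tail A [time_series()] of lateral displacement in body lengths.
#' @param threshold Displacement threshold in body lengths (> 0); default
#'   0.05.
#' @param min_gap_s Sub-threshold gaps shorter than this are merged (s).
#' @param envelope_s Rolling-maximum window (s), default 0.15.
#' @return A data.frame of bout events: `start_s`, `end_s`,
#'   `peak_displacement`.
#' @export
detect_bouts <- function(tail, threshold = 0.05, min_gap_s = 0.1,
                         envelope_s = 0.15) {
  stopifnot(is_time_series(tail))
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  x <- abs(tail$v)
  fps <- tail$fps
  k <- max(1L, 2L * floor(envelope_s * fps / 2) + 1L)
  env <- if (k >= 3) {
    zoo::rollapply(x, k, max, fill = NA, align = "center")
  } else {
    x
  }
  env[is.na(env)] <- x[is.na(env)]

  above <- env > threshold
  if (!any(above)) {
    return(data.frame(
      start_s = numeric(0), end_s = numeric(0),
      peak_displacement = numeric(0)
    ))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])

  # merge intervals separated by < min_gap_s
  merged <- list()
  cur <- iv[1, ]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      gap <- (iv[i, 1] - cur[2] - 1) / fps
      if (gap < min_gap_s) {
        cur[2] <- iv[i, 2]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- iv[i, ]
      }
    }
  }
  merged[[length(merged) + 1]] <- cur

  out <- lapply(merged, function(m) {
    idx <- m[1]:m[2]
    raw_above <- idx[x[idx] > threshold]
    if (length(raw_above) == 0) raw_above <- idx # envelope-only excursion
    data.frame(
      start_s = tail$t[min(raw_above)],
      end_s = tail$t[max(raw_above)],
      peak_displacement = max(x[idx])
    )
  })
  do.call(rbind, out)
}

#' Classify a stimulation trial from its bout list
#'
#' A pure rule on the bout table: the trial is `pre_stimulus_active` if any
#' bout starts before the stimulus onset, and `induced` if the first
#' post-stimulus bout starts within the induction window. Latency, duration
#' and strength are taken from that first post-stimulus bout.
#'
#' @param bouts Bout data.frame as returned by [detect_bouts()].
#' @param stim_onset_s Stimulus onset (s).
#' @param induction_window_s Window after onset within which an induced bout
#'   must start (default 8 s).
#' @return A one-row data.frame (`LocomotionTrialResult`):
#'   `pre_stimulus_active`, `induced`, `latency_s`, `duration_s`, `strength`.
#' @export
classify_trial <- function(bouts, stim_onset_s, induction_window_s = 8) {
  stopifnot(is.data.frame(bouts))
  pre <- any(bouts$start_s < stim_onset_s)
  post <- bouts[bouts$start_s >= stim_onset_s, , drop = FALSE]
  if (nrow(post) == 0) {
    res <- data.frame(
      pre_stimulus_active = pre, induced = FALSE,
      latency_s = NA_real_, duration_s = NA_real_, strength = NA_real_
    )
  } else {
    first <- post[which.min(post$start_s), ]
    lat <- first$start_s - stim_onset_s
    res <- data.frame(
      pre_stimulus_active = pre,
      induced = lat <= induction_window_s,
      latency_s = lat,
      duration_s = first$end_s - first$start_s,
      strength = first$peak_displacement
    )
  }
  class(res) <- c("LocomotionTrialResult", "data.frame")
  res
}

#' Per-larva locomotion rate
#'
#' Percentage of trials in which a bout was induced within the induction
#' window, excluding trials with pre-stimulus movement from the denominator.
#'
#' @param trials A data.frame with logical columns `induced` and
#'   `pre_stimulus_active` (one row per trial for one larva).
#' @return Percentage in \[0, 100\].
#' @export
locomotion_rate <- function(trials) {
  stopifnot(is.data.frame(trials))
  counted <- trials[!trials$pre_stimulus_active, , drop = FALSE]
  if (nrow(counted) == 0) {
    stop("all trials excluded (pre-stimulus movement)", call. = FALSE)
  }
  100 * sum(counted$induced) / nrow(counted)
}

#' Locomotion-inhibition rate
#'
#' For trials with ongoing (white-light-evoked) swimming at the moment of
#' opsin stimulation: a trial counts as a locomotion-inhibition trial when
#' the ongoing bout ends within `stop_window_s` of the stimulation onset.
#' Trials without an ongoing bout at onset are excluded with a warning.
#'
#' @param trials A list, one element per trial, each a list with `bouts`
#'   (bout data.frame) and `stim_onset_s`.
#' @param stop_window_s Stop window (s), default 1.
#' @return Percentage of inhibition trials among the evaluable trials.
#' @export
inhibition_rate <- function(trials, stop_window_s = 1) {
  flags <- logical(0)
  for (tr in trials) {
    b <- tr$bouts
    ongoing <- b[b$start_s < tr$stim_onset_s & b$end_s >= tr$stim_onset_s, ,
      drop = FALSE
    ]
    if (nrow(ongoing) == 0) {
      warning("trial without ongoing bout at stimulation onset excluded")
      next
    }
    flags <- c(flags, ongoing$end_s[1] <= tr$stim_onset_s + stop_window_s)
  }
  if (length(flags) == 0) stop("no evaluable trials", call. = FALSE)
  100 * mean(flags)
}
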