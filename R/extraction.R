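#' ROI mask from a polygon
#'
#' Rasterizes a closed polygon (vertex coordinates in pixel units, x =
#' column, y = row) onto an image grid: a pixel belongs to the ROI when its
#' center lies inside the polygon.
#'
#' @param x,y Polygon vertex coordinates (pixels).
#' @param dim Integer `c(height, width)` of the target image.
#' @return A logical `height x width` mask.
#' @export
roi_from_polygon <- function(x, y, dim) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("polygon needs at least 3 vertices", call. = FALSE)
  }
  nr <- dim[1]
  nc <- dim[2]
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), times = nc)
  inside <- mgcv::in.out(cbind(c(x, x[1]), c(y, y[1])), cbind(px, py))
  matrix(inside, nr, nc)
}

#' Mean ROI luminosity per frame
#'
#' The mean pixel intensity inside the ROI, frame by frame — the raw
#' heartbeat readout. Linear in pixel intensities by construction.
#'
#' @param stack A [frame_stack()].
#' @param roi Logical mask matching the frame dimensions; must be non-empty.
#' @param label Label attached to the returned trace.
#' @return A [time_series()] with `t = (0:(n-1)) / fps` (frames timestamped
#'   at frame start, origin at the first frame).
#' @export
extract_roi_luminosity <- function(stack, roi, label = "roi") {
  stopifnot(inherits(stack, "FrameStack"))
  d <- dim(stack$frames)
  if (!is.matrix(roi) || !identical(dim(roi), d[1:2])) {
    stop("roi mask must match the frame dimensions", call. = FALSE)
  }
  roi <- roi & !is.na(roi)
  if (!any(roi)) stop("roi mask is empty", call. = FALSE)
  idx <- which(roi)
  n <- d[3]
  v <- vapply(seq_len(n), function(f) {
    mean(stack$frames[, , f][idx])
  }, numeric(1))
  time_series((seq_len(n) - 1) / stack$fps, v, label = label)
}

#' Normalize a fluorescence trace to delta-F/F
#'
#' `dff = (F - F0) / F0`, with the baseline `F0` chosen by convention:
#' the fluorescence at the stimulus-onset sample (`"stim_onset"`), the mean
#' over a window immediately before the stimulus (`"pre_stimulus"`), or the
#' mean over a user-marked post-resumption window (`"steady_state"`).
#'
#' @param F A [time_series()] fluorescence trace.
#' @param convention One of `"stim_onset"`, `"pre_stimulus"`,
#'   `"steady_state"`.
#' @param stim A [light_schedule()] or a numeric stimulus-onset time (s);
#'   required for the first two conventions.
#' @param baseline_window_s Length of the pre-stimulus baseline window (s),
#'   default 2.
#' @param steady_window Numeric `c(start_s, end_s)` of the steady-state
#'   window; required for (and only used by) `"steady_state"`.
#' @return An object of class `"DffTrace"`: data.frame with `t` and `dff`,
#'   attributes `F0` and `baseline_convention`.
#' @export
compute_dff <- function(F, convention = c("stim_onset", "pre_stimulus",
                                          "steady_state"),
                        stim = NULL, baseline_window_s = 2,
                        steady_window = NULL) {
  stopifnot(is_time_series(F))
  convention <- match.arg(convention)

  onset <- NULL
  if (convention %in% c("stim_onset", "pre_stimulus")) {
    if (is.null(stim)) {
      stop("stim is required for the ", convention, " convention",
        call. = FALSE
      )
    }
    onset <- if (inherits(stim, "LightSchedule")) {
      if (nrow(stim) == 0) stop("stimulus schedule is empty", call. = FALSE)
      min(stim$start_s)
    } else {
      as.numeric(stim)[1]
    }
  }

  F0 <- switch(convention,
    stim_onset = F$v[which.min(abs(F$t - onset))],
    pre_stimulus = {
      idx <- F$t >= onset - baseline_window_s & F$t < onset
      if (!any(idx)) {
        stop("no samples in the pre-stimulus baseline window", call. = FALSE)
      }
      mean(F$v[idx])
    },
    steady_state = {
      if (is.null(steady_window) || length(steady_window) != 2) {
        stop("steady_state convention requires a marked steady_window",
          call. = FALSE
        )
      }
      idx <- F$t >= steady_window[1] & F$t <= steady_window[2]
      if (!any(idx)) {
        stop("no samples in the steady-state window", call. = FALSE)
      }
      mean(F$v[idx])
    }
  )
  if (!is.finite(F0) || F0 <= 0) {
    stop("baseline F0 must be > 0", call. = FALSE)
  }

  out <- data.frame(t = F$t, dff = (F$v - F0) / F0)
  attr(out, "F0") <- F0
  attr(out, "baseline_convention") <- convention
  class(out) <- c("DffTrace", "data.frame")
  out
}

#' Heart area ratio over time
#'
#' Segments the heart in each frame (Otsu threshold on a temporally smoothed
#' stack, then the largest connected component) and reports the foreground
#' pixel count divided by the count at the frame nearest `t0_arrest_s` — the
#' relative heart-size trace used to read relaxation versus contraction after
#' arrest.
#'
#' @param stack A [frame_stack()].
#' @param t0_arrest_s Reference time (arrest onset); must lie in the record.
#' @param smooth_frames Width (frames, odd) of the temporal running mean
#'   applied before thresholding.
#' @return A [time_series()] of the area ratio (exactly 1 at the reference
#'   frame); the per-frame pixel counts are attached as attribute
#'   `area_px`.
#' @export
measure_heart_area <- function(stack, t0_arrest_s, smooth_frames = 5) {
  stopifnot(inherits(stack, "FrameStack"))
  d <- dim(stack$frames)
  n <- d[3]
  t <- (seq_len(n) - 1) / stack$fps
  if (t0_arrest_s < t[1] - 1e-9 || t0_arrest_s > t[n] + 1e-9) {
    stop("t0_arrest_s must lie within the record", call. = FALSE)
  }

  sm <- stack$frames
  if (smooth_frames >= 3 && n >= smooth_frames) {
    half <- floor(smooth_frames / 2)
    csum <- array(0, dim = c(d[1], d[2], n + 1))
    for (f in seq_len(n)) csum[, , f + 1] <- csum[, , f] + stack$frames[, , f]
    for (f in seq_len(n)) {
      lo <- max(1, f - half)
      hi <- min(n, f + half)
      sm[, , f] <- (csum[, , hi + 1] - csum[, , lo]) / (hi - lo + 1)
    }
  }

  # one global threshold, from the temporal mean image: per-frame thresholds
  # would track the pulsing fill intensity and flip between structures
  rng <- range(sm)
  span <- max(rng[2] - rng[1], .Machine$double.eps)
  mean_img <- (apply(sm, c(1, 2), mean) - rng[1]) / span
  th <- EBImage::otsu(mean_img, range = c(0, 1))
  area <- vapply(seq_len(n), function(f) {
    fg <- (sm[, , f] - rng[1]) / span > th
    if (!any(fg)) {
      return(0)
    }
    lab <- EBImage::bwlabel(fg)
    max(tabulate(lab[lab > 0]))
  }, numeric(1))

  ref <- which.min(abs(t - t0_arrest_s))
  if (area[ref] == 0) {
    stop("zero segmented area at the reference frame", call. = FALSE)
  }
  out <- time_series(t - t[ref], area / area[ref], label = "area_ratio")
  attr(out, "area_px") <- area
  out
}
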