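#' Frame stack container
#'
#' @param frames Numeric array `height x width x n_frames`, values in
#'   \[0, 1\] (grayscale).
#' @param fps Frames per second.
#' @return An object of class `"FrameStack"`.
#' @export
frame_stack <- function(frames, fps) {
  if (length(dim(frames)) == 2) {
    frames <- array(frames, dim = c(dim(frames), 1))
  }
  if (length(dim(frames)) != 3) {
    stop("frames must be a height x width x n array", call. = FALSE)
  }
  if (dim(frames)[3] < 1) stop("frame count must be >= 1", call. = FALSE)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  structure(list(frames = frames, fps = fps), class = "FrameStack")
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<FrameStack: %d frames of %dx%d at %.6g fps>\n", d[3], d[1], d[2], x$fps
  ))
  invisible(x)
}

ellipse_mask <- function(nr, nc, cy, cx, ry, rx) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}

#' Render synthetic two-chamber heart frames
#'
#' Draws two pulsating-ellipse regions (atrium and ventricle) whose uniform
#' fill intensity follows the two input traces, affinely rescaled into
#' \[`fill_lo`, 1\] over a dark background, so that the ROI-mean luminosity
#' reproduces the input traces up to affine scaling. The ellipse areas can
#' optionally be modulated over time.
#'
#' @param atrium,ventricle [time_series()] traces on the same grid.
#' @param image_size Integer edge length of the square frames (>= 32).
#' @param seed Integer seed for the pixel noise (mandatory).
#' @param noise_sd Pixel Gaussian noise SD (on the \[0, 1\] intensity scale).
#' @param area_scale Optional numeric vector (one value per frame)
#'   multiplying the *area* of both ellipses (radii scale by its square
#'   root); default constant 1.
#' @param fill_lo Lower end of the intensity range the traces are mapped to.
#' @return A list with `stack` (a [frame_stack()]), `rois` (named list of
#'   logical masks, at unit area scale), and `scaling` (the affine map
#'   applied to each trace).
#' @export
render_heart_frames <- function(atrium, ventricle, image_size = 96, seed,
                                noise_sd = 0, area_scale = NULL,
                                fill_lo = 0.2) {
  stopifnot(is_time_series(atrium), is_time_series(ventricle))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  n <- length(atrium$t)
  if (length(ventricle$t) != n) {
    stop("atrium and ventricle traces must share a grid", call. = FALSE)
  }
  if (is.null(area_scale)) area_scale <- rep(1, n)
  if (length(area_scale) != n || any(area_scale <= 0)) {
    stop("area_scale must be positive with one value per frame", call. = FALSE)
  }

  sz <- as.integer(image_size)
  geom <- list(
    atrium = c(cy = sz / 2, cx = sz * 0.28, ry = sz * 0.14, rx = sz * 0.16),
    ventricle = c(cy = sz / 2, cx = sz * 0.72, ry = sz * 0.17, rx = sz * 0.19)
  )
  smax <- sqrt(max(area_scale))
  m_a <- ellipse_mask(sz, sz, geom$atrium["cy"], geom$atrium["cx"],
    geom$atrium["ry"] * smax, geom$atrium["rx"] * smax
  )
  m_v <- ellipse_mask(sz, sz, geom$ventricle["cy"], geom$ventricle["cx"],
    geom$ventricle["ry"] * smax, geom$ventricle["rx"] * smax
  )
  if (any(m_a & m_v)) {
    stop("atrium and ventricle regions overlap at this size", call. = FALSE)
  }

  rescale <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) {
      list(v = rep((fill_lo + 1) / 2, length(v)), a = 0, b = (fill_lo + 1) / 2)
    } else {
      a <- (1 - fill_lo) / diff(rng)
      list(v = fill_lo + (v - rng[1]) * a, a = a, b = fill_lo - rng[1] * a)
    }
  }
  fa <- rescale(atrium$v)
  fv <- rescale(ventricle$v)

  frames <- array(0, dim = c(sz, sz, n))
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(sz * sz * n, 0, noise_sd))
  } else {
    NULL
  }
  for (f in seq_len(n)) {
    s <- sqrt(area_scale[f])
    img <- matrix(0, sz, sz)
    ma <- ellipse_mask(sz, sz, geom$atrium["cy"], geom$atrium["cx"],
      geom$atrium["ry"] * s, geom$atrium["rx"] * s
    )
    mv <- ellipse_mask(sz, sz, geom$ventricle["cy"], geom$ventricle["cx"],
      geom$ventricle["ry"] * s, geom$ventricle["rx"] * s
    )
    img[ma] <- fa$v[f]
    img[mv] <- fv$v[f]
    frames[, , f] <- img
  }
  if (!is.null(noise)) {
    frames <- pmin(pmax(frames + array(noise, dim = dim(frames)), 0), 1)
  }

  roi_a <- ellipse_mask(sz, sz, geom$atrium["cy"], geom$atrium["cx"],
    geom$atrium["ry"], geom$atrium["rx"]
  )
  roi_v <- ellipse_mask(sz, sz, geom$ventricle["cy"], geom$ventricle["cx"],
    geom$ventricle["ry"], geom$ventricle["rx"]
  )
  list(
    stack = frame_stack(frames, fps = atrium$fps),
    rois = list(atrium = roi_a, ventricle = roi_v),
    scaling = list(
      atrium = c(slope = fa$a, intercept = fa$b),
      ventricle = c(slope = fv$a, intercept = fv$b)
    )
  )
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' @param stack A [frame_stack()]; intensities must lie in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "FrameStack"))
  fr <- stack$frames
  if (min(fr) < 0 || max(fr) > 1) {
    stop("frame intensities must lie in [0, 1] for TIFF output", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(fr)[3]), function(i) fr[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path Path to the TIFF file.
#' @param fps Frames per second; there is no in-band frame rate in TIFF, so
#'   it must be supplied (an error otherwise).
#' @param rgb One of `"convert"` (average RGB channels to gray, with a
#'   warning) or `"reject"`.
#' @return A [frame_stack()].
#' @export
read_tiff_stack <- function(path, fps, rgb = c("convert", "reject")) {
  rgb <- match.arg(rgb)
  if (missing(fps) || is.null(fps) || is.na(fps)) {
    stop("fps must be supplied when reading a TIFF stack", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      if (rgb == "reject") {
        stop("RGB TIFF rejected (grayscale required)", call. = FALSE)
      }
      warning("RGB TIFF converted to grayscale by channel averaging")
      p <- apply(p, c(1, 2), mean)
    }
    p
  })
  d <- dim(pages[[1]])
  frames <- array(unlist(pages), dim = c(d[1], d[2], length(pages)))
  frame_stack(frames, fps = fps)
}
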