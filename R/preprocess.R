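# Offsets of a disk neighbourhood of given radius (centre included).
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= radius^2, , drop = FALSE]
}

# Ball-cap structuring element: offsets within `radius` with height
# sqrt(radius^2 - r^2), the classic rolling-ball structuring function.
ball_se <- function(radius) {
  g <- disk_offsets(radius)
  g$h <- sqrt(radius^2 - g$di^2 - g$dj^2)
  g
}

#' Parameters of the image-conditioning chain
#'
#' @param ball_radius Rolling-ball radius in pixels (about 1 um at the
#'   default sampling; the ball must be wider than a vesicle spot).
#' @param despeckle_window Median-filter window (odd, >= 3).
#' @param outlier_radius Disk radius for outlier removal, pixels.
#' @param outlier_threshold Deviation from the local median beyond which a
#'   pixel is replaced.  `NULL` picks a per-frame spike threshold,
#'   `max(6 * sigma_MAD, 0.45 * (max - median))`, which removes isolated
#'   spikes while sparing smooth vesicle peaks.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(ball_radius = 10, despeckle_window = 3,
                              outlier_radius = 2, outlier_threshold = NULL) {
  if (ball_radius < 1) stop("ball_radius must be >= 1")
  if (despeckle_window < 3 || despeckle_window %% 2 == 0)
    stop("despeckle_window must be odd and >= 3")
  if (outlier_radius < 1) stop("outlier_radius must be >= 1")
  if (!is.null(outlier_threshold) && outlier_threshold < 0)
    stop("outlier_threshold must be >= 0")
  structure(list(ball_radius = ball_radius,
                 despeckle_window = despeckle_window,
                 outlier_radius = outlier_radius,
                 outlier_threshold = outlier_threshold),
            class = "preprocess_params")
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of an image by grayscale opening with a
#' ball-cap structuring element (a ball of the given radius rolled under
#' the intensity surface) and subtracts it.  Features narrower than the
#' ball are preserved; the result is non-negative everywhere.
#'
#' @param image Numeric matrix.
#' @param ball_radius Ball radius in pixels (>= 1).
#' @return Background-subtracted matrix of the same shape.
#' @export
rolling_ball <- function(image, ball_radius) {
  if (!is.matrix(image)) stop("image must be a 2-D raster")
  if (ball_radius < 1) stop("ball_radius must be >= 1")
  se <- ball_se(ball_radius)
  er <- cpp_gray_morph(image, se$di, se$dj, se$h, TRUE)
  bg <- cpp_gray_morph(er, se$di, se$dj, se$h, FALSE)
  pmax(image - bg, 0)
}

#' Despeckle (median) filter
#'
#' Replaces each pixel by the median of its `window` x `window`
#' neighbourhood (reflective edge padding), the ImageJ de-speckle
#' operation generalised to any odd window.
#'
#' @param image Numeric matrix.
#' @param window Odd window width >= 3.
#' @return Filtered matrix.
#' @export
despeckle <- function(image, window = 3) {
  if (!is.matrix(image)) stop("image must be a 2-D raster")
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  r <- (window - 1) / 2
  g <- expand.grid(di = -r:r, dj = -r:r)
  cpp_median_filter(image, g$di, g$dj)
}

#' Remove single-pixel outliers
#'
#' Pixels deviating from the median of their disk neighbourhood (centre
#' included) by more than `threshold` are replaced by that median; all
#' other pixels are untouched.
#'
#' @param image Numeric matrix.
#' @param radius Disk radius in pixels (>= 1).
#' @param threshold Intensity deviation above which a pixel is replaced.
#' @return Filtered matrix.
#' @export
remove_outliers <- function(image, radius = 2, threshold) {
  if (!is.matrix(image)) stop("image must be a 2-D raster")
  if (radius < 1) stop("radius must be >= 1")
  if (threshold < 0) stop("threshold must be >= 0")
  g <- disk_offsets(radius)
  cpp_remove_outliers(image, g$di, g$dj, threshold)
}

# Spike threshold used when preprocess_params$outlier_threshold is NULL:
# 6 robust sigma catches spikes on flat frames; the 0.45 * (max - median)
# term keeps the threshold above the deviation a smooth Gaussian spot
# shows against its local median (~0.36 * amplitude), so real vesicles
# are spared while isolated hot pixels are still removed.
default_outlier_threshold <- function(image) {
  med <- stats::median(image)
  max(6 * stats::mad(image), 0.45 * (max(image) - med))
}

#' Run the full conditioning chain on a movie
#'
#' Applies, frame by frame, rolling-ball background subtraction, then the
#' despeckle median filter, then outlier removal.  Geometry, insulin frame
#' and frame times are preserved.
#'
#' @param movie A [tirf_movie()].
#' @param params A [preprocess_params()].
#' @return A [tirf_movie()] with conditioned frames.
#' @export
preprocess_stack <- function(movie, params = preprocess_params()) {
  stopifnot(inherits(movie, "tirf_movie"),
            inherits(params, "preprocess_params"))
  d <- dim(movie$frames)
  out <- array(0, dim = d)
  for (f in seq_len(d[3])) {
    img <- rolling_ball(movie$frames[, , f], params$ball_radius)
    img <- despeckle(img, params$despeckle_window)
    thr <- if (is.null(params$outlier_threshold))
      default_outlier_threshold(img) else params$outlier_threshold
    out[, , f] <- remove_outliers(img, params$outlier_radius, thr)
  }
  tirf_movie(pmax(out, 0), movie$geometry, movie$insulin_frame,
             frame_times = movie$frame_times,
             insulin_time = movie$insulin_time)
}
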