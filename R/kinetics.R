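#' Segment the adherent cell footprint from a reference image
#'
#' Global Otsu threshold on the reference (typically the temporal mean of
#' the pre-insulin frames), holes filled, largest connected component
#' retained.  The reference is first opened with a flat disk
#' (`smooth_radius` px) so that bright punctate vesicles — which would
#' otherwise dominate the intensity histogram — are levelled down to the
#' diffuse footprint elevation they sit on; the opening preserves the
#' footprint's own extent.
#'
#' @param reference Numeric matrix.
#' @param geometry Optional [acquisition_geometry()] used to report the
#'   footprint area in um^2.
#' @param smooth_radius Radius (px) of the flat structuring disk; should
#'   exceed the vesicle spot radius and stay below the footprint scale.
#' @return List of class `footprint_mask`: `mask` (logical matrix),
#'   `area_um2` (or `NA`), `threshold`.
#' @export
footprint_mask <- function(reference, geometry = NULL, smooth_radius = 5) {
  if (!is.matrix(reference)) stop("reference must be a 2-D raster")
  rng <- range(reference)
  if (!all(is.finite(rng)) || diff(rng) <= .Machine$double.eps * 100)
    stop("reference is blank or near-constant: no footprint found")
  se <- disk_offsets(smooth_radius)
  er <- cpp_gray_morph(reference, se$di, se$dj, rep(0, nrow(se)), TRUE)
  smooth <- cpp_gray_morph(er, se$di, se$dj, rep(0, nrow(se)), FALSE)
  rng <- range(smooth)
  if (diff(rng) <= .Machine$double.eps * 100)
    stop("reference is blank or near-constant: no footprint found")
  norm <- (smooth - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (!any(bw)) stop("no foreground above the Otsu threshold")
  lab <- EBImage::bwlabel(bw)
  lab <- EBImage::fillHull(lab)
  lab <- EBImage::bwlabel(lab > 0)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  mask <- matrix(as.integer(lab) == which.max(sizes), nrow(reference),
                 ncol(reference))
  area <- if (is.null(geometry)) NA_real_
    else sum(mask) * geometry$pixel_size^2
  structure(list(mask = mask, area_um2 = area,
                 threshold = thr * diff(rng) + rng[1]),
            class = "footprint_mask")
}

#' Mean footprint intensity at discrete time points
#'
#' Groups frames into consecutive blocks of `frames_per_timepoint` (the
#' burst of frames acquired at each time point) and returns, per block,
#' the mean intensity over the footprint pixels, with times at block
#' midpoints relative to insulin addition.
#'
#' @param movie A [tirf_movie()].
#' @param mask A [footprint_mask()] (or logical matrix) matching the frame
#'   shape.
#' @param frames_per_timepoint Frames per time point (default 10).
#' @param background `"none"` (the plain masked mean) or `"outside"`:
#'   subtract, per time point, the median intensity outside the mask.
#'   Background-subtracted movies retain a positive noise pedestal
#'   (clipping noise at zero biases it upward), which dilutes fold
#'   changes; an off-cell reference region removes it.
#' @return Data frame `t_min`, `intensity`.
#' @export
intensity_series <- function(movie, mask, frames_per_timepoint = 10,
                             background = c("none", "outside")) {
  stopifnot(inherits(movie, "tirf_movie"))
  background <- match.arg(background)
  m <- if (inherits(mask, "footprint_mask")) mask$mask else mask
  d <- dim(movie$frames)
  if (!identical(dim(m), d[1:2]))
    stop("mask shape does not match movie frames")
  if (!any(m)) stop("mask is empty")
  if (background == "outside" && !any(!m)) {
    warning("mask covers the whole frame; no outside region, using ",
            "background = \"none\"")
    background <- "none"
  }
  nT <- d[3]
  n_groups <- nT %/% frames_per_timepoint
  if (n_groups < 1L) stop("movie shorter than one time point")
  t_min <- numeric(n_groups); val <- numeric(n_groups)
  midx <- which(m)
  oidx <- which(!m)
  npx <- length(midx)
  for (g in seq_len(n_groups)) {
    idx <- ((g - 1L) * frames_per_timepoint + 1L):
      (g * frames_per_timepoint)
    acc <- 0; bg <- 0
    for (f in idx) {
      fr <- movie$frames[, , f]
      acc <- acc + sum(fr[midx])
      if (background == "outside") bg <- bg + stats::median(fr[oidx])
    }
    val[g] <- acc / (npx * frames_per_timepoint) -
      bg / frames_per_timepoint
    t_min[g] <- (mean(movie$frame_times[idx]) - movie$insulin_time) / 60
  }
  data.frame(t_min = t_min, intensity = val)
}

#' Saturating-exponential translocation model
#'
#' `R(t) = 1` for `t < 0` and `R(t) = 1 + (A - 1) * (1 - 2^(-t / t_half))`
#' for `t >= 0`: a rise from the unit baseline to the plateau fold `A`
#' with half-time `t_half` (time to reach half of `A - 1`).
#'
#' @param t Times in minutes relative to insulin addition.
#' @param A Plateau fold-increase.
#' @param t_half Half-time, minutes.
#' @return Model values.
#' @export
translocation_model <- function(t, A, t_half) {
  ifelse(t < 0, 1, 1 + (A - 1) * (1 - 2^(-t / t_half)))
}

#' Fit insulin-stimulated translocation kinetics
#'
#' Normalises the intensity series to a pre-insulin mean of 1 and fits the
#' saturating-exponential [translocation_model()] by least squares over
#' all time points (pre-insulin model value is 1).  Returns the plateau
#' fold `A` and half-time `t_half`; a flat series is flagged as a null
#' response with `t_half = NA`.
#'
#' When the half-time approaches the observation window the plateau is an
#' extrapolation and the two parameters trade off almost freely; to keep
#' estimates identifiable the fit bounds `A` at three times the observed
#' rise and `t_half` at three times the last observation, and flags an
#' estimate that lands on a bound (`at_bound`).
#'
#' @param times Time points, minutes relative to insulin (negative =
#'   baseline).
#' @param series Intensities (or a data frame from [intensity_series()] as
#'   `times`, in which case `series` may be omitted).
#' @param min_pre,min_post Minimum numbers of baseline and stimulated
#'   time points.
#' @return Object of class `translocation_fit`: `times`,
#'   `normalized_intensity`, `A` (fold), `t_half` (min), `rss`,
#'   `fold_final` (mean of the last 3 time points), `converged`, `null_response`.
#' @export
fit_translocation <- function(times, series = NULL, min_pre = 3,
                              min_post = 5) {
  if (is.data.frame(times)) {
    series <- times$intensity
    times <- times$t_min
  }
  stopifnot(length(times) == length(series))
  pre <- times < 0
  if (sum(pre) < min_pre)
    stop(sprintf("need >= %d pre-insulin time points", min_pre))
  if (sum(!pre) < min_post)
    stop(sprintf("need >= %d post-insulin time points", min_post))
  base <- mean(series[pre])
  if (base <= 0) stop("non-positive pre-insulin baseline")
  y <- series / base
  null_fit <- function(flag) {
    rss0 <- sum((y - 1)^2)
    structure(list(times = times, normalized_intensity = y, A = 1,
                   t_half = NA_real_, rss = rss0,
                   fold_final = mean(utils::tail(y, 3)),
                   converged = flag, null_response = TRUE),
              class = "translocation_fit")
  }
  post_amp <- mean(y[times >= max(times) / 2]) - 1
  if (stats::sd(y) < 1e-12 || abs(post_amp) < 1e-12) return(null_fit(TRUE))
  A0 <- max(1 + post_amp, 1.01)
  half_level <- 1 + (A0 - 1) / 2
  cross <- which(!pre & y >= half_level)
  th0 <- if (length(cross)) max(times[cross[1]], 1e-2) else max(times) / 3
  dat <- data.frame(t = times, y = y)
  A_max <- 1 + 3 * max(max(y) - 1, 0.1)
  th_max <- 3 * max(times)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ifelse(t < 0, 1, 1 + (A - 1) * (1 - 2^(-t / th))),
      data = dat, start = list(A = min(A0, A_max), th = min(th0, th_max)),
      lower = c(A = 0, th = 1e-6),
      upper = c(A = A_max, th = th_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- null_fit(FALSE)
    out$null_response <- FALSE
    out$diagnostics <- conditionMessage(fit)
    return(out)
  }
  cf <- stats::coef(fit)
  at_bound <- cf["A"] >= A_max * (1 - 1e-6) ||
    cf["th"] >= th_max * (1 - 1e-6)
  structure(list(times = times, normalized_intensity = y,
                 A = unname(cf["A"]), t_half = unname(cf["th"]),
                 rss = sum(stats::resid(fit)^2),
                 fold_final = mean(utils::tail(y, 3)),
                 converged = TRUE, at_bound = unname(at_bound),
                 null_response = FALSE),
            class = "translocation_fit")
}

#' @export
print.translocation_fit <- function(x, ...) {
  cat("Translocation fit\n")
  cat(sprintf("  plateau fold A : %.3f\n", x$A))
  cat(sprintf("  half-time      : %s min\n",
              ifelse(is.na(x$t_half), "undefined (null response)",
                     sprintf("%.3f", x$t_half))))
  cat(sprintf("  final fold     : %.3f\n", x$fold_final))
  cat(sprintf("  rss            : %.4g; converged: %s\n",
              x$rss, x$converged))
  invisible(x)
}

#' Estimate the evanescent penetration depth from a bead image
#'
#' A large bead of known diameter maps lateral offset `r` from its contact
#' point to height `z(r) = R - sqrt(R^2 - r^2)`.  Intensities are
#' aggregated in 1-px annuli (mean height and mean log-intensity per
#' annulus; log-intensity is exactly linear in `z`, so the geometric mean
#' avoids the curvature bias of arithmetic annulus means) and
#' log-intensity is regressed on height over the range `z <= 3 x` the
#' current depth estimate, iterated to self-consistency; the depth is
#' `-1 / slope`.
#'
#' @param bead_image Numeric matrix from a bead acquisition.
#' @param bead_diameter Bead diameter, micrometres.
#' @param geometry An [acquisition_geometry()] (pixel size).
#' @param initial_depth Starting depth guess, nm.
#' @return Estimated penetration depth, nm.
#' @export
estimate_penetration_depth <- function(bead_image, bead_diameter = 10,
                                       geometry = acquisition_geometry(),
                                       initial_depth = 200) {
  if (!is.matrix(bead_image)) stop("bead_image must be a 2-D raster")
  if (bead_diameter <= 10 * geometry$pixel_size)
    stop("bead diameter must be much larger than the pixel size")
  R_nm <- bead_diameter / 2 * 1000
  # contact point: centroid of the brightest region
  mx <- max(bead_image)
  if (mx <= 0) stop("blank bead image")
  bright <- which(bead_image >= 0.5 * mx, arr.ind = TRUE)
  cy <- mean(bright[, 1]) ; cx <- mean(bright[, 2])
  ri <- row(bead_image) - cy; ci <- col(bead_image) - cx
  r_nm <- sqrt(ri^2 + ci^2) * geometry$pixel_size * 1000
  sel <- r_nm < R_nm & bead_image > 0
  z <- (R_nm - sqrt(pmax(R_nm^2 - r_nm[sel]^2, 0)))
  logi <- log(bead_image[sel])
  ann <- floor(r_nm[sel] / (geometry$pixel_size * 1000))
  zbar <- tapply(z, ann, mean)
  lbar <- tapply(logi, ann, mean)
  npx <- tapply(z, ann, length)
  d <- initial_depth
  for (it in 1:4) {
    use <- zbar <= 3 * d
    if (sum(use) < 3) use <- seq_along(zbar) <= 5
    fit <- stats::lm(lbar[use] ~ zbar[use], weights = npx[use])
    slope <- stats::coef(fit)[2]
    if (!is.finite(slope) || slope >= 0)
      stop("intensity profile does not decay: not evanescent")
    d <- -1 / slope
  }
  unname(d)
}
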