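#' Synthetic TIRF movie configuration
#'
#' Describes the ground-truth scene for [simulate_tirf_movie()]: a field of
#' docked (static) and slowly diffusing (mobile) GLUT4 vesicles under
#' evanescent illumination whose densities relax from a pre-insulin to a
#' post-insulin level after the insulin-addition time.
#'
#' Static (docked) vesicles persist at fixed positions; their density is
#' vesicles per 100 um^2.  Mobile vesicles are transient visitors to the
#' evanescent zone: they arrive as a Poisson process, dwell for an
#' exponential time (`dwell_time`, seconds) while diffusing laterally,
#' then leave; `mobile_density_*` is the expected number of distinct
#' visits per 100 um^2 per one-minute analysis bin — the quantity a
#' per-bin foci count measures.  Density changes after insulin follow a
#' single-exponential relaxation with half-time `transition_halftime`
#' (minutes), the simplest monotone approach to a plateau.  Vesicle depth
#' `z` is drawn uniformly on `[0, vesicle_z_range]` nm and the rendered
#' amplitude is `vesicle_brightness * exp(-z / penetration_depth)`.
#'
#' @param field_size Field dimensions in pixels, `c(H, W)` (a scalar is
#'   square).
#' @param duration_pre,duration_post Seconds of acquisition before and
#'   after insulin addition.
#' @param static_density_pre,static_density_post Docked-vesicle densities
#'   per 100 um^2 before insulin and at the post-insulin plateau.
#' @param mobile_density_pre,mobile_density_post Mobile-vesicle visit
#'   rates, distinct visits per 100 um^2 per minute.
#' @param diffusion_coeff Lateral diffusion coefficient of mobile vesicles
#'   while in the evanescent zone, um^2/s.  The default 0.003 um^2/s is
#'   the slow sub-micrometre wobble of near-membrane carriers (~0.2 um RMS
#'   over a 6-s visit).
#' @param dwell_time Mean dwell of a mobile vesicle in the evanescent
#'   zone, seconds (exponentially distributed).
#' @param transition_halftime Half-time of the post-insulin density
#'   relaxation, minutes.
#' @param vesicle_brightness Photons at `z = 0`.
#' @param vesicle_z_range Vesicle depths are uniform on `[0, this]`, nm.
#' @param background_offset,background_amplitude Flat offset and peak
#'   amplitude of the smooth uneven background (low-order polynomial plus
#'   wide Gaussian blobs), intensity units.
#' @param read_noise_sd Gaussian read noise, intensity units (0 disables).
#' @param poisson_noise Apply Poisson photon noise? (`FALSE` with
#'   `read_noise_sd = 0` gives a fully deterministic rendering.)
#' @param footprint_radius Optional radius (um) of a circular cell
#'   footprint centred in the field; vesicles are confined to it
#'   (reflected at its edge) and a diffuse membrane glow of
#'   `footprint_intensity` is added inside.  `NULL` = cell fills the field.
#' @param footprint_intensity Diffuse intensity inside the footprint.
#' @param acquisition Either `"continuous"` (every `frame_interval`) or a
#'   list `list(timepoint_interval =, frames_per_timepoint =)` for the
#'   discrete-timepoint protocol (a burst of frames at each time point).
#' @param seed Integer; fixes the realisation bit-exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(field_size = c(128L, 128L),
                       duration_pre = 120, duration_post = 1500,
                       static_density_pre = 4, static_density_post = 3,
                       mobile_density_pre = 1, mobile_density_post = 2,
                       diffusion_coeff = 0.003, dwell_time = 6,
                       transition_halftime = 2,
                       vesicle_brightness = 2000, vesicle_z_range = 300,
                       background_offset = 20, background_amplitude = 10,
                       read_noise_sd = 3, poisson_noise = TRUE,
                       footprint_radius = NULL, footprint_intensity = 0,
                       acquisition = "continuous", seed = 1L) {
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  field_size <- as.integer(field_size)
  if (any(field_size <= 0L)) stop("field_size must be positive")
  dens <- c(static_density_pre, static_density_post,
            mobile_density_pre, mobile_density_post)
  if (any(dens < 0)) stop("densities must be >= 0")
  if (diffusion_coeff < 0) stop("diffusion_coeff must be >= 0")
  if (dwell_time <= 0) stop("dwell_time must be > 0")
  if (duration_pre < 0 || duration_post < 0)
    stop("durations must be >= 0")
  if (transition_halftime <= 0) stop("transition_halftime must be > 0")
  if (is.list(acquisition)) {
    stopifnot(acquisition$timepoint_interval > 0,
              acquisition$frames_per_timepoint >= 1)
  } else if (!identical(acquisition, "continuous")) {
    stop("acquisition must be \"continuous\" or a burst specification")
  }
  structure(list(field_size = field_size, duration_pre = duration_pre,
                 duration_post = duration_post,
                 static_density_pre = static_density_pre,
                 static_density_post = static_density_post,
                 mobile_density_pre = mobile_density_pre,
                 mobile_density_post = mobile_density_post,
                 diffusion_coeff = diffusion_coeff,
                 dwell_time = dwell_time,
                 transition_halftime = transition_halftime,
                 vesicle_brightness = vesicle_brightness,
                 vesicle_z_range = vesicle_z_range,
                 background_offset = background_offset,
                 background_amplitude = background_amplitude,
                 read_noise_sd = read_noise_sd,
                 poisson_noise = poisson_noise,
                 footprint_radius = footprint_radius,
                 footprint_intensity = footprint_intensity,
                 acquisition = acquisition, seed = as.integer(seed)),
            class = "sim_config")
}

# Smooth uneven background: offset + amplitude * S with S in [0, 1], a
# low-order 2-D polynomial plus three wide Gaussian blobs.
build_background <- function(field_size, offset, amplitude) {
  H <- field_size[1]; W <- field_size[2]
  u <- matrix(rep(seq(-1, 1, length.out = H), W), H, W)
  v <- matrix(rep(seq(-1, 1, length.out = W), each = H), H, W)
  a <- stats::runif(6, -1, 1)
  S <- a[1] + a[2] * u + a[3] * v + a[4] * u * v + a[5] * u^2 + a[6] * v^2
  for (b in 1:3) {
    cy <- stats::runif(1, 0, H); cx <- stats::runif(1, 0, W)
    sg <- stats::runif(1, 0.2, 0.4) * max(H, W)
    am <- stats::runif(1, 0.5, 1)
    row <- (seq_len(H) - 0.5 - cy)^2
    col <- (seq_len(W) - 0.5 - cx)^2
    S <- S + am * exp(-outer(row, col, "+") / (2 * sg^2))
  }
  rng <- range(S)
  if (diff(rng) > 0) S <- (S - rng[1]) / diff(rng)
  offset + amplitude * S
}

# Frame mid-exposure times (s) for a config; insulin occurs at t =
# duration_pre.
sim_frame_times <- function(config, geometry) {
  total <- config$duration_pre + config$duration_post
  dt <- geometry$frame_interval
  if (identical(config$acquisition, "continuous")) {
    n <- max(1L, floor(total / dt))
    (seq_len(n) - 0.5) * dt
  } else {
    tp <- config$acquisition$timepoint_interval
    k <- config$acquisition$frames_per_timepoint
    starts <- seq(0, total - k * dt, by = tp)
    as.numeric(outer((seq_len(k) - 0.5) * dt, starts, "+"))
  }
}

#' Simulate a TIRF time-lapse movie with per-vesicle ground truth
#'
#' Renders a movie of docked (static) and diffusing (mobile) vesicles under
#' evanescent illumination.  Each vesicle is a Gaussian spot of
#' `geometry$psf_sigma` (truncated at 4 sigma) with amplitude
#' `vesicle_brightness * exp(-z / penetration_depth)`.  Static vesicles
#' hold a fixed position and depth; mobile vesicles diffuse laterally with
#' `diffusion_coeff` and wrap across the field edge (or reflect at the cell
#' footprint).  After the insulin frame, class densities relax
#' exponentially from their pre- to post-insulin levels.  Poisson photon
#' noise, Gaussian read noise and a smooth uneven background are added.
#'
#' @param config A [sim_config()].
#' @param geometry An [acquisition_geometry()].
#' @return A list of class `tirf_simulation` with elements `movie` (a
#'   [tirf_movie()]), `truth` (data frame: `id`, `class`, `frame`, `x_px`,
#'   `y_px`, `z_nm`, `amplitude`; `x` = column, `y` = row, 0-based
#'   continuous coordinates) and `background` (the noise-free background
#'   raster).
#' @export
simulate_tirf_movie <- function(config, geometry = acquisition_geometry()) {
  stopifnot(inherits(config, "sim_config"),
            inherits(geometry, "acq_geometry"))
  H <- config$field_size[1]; W <- config$field_size[2]
  px <- geometry$pixel_size
  roi_side_px <- sqrt(100) / px
  if (H < roi_side_px || W < roi_side_px)
    stop(sprintf(
      "field too small: at least one 100 um^2 ROI (%.0f px side) must fit",
      roi_side_px))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  bg <- build_background(config$field_size, config$background_offset,
                         config$background_amplitude)
  fp_r <- if (is.null(config$footprint_radius)) NULL
    else config$footprint_radius / px
  cy <- H / 2; cx <- W / 2
  if (!is.null(fp_r)) {
    row2 <- (seq_len(H) - 0.5 - cy)^2
    col2 <- (seq_len(W) - 0.5 - cx)^2
    inside <- outer(row2, col2, "+") <= fp_r^2
    bg <- bg + config$footprint_intensity * inside
    area_units <- pi * (fp_r * px)^2 / 100
  } else {
    area_units <- H * W * px^2 / 100
  }

  times <- sim_frame_times(config, geometry)
  nT <- length(times)
  t_ins <- config$duration_pre
  th_s <- config$transition_halftime * 60
  target <- function(t, pre, post) {
    if (t <= t_ins) pre else post + (pre - post) * 2^(-(t - t_ins) / th_s)
  }

  place <- function(n) {
    if (n == 0L) return(cbind(y = numeric(0), x = numeric(0)))
    if (is.null(fp_r)) {
      cbind(y = stats::runif(n, 0, H), x = stats::runif(n, 0, W))
    } else {
      r <- fp_r * sqrt(stats::runif(n)); a <- stats::runif(n, 0, 2 * pi)
      cbind(y = cy + r * sin(a), x = cx + r * cos(a))
    }
  }
  new_vesicles <- function(n, state) {
    if (n == 0L) return(state)
    pos <- place(n)
    state$y <- c(state$y, pos[, "y"]); state$x <- c(state$x, pos[, "x"])
    state$z <- c(state$z, stats::runif(n, 0, config$vesicle_z_range))
    state$id <- c(state$id, state$next_id + seq_len(n) - 1L)
    state$next_id <- state$next_id + n
    state
  }

  # static: persistent docked vesicles at the target density
  # mobile: transient visitors; arrival rate lambda(t) [visits/min] times
  # area, exponential dwell, so the instantaneous count is
  # lambda * area * dwell/60 in steady state
  dwell <- config$dwell_time
  E0_static <- target(times[1], config$static_density_pre,
                      config$static_density_post) * area_units
  state <- list(
    static = new_vesicles(stats::rpois(1, E0_static),
                          list(y = numeric(0), x = numeric(0),
                               z = numeric(0), id = integer(0),
                               next_id = 1L)),
    mobile = list(y = numeric(0), x = numeric(0), z = numeric(0),
                  id = integer(0), expiry = numeric(0),
                  next_id = 1000001L))
  E_prev_static <- E0_static
  lambda0 <- target(times[1], config$mobile_density_pre,
                    config$mobile_density_post) * area_units
  n0 <- stats::rpois(1, lambda0 * dwell / 60)
  if (n0 > 0) {
    state$mobile <- new_vesicles(n0, state$mobile)
    state$mobile$expiry <- times[1] + stats::rexp(n0, 1 / dwell)
  }

  d_nm <- geometry$penetration_depth
  amp_of <- function(z) config$vesicle_brightness * exp(-z / d_nm)
  frames <- array(0, dim = c(H, W, nT))
  truth <- vector("list", nT)
  insulin_frame <- sum(times < t_ins)

  for (f in seq_len(nT)) {
    t <- times[f]
    dt_s <- if (f == 1L) 0 else times[f] - times[f - 1L]
    # mobile diffusion
    if (dt_s > 0 && config$diffusion_coeff > 0 &&
        length(state$mobile$id) > 0) {
      sd_px <- sqrt(2 * config$diffusion_coeff * dt_s) / px
      n <- length(state$mobile$id)
      state$mobile$y <- state$mobile$y + stats::rnorm(n, 0, sd_px)
      state$mobile$x <- state$mobile$x + stats::rnorm(n, 0, sd_px)
      if (is.null(fp_r)) {
        state$mobile$y <- state$mobile$y %% H
        state$mobile$x <- state$mobile$x %% W
      } else {
        dy <- state$mobile$y - cy; dx <- state$mobile$x - cx
        r <- sqrt(dy^2 + dx^2)
        out <- r > fp_r
        if (any(out)) {
          rr <- pmax(2 * fp_r - r[out], 0)  # radial reflection
          state$mobile$y[out] <- cy + dy[out] / r[out] * rr
          state$mobile$x[out] <- cx + dx[out] / r[out] * rr
        }
      }
    }
    # static density relaxation: spawn on increase, thin on decrease
    E_now <- target(t, config$static_density_pre,
                    config$static_density_post) * area_units
    dE <- E_now - E_prev_static
    if (dE > 0) {
      state$static <- new_vesicles(stats::rpois(1, dE), state$static)
    } else if (dE < 0 && length(state$static$id) > 0) {
      p <- min(1, -dE / max(E_prev_static, 1e-12))
      keep <- stats::runif(length(state$static$id)) >= p
      for (fld in c("y", "x", "z", "id"))
        state$static[[fld]] <- state$static[[fld]][keep]
    }
    E_prev_static <- E_now
    # mobile turnover: departures, then arrivals still present now.
    # Arrivals over (t - dt, t] that survive to t number
    # lambda/60 * area * dwell * (1 - exp(-dt/dwell)) in expectation;
    # residual dwell of a survivor is Exp(dwell) by memorylessness.
    if (dt_s > 0) {
      alive <- state$mobile$expiry > t
      for (fld in c("y", "x", "z", "id", "expiry"))
        state$mobile[[fld]] <- state$mobile[[fld]][alive]
      lam <- target(t, config$mobile_density_pre,
                    config$mobile_density_post) * area_units / 60
      n_new <- stats::rpois(1, lam * dwell * (1 - exp(-dt_s / dwell)))
      if (n_new > 0) {
        state$mobile <- new_vesicles(n_new, state$mobile)
        state$mobile$expiry <- c(state$mobile$expiry,
                                 t + stats::rexp(n_new, 1 / dwell))
      }
    }
    ys <- c(state$static$y, state$mobile$y)
    xs <- c(state$static$x, state$mobile$x)
    zs <- c(state$static$z, state$mobile$z)
    ids <- c(state$static$id, state$mobile$id)
    cls <- rep(c("static", "mobile"),
               c(length(state$static$id), length(state$mobile$id)))
    amps <- amp_of(zs)
    img <- cpp_render_spots(bg, ys, xs, amps, geometry$psf_sigma, 4)
    if (config$poisson_noise)
      img <- matrix(stats::rpois(length(img), img), H, W)
    if (config$read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0,
                                       config$read_noise_sd), H, W)
    frames[, , f] <- pmax(img, 0)
    if (length(ids))
      truth[[f]] <- data.frame(id = ids, class = cls, frame = f,
                               x_px = xs, y_px = ys, z_nm = zs,
                               amplitude = amps)
  }

  truth <- if (all(vapply(truth, is.null, logical(1))))
    data.frame(id = integer(0), class = character(0), frame = integer(0),
               x_px = numeric(0), y_px = numeric(0), z_nm = numeric(0),
               amplitude = numeric(0))
  else do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  rownames(truth) <- NULL

  movie <- tirf_movie(frames, geometry, insulin_frame,
                      frame_times = times, insulin_time = t_ins)
  structure(list(movie = movie, truth = truth, background = bg,
                 config = config),
            class = "tirf_simulation")
}

#' Simulate a calibration-bead image
#'
#' Renders the TIRF image of a large fluorescent bead resting on the
#' coverslip.  At lateral offset `r` from the contact point the bead
#' surface sits at height `z(r) = R - sqrt(R^2 - r^2)` (bead radius `R`),
#' so the evanescent excitation gives intensity
#' `brightness * exp(-z(r) / d)` for `r <= R` and 0 outside.
#'
#' @param geometry An [acquisition_geometry()]; supplies pixel size and the
#'   penetration depth `d` used for rendering.
#' @param bead_diameter Bead diameter, micrometres.
#' @param brightness Intensity at the contact point (`z = 0`).
#' @param noise_sd Additive Gaussian noise, intensity units (0 = none).
#' @param size Image side in pixels; default covers the bead with a 10%
#'   margin.
#' @return Numeric matrix (the bead image).
#' @export
simulate_bead_image <- function(geometry = acquisition_geometry(),
                                bead_diameter = 10, brightness = 1000,
                                noise_sd = 0, size = NULL) {
  if (bead_diameter <= 0) stop("bead_diameter must be > 0")
  if (bead_diameter < geometry$pixel_size)
    stop("bead_diameter smaller than one pixel")
  R_um <- bead_diameter / 2
  if (is.null(size))
    size <- ceiling(2.2 * R_um / geometry$pixel_size)
  cy <- size / 2; cx <- size / 2
  row2 <- ((seq_len(size) - 0.5) - cy)^2
  col2 <- ((seq_len(size) - 0.5) - cx)^2
  r_um <- sqrt(outer(row2, col2, "+")) * geometry$pixel_size
  z_nm <- ifelse(r_um <= R_um,
                 (R_um - sqrt(pmax(R_um^2 - r_um^2, 0))) * 1000, NA_real_)
  img <- ifelse(is.na(z_nm), 0,
                brightness * exp(-z_nm / geometry$penetration_depth))
  if (noise_sd > 0)
    img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                             size, size), 0)
  img
}
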