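#' Reference study conditions
#'
#' Packaged acquisition geometries and scene configurations for the two
#' closed-loop simulation studies the package ships: translocation
#' kinetics (discrete-timepoint burst acquisition over a cell footprint)
#' and near-membrane vesicle dynamics (continuous 2 Hz acquisition tiled
#' with 100 um^2 ROIs).  Parameter values and their rationale are
#' documented in the methods vignette.
#'
#' @name study-conditions
NULL

#' @describeIn study-conditions Geometry of the kinetics study: 0.2 um/px
#'   sampling, 2 Hz, 110 nm evanescent depth, 1.2 px spot sigma.
#' @export
kinetics_geometry <- function() {
  acquisition_geometry(pixel_size = 0.2, frame_interval = 0.5,
                       exposure = 0.5, penetration_depth = 110,
                       psf_sigma = 1.2)
}

#' @describeIn study-conditions Geometry of the dynamics study: 0.2 um/px,
#'   2 Hz, spot sigma 2.2 px (the spot scale the three-criterion foci
#'   definition targets).
#' @export
dynamics_geometry <- function() {
  acquisition_geometry(pixel_size = 0.2, frame_interval = 0.5,
                       exposure = 0.5, penetration_depth = 110,
                       psf_sigma = 2.2)
}

#' @describeIn study-conditions Scene for a translocation-kinetics movie:
#'   a 10 um-radius cell footprint in a 128 x 128 px field, docked and
#'   mobile vesicle pools whose levels rise `fold`-fold after insulin
#'   with half-time `transition_halftime` (minutes), imaged as 10-frame
#'   bursts once per minute for 3 min before and (by default) 25 min
#'   after insulin.
#' @param fold Ground-truth plateau fold-change of the vesicle load.
#' @param transition_halftime Half-time of the rise, minutes.
#' @param seed Integer seed.
#' @param duration_post Post-insulin acquisition, seconds.
#' @export
kinetics_study_config <- function(fold, transition_halftime, seed,
                                  duration_post = 1500) {
  sim_config(field_size = 128L, duration_pre = 180,
             duration_post = duration_post,
             static_density_pre = 25, static_density_post = 25 * fold,
             mobile_density_pre = 5, mobile_density_post = 5 * fold,
             transition_halftime = transition_halftime,
             footprint_radius = 10, footprint_intensity = 30,
             acquisition = list(timepoint_interval = 60,
                                frames_per_timepoint = 10),
             seed = seed)
}

#' @describeIn study-conditions Run one kinetics movie end to end:
#'   simulate, segment the footprint on the raw pre-insulin mean,
#'   condition the stack, measure the footprint intensity series
#'   (off-cell background subtracted) and fit the translocation model.
#'   Returns the [fit_translocation()] object.
#' @export
run_kinetics_study <- function(fold, transition_halftime, seed,
                               duration_post = 1500) {
  geo <- kinetics_geometry()
  cfg <- kinetics_study_config(fold, transition_halftime, seed,
                               duration_post)
  sim <- simulate_tirf_movie(cfg, geo)
  raw <- sim$movie
  ref <- proj_mean(raw$frames[, , seq_len(raw$insulin_frame),
                              drop = FALSE])
  mask <- footprint_mask(ref, geo)
  clean <- preprocess_stack(raw, preprocess_params(ball_radius = 8))
  ser <- intensity_series(clean, mask, 10, background = "outside")
  fit_translocation(ser)
}

#' @describeIn study-conditions Scene for a vesicle-dynamics movie: a
#'   100 x 250 px field (ten 100 um^2 ROIs), docked vesicles at
#'   `static_pre` relaxing to `static_post` per 100 um^2 and mobile-visit
#'   rates `mobile_pre` to `mobile_post` per 100 um^2 per minute
#'   (half-time 0.5 min), 1 min before and 6 min after insulin at 2 Hz.
#' @param mobile_pre,mobile_post,static_pre,static_post Scene densities.
#' @export
dynamics_study_config <- function(seed, mobile_pre = 1, mobile_post = 2,
                                  static_pre = 4, static_post = 3) {
  sim_config(field_size = c(100L, 250L), duration_pre = 60,
             duration_post = 360,
             static_density_pre = static_pre,
             static_density_post = static_post,
             mobile_density_pre = mobile_pre,
             mobile_density_post = mobile_post,
             transition_halftime = 0.5, seed = seed)
}

#' @describeIn study-conditions Run one dynamics movie end to end:
#'   simulate, condition, decompose, detect and count.  Returns the
#'   `roi_count_series` data frame.
#' @export
run_dynamics_study <- function(seed, mobile_pre = 1, mobile_post = 2,
                               static_pre = 4, static_post = 3) {
  geo <- dynamics_geometry()
  cfg <- dynamics_study_config(seed, mobile_pre, mobile_post,
                               static_pre, static_post)
  sim <- simulate_tirf_movie(cfg, geo)
  clean <- preprocess_stack(sim$movie, preprocess_params(ball_radius = 8))
  run_dynamics(clean, dynamics_params(n_rois = 10))
}

#' Summarise replicate translocation fits
#'
#' Averages plateau folds and half-times over replicate fits, excluding
#' fits flagged as non-identifiable (`at_bound`: the optimiser landed on
#' a parameter bound, so plateau and half-time traded off freely) or
#' non-converged.  The exclusion is driven solely by each fit's own
#' diagnostic flags.
#'
#' @param fits List of [fit_translocation()] results.
#' @return One-row data frame: `mean_A`, `mean_t_half`, `n_used`,
#'   `n_flagged`.
#' @export
summarize_kinetics_fits <- function(fits) {
  ok <- vapply(fits, function(f)
    isTRUE(f$converged) && !isTRUE(f$at_bound) && !isTRUE(f$null_response),
    logical(1))
  data.frame(
    mean_A = mean(vapply(fits[ok], function(f) f$A, numeric(1))),
    mean_t_half = mean(vapply(fits[ok], function(f) f$t_half,
                              numeric(1))),
    n_used = sum(ok), n_flagged = sum(!ok))
}

#' Mean mobile count over the final post-insulin bins
#'
#' @param counts A `roi_count_series` from [run_dynamics()].
#' @param n_bins Number of trailing bins to average (default 5).
#' @return Mean mobile count per ROI per bin.
#' @export
plateau_mobile_count <- function(counts, n_bins = 5) {
  nb <- max(counts$bin_index)
  mean(counts$mobile_count[counts$bin_index > nb - n_bins])
}
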