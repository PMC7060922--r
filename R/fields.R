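# Render smooth cell-shaped blobs (Gaussian profiles) and return the
# field raster plus per-cell totals.
render_cells <- function(field_size, n_cells, amp, cell_cv, sigma_range) {
  H <- field_size[1]; W <- field_size[2]
  img <- matrix(0, H, W)
  centres <- cbind(y = stats::runif(n_cells, 0.15 * H, 0.85 * H),
                   x = stats::runif(n_cells, 0.15 * W, 0.85 * W))
  sig <- stats::runif(n_cells, sigma_range[1], sigma_range[2])
  amps <- amp * exp(stats::rnorm(n_cells, 0, cell_cv))
  for (k in seq_len(n_cells)) {
    row <- (seq_len(H) - 0.5 - centres[k, "y"])^2
    col <- (seq_len(W) - 0.5 - centres[k, "x"])^2
    img <- img + amps[k] * exp(-outer(row, col, "+") / (2 * sig[k]^2))
  }
  list(img = img, centres = centres, sigma = sig, amps = amps)
}

#' Simulate multi-channel cell fields for translocation quantification
#'
#' Generates per-field GFP (total reporter), HA (surface-exposed reporter)
#' and DAPI (nuclei) channels for a basal and an insulin-stimulated group.
#' The HA channel is the GFP channel scaled by the surface-exposed
#' fraction, which is `surface_fraction_basal` in basal fields and
#' `fold x surface_fraction_basal` in insulin fields, so the per-field
#' HA/GFP ratio carries the configured fold exactly when noise is
#' disabled.
#'
#' @param n_fields Fields per stimulation group.
#' @param surface_fraction_basal Basal surface-exposed fraction, in (0, 1].
#' @param fold Insulin-stimulated fold-change of the surface fraction;
#'   `fold * surface_fraction_basal` must not exceed 1.
#' @param noise `NULL` for none, or a list with any of `cell_cv`
#'   (per-cell brightness CV), `field_cv` (per-field surface-fraction CV),
#'   `pixel_sd` (additive Gaussian pixel noise).
#' @param seed Integer seed.
#' @param treatment Treatment label attached to every field (e.g. an siRNA
#'   name).
#' @param gfp_scale Multiplier on total-reporter brightness (models
#'   knockdown-altered expression; affects GFP and HA together).
#' @param field_size,n_cells,gfp_amp,dapi_amp Field geometry and channel
#'   amplitudes.
#' @return Object of class `field_image_set`: list of fields, each with
#'   `field_id`, `treatment`, `stimulation` ("basal"/"insulin"),
#'   `channels` (named list of rasters) and `truth` (realised
#'   `surface_fraction`).
#' @export
simulate_translocation_fields <- function(n_fields = 16,
                                          surface_fraction_basal = 0.1,
                                          fold = 3, noise = NULL,
                                          seed = 1L, treatment = "SCR",
                                          gfp_scale = 1,
                                          field_size = c(128L, 128L),
                                          n_cells = 6, gfp_amp = 100,
                                          dapi_amp = 80) {
  if (fold < 0) stop("fold must be >= 0")
  if (surface_fraction_basal <= 0 || surface_fraction_basal > 1)
    stop("surface_fraction_basal must be in (0, 1]")
  if (fold * surface_fraction_basal > 1)
    stop("infeasible fold: surface fraction would exceed 1")
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  cell_cv <- if (is.null(noise)) 0 else noise$cell_cv %||% 0
  field_cv <- if (is.null(noise)) 0 else noise$field_cv %||% 0
  pixel_sd <- if (is.null(noise)) 0 else noise$pixel_sd %||% 0

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  fields <- list()
  for (stim in c("basal", "insulin")) {
    sf_group <- surface_fraction_basal * (if (stim == "insulin") fold else 1)
    for (k in seq_len(n_fields)) {
      cells <- render_cells(field_size, n_cells, gfp_amp * gfp_scale,
                            cell_cv, c(8, 14))
      sf <- min(sf_group * exp(stats::rnorm(1, 0, field_cv)), 1)
      gfp <- cells$img
      ha <- sf * gfp
      dapi <- matrix(0, field_size[1], field_size[2])
      for (j in seq_len(nrow(cells$centres))) {
        row <- (seq_len(field_size[1]) - 0.5 - cells$centres[j, "y"])^2
        col <- (seq_len(field_size[2]) - 0.5 - cells$centres[j, "x"])^2
        dapi <- dapi + dapi_amp *
          exp(-outer(row, col, "+") / (2 * (cells$sigma[j] / 2.5)^2))
      }
      # additive detector noise is left unclamped: clipping at zero
      # would bias the dim (HA) channel means upward and dilute ratios
      if (pixel_sd > 0) {
        gfp <- gfp + stats::rnorm(length(gfp), 0, pixel_sd)
        ha <- ha + stats::rnorm(length(ha), 0, pixel_sd)
        dapi <- dapi + stats::rnorm(length(dapi), 0, pixel_sd)
      }
      fields[[length(fields) + 1L]] <- list(
        field_id = sprintf("%s_%s_%02d", treatment, stim, k),
        treatment = treatment, stimulation = stim,
        channels = list(GFP = gfp, HA = ha, DAPI = dapi),
        truth = list(surface_fraction = sf))
    }
  }
  structure(fields, class = "field_image_set")
}

#' Simulate two-channel fields with a configured colocalised fraction
#'
#' Channel 1 contains `n_structures` Gaussian spots of which a binomial
#' fraction (`overlap_fraction`) are co-placed with channel-2 spots; the
#' remaining structures of both channels are placed mutually disjoint
#' (minimum separation enforced), so Manders M1 recovers the overlap
#' fraction.
#'
#' @param n_fields Number of fields.
#' @param overlap_fraction Fraction of channel-1 structures co-placed with
#'   channel-2 structures, in `[0, 1]`.
#' @param seed Integer seed.
#' @param field_size,n_structures,psf_sigma,amp,amp_cv,noise_sd Rendering
#'   parameters (spot amplitude is lognormal with CV `amp_cv`; `noise_sd`
#'   adds Gaussian pixel noise).
#' @param min_sep Minimum separation (px) between non-co-placed structures
#'   of *different* channels; the default `5 * psf_sigma` keeps their
#'   threshold-level supports apart.  Use `8 * psf_sigma + 1` with
#'   `thresholds = 0` for exactly disjoint truncated supports (feasible
#'   only at low structure counts).
#' @return Object of class `field_image_set`; each field has channels
#'   `ch1`, `ch2` and `truth$overlap_fraction` (the realised fraction).
#' @export
simulate_coloc_fields <- function(n_fields = 10, overlap_fraction = 0.5,
                                  seed = 1L, field_size = c(160L, 160L),
                                  n_structures = 40, psf_sigma = 2,
                                  amp = 100, amp_cv = 0.2, noise_sd = 0,
                                  min_sep = 5 * psf_sigma) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (length(field_size) == 1L) field_size <- rep(field_size, 2L)
  H <- field_size[1]; W <- field_size[2]
  margin <- 4 * psf_sigma + 1

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  sample_sites <- function(n, avoid_y, avoid_x, sep) {
    ys <- numeric(0); xs <- numeric(0)
    tries <- 0L
    while (length(ys) < n) {
      y <- stats::runif(1, margin, H - margin)
      x <- stats::runif(1, margin, W - margin)
      d2 <- (avoid_y - y)^2 + (avoid_x - x)^2
      if (!length(d2) || min(d2) >= sep^2) {
        ys <- c(ys, y); xs <- c(xs, x)
      }
      tries <- tries + 1L
      if (tries > 500L * n)
        stop("cannot place structures with the required separation; ",
             "reduce n_structures or enlarge the field")
    }
    cbind(y = ys, x = xs)
  }

  fields <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    K <- stats::rbinom(1, n_structures, overlap_fraction)
    shared <- if (K > 0)
      cbind(y = stats::runif(K, margin, H - margin),
            x = stats::runif(K, margin, W - margin))
    else cbind(y = numeric(0), x = numeric(0))
    only1 <- sample_sites(n_structures - K, shared[, "y"], shared[, "x"],
                          min_sep)
    only2 <- sample_sites(n_structures - K,
                          c(shared[, "y"], only1[, "y"]),
                          c(shared[, "x"], only1[, "x"]), min_sep)
    a1 <- amp * exp(stats::rnorm(n_structures, 0, amp_cv))
    a2 <- amp * exp(stats::rnorm(n_structures, 0, amp_cv))
    zero <- matrix(0, H, W)
    ch1 <- cpp_render_spots(zero, c(shared[, "y"], only1[, "y"]),
                            c(shared[, "x"], only1[, "x"]), a1,
                            psf_sigma, 4)
    ch2 <- cpp_render_spots(zero, c(shared[, "y"], only2[, "y"]),
                            c(shared[, "x"], only2[, "x"]), a2,
                            psf_sigma, 4)
    if (noise_sd > 0) {
      ch1 <- ch1 + stats::rnorm(length(ch1), 0, noise_sd)
      ch2 <- ch2 + stats::rnorm(length(ch2), 0, noise_sd)
    }
    fields[[f]] <- list(
      field_id = sprintf("coloc_%02d", f), treatment = "none",
      stimulation = "none", channels = list(ch1 = ch1, ch2 = ch2),
      truth = list(overlap_fraction = K / n_structures))
  }
  structure(fields, class = "field_image_set")
}

#' Per-field channel means
#'
#' @param fields A `field_image_set`.
#' @return Data frame with `field_id`, `treatment`, `stimulation` and one
#'   `mean_<channel>` column per channel present.
#' @export
measure_fields <- function(fields) {
  stopifnot(inherits(fields, "field_image_set"))
  rows <- lapply(fields, function(f) {
    m <- vapply(f$channels, mean, numeric(1))
    names(m) <- paste0("mean_", names(m))
    cbind(data.frame(field_id = f$field_id, treatment = f$treatment,
                     stimulation = f$stimulation,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
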