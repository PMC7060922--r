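geo02 <- acquisition_geometry(pixel_size = 0.2, psf_sigma = 2.2)

test_that("an empty scene renders exactly the background", {
  cfg <- sim_config(field_size = 64L, duration_pre = 10, duration_post = 20,
                    static_density_pre = 0, static_density_post = 0,
                    mobile_density_pre = 0, mobile_density_post = 0,
                    poisson_noise = FALSE, read_noise_sd = 0, seed = 4)
  sim <- simulate_tirf_movie(cfg, geo02)
  expect_equal(nrow(sim$truth), 0L)
  for (f in seq_len(dim(sim$movie$frames)[3]))
    expect_equal(sim$movie$frames[, , f], sim$background)
})

test_that("seeded simulations are bit-identical and validated", {
  cfg <- sim_config(field_size = 64L, duration_pre = 10, duration_post = 20,
                    seed = 77)
  a <- simulate_tirf_movie(cfg, geo02)
  b <- simulate_tirf_movie(cfg, geo02)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth, b$truth)
  expect_error(sim_config(static_density_pre = -1), "densities")
  expect_error(sim_config(field_size = 0), "positive")
  expect_error(simulate_tirf_movie(sim_config(field_size = 32L), geo02),
               "field too small")
})

test_that("a noise-free static scene is time-invariant and conserves flux", {
  cfg <- sim_config(field_size = 128L, duration_pre = 0, duration_post = 15,
                    static_density_pre = 12, static_density_post = 12,
                    mobile_density_pre = 0, mobile_density_post = 0,
                    footprint_radius = 10,  # keep all spots interior
                    poisson_noise = FALSE, read_noise_sd = 0, seed = 5)
  sim <- simulate_tirf_movie(cfg, geo02)
  nT <- dim(sim$movie$frames)[3]
  for (f in seq_len(nT)[-1])
    expect_identical(sim$movie$frames[, , f], sim$movie$frames[, , 1])
  # rendered flux equals the analytic sum of per-vesicle Gaussians
  tr1 <- sim$truth[sim$truth$frame == 1, ]
  analytic <- sum(tr1$amplitude) * 2 * pi * geo02$psf_sigma^2
  rendered <- sum(sim$movie$frames[, , 1] - sim$background)
  expect_equal(rendered, analytic, tolerance = 0.005)
  # every rendered vesicle is traceable through the ground truth
  expect_equal(nrow(tr1), length(unique(sim$truth$id)))
})

test_that("mobile trajectories obey the configured diffusion law", {
  # persistent walkers: dwell much longer than the movie
  dwell <- 5400
  cfg <- sim_config(field_size = 100L, duration_pre = 0, duration_post = 50,
                    static_density_pre = 0, static_density_post = 0,
                    mobile_density_pre = 12 * 60 / dwell,
                    mobile_density_post = 12 * 60 / dwell,
                    dwell_time = dwell, diffusion_coeff = 0.01, seed = 8)
  sim <- simulate_tirf_movie(cfg, geo02)
  tr <- sim$truth
  px <- geo02$pixel_size
  for (lag in c(1L, 2L, 5L)) {
    sq <- c()
    for (id in unique(tr$id)) {
      v <- tr[tr$id == id, ]
      f <- v$frame
      m <- match(f + lag, f)
      ok <- !is.na(m)
      if (!any(ok)) next
      wrap <- function(d, n) ifelse(d > n / 2, d - n,
                                    ifelse(d < -n / 2, d + n, d))
      dx <- wrap(v$x_px[m[ok]] - v$x_px[ok], 100) * px
      dy <- wrap(v$y_px[m[ok]] - v$y_px[ok], 100) * px
      sq <- c(sq, dx^2 + dy^2)
    }
    msd <- mean(sq)
    expected <- 4 * 0.01 * lag * geo02$frame_interval
    expect_equal(msd, expected, tolerance = 0.15,
                 label = sprintf("MSD at lag %d", lag))
  }
})

test_that("burst acquisition produces grouped frame times", {
  cfg <- sim_config(field_size = 64L, duration_pre = 120,
                    duration_post = 240,
                    acquisition = list(timepoint_interval = 60,
                                       frames_per_timepoint = 10),
                    seed = 3)
  sim <- simulate_tirf_movie(cfg, geo02)
  ft <- sim$movie$frame_times
  expect_equal(length(ft), 60L)  # 6 bursts of 10
  expect_equal(diff(ft)[1:9], rep(0.5, 9))
  expect_equal(ft[11] - ft[10], 60 - 9 * 0.5)
  expect_equal(sim$movie$insulin_frame, 20L)  # two pre-insulin bursts
  expect_equal(sim$movie$insulin_time, 120)
})

test_that("bead images follow the evanescent-decay geometry", {
  # contact point carries the full brightness
  img <- simulate_bead_image(geo02, bead_diameter = 10, brightness = 500)
  expect_equal(max(img), 500, tolerance = 1e-6)
  # a huge penetration depth gives a uniform disk
  deep <- acquisition_geometry(pixel_size = 0.2, penetration_depth = 1e9)
  disk <- simulate_bead_image(deep, bead_diameter = 10, brightness = 500)
  vals <- disk[disk > 0]
  expect_lt(diff(range(vals)) / 500, 1e-4)
  # log-intensity is linear in bead height with slope -1/d
  R_nm <- 5 * 1000
  n <- nrow(img)
  ctr <- n / 2
  r_nm <- sqrt(outer(((seq_len(n) - 0.5) - ctr)^2,
                     ((seq_len(n) - 0.5) - ctr)^2, "+")) * 0.2 * 1000
  sel <- r_nm < 3000 & img > 0
  z <- R_nm - sqrt(R_nm^2 - r_nm[sel]^2)
  fit <- lm(log(img[sel]) ~ z)
  expect_equal(unname(coef(fit)[2]), -1 / 110, tolerance = 1e-6)
  expect_error(simulate_bead_image(geo02, bead_diameter = 0.1),
               "smaller than one pixel")
})

test_that("translocation fields encode the configured surface fold", {
  # noise disabled, fold 3: per-field HA/GFP is exact
  fs <- simulate_translocation_fields(n_fields = 4,
                                      surface_fraction_basal = 0.1,
                                      fold = 3, noise = NULL, seed = 2)
  m <- measure_fields(fs)
  ratio <- m$mean_HA / m$mean_GFP
  expect_equal(ratio[m$stimulation == "basal"], rep(0.1, 4),
               tolerance = 1e-12)
  expect_equal(ratio[m$stimulation == "insulin"], rep(0.3, 4),
               tolerance = 1e-12)
  # fold 1: the two groups are statistically indistinguishable
  f1 <- simulate_translocation_fields(n_fields = 12,
                                      surface_fraction_basal = 0.1,
                                      fold = 1,
                                      noise = list(cell_cv = 0.2,
                                                   field_cv = 0.05,
                                                   pixel_sd = 1),
                                      seed = 9)
  m1 <- measure_fields(f1)
  r1 <- m1$mean_HA / m1$mean_GFP
  tt <- t.test(r1[m1$stimulation == "basal"],
               r1[m1$stimulation == "insulin"])
  expect_gt(tt$p.value, 0.05)
  # seeded reproducibility
  a <- simulate_translocation_fields(n_fields = 2, seed = 5)
  b <- simulate_translocation_fields(n_fields = 2, seed = 5)
  expect_identical(a[[1]]$channels$GFP, b[[1]]$channels$GFP)
  expect_error(simulate_translocation_fields(surface_fraction_basal = 0.5,
                                             fold = 3), "infeasible")
})

test_that("coloc fields realise the configured overlap fraction", {
  # full overlap, noise-free: all channel-1 intensity sits on channel-2
  # support
  f1 <- simulate_coloc_fields(n_fields = 1, overlap_fraction = 1, seed = 1)
  cc <- coloc(f1[[1]]$channels$ch1, f1[[1]]$channels$ch2, thresholds = 0)
  expect_equal(cc$manders_m1, 1)
  # fully disjoint truncated supports: no overlap at all
  f0 <- simulate_coloc_fields(n_fields = 1, overlap_fraction = 0, seed = 2,
                              n_structures = 10, min_sep = 8 * 2 + 1)
  cc0 <- coloc(f0[[1]]$channels$ch1, f0[[1]]$channels$ch2, thresholds = 0)
  expect_equal(cc0$manders_m1, 0)
  expect_equal(cc0$manders_m2, 0)
  # overlap 0.5 is recovered across 20 seeded fields with a noise-floor
  # threshold (Otsu sits a third of the way up the spots and keeps only
  # their cores, biasing M1 low; see the methods vignette), tolerance
  # from binomial sampling error plus the threshold tail
  fh <- simulate_coloc_fields(n_fields = 20, overlap_fraction = 0.5,
                              seed = 3, noise_sd = 1)
  m1 <- vapply(fh, function(f)
    coloc(f$channels$ch1, f$channels$ch2, thresholds = 3)$manders_m1,
    numeric(1))
  expect_equal(mean(m1), 0.5, tolerance = 0.1)
  truth <- vapply(fh, function(f) f$truth$overlap_fraction, numeric(1))
  expect_lt(abs(mean(m1) - mean(truth)), 0.05)
  expect_error(simulate_coloc_fields(overlap_fraction = 1.5), "overlap")
})
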