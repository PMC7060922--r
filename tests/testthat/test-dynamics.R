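fake_movie <- function(nT, H = 4, W = 4, pixel_size = 0.2, value = 0) {
  geo <- acquisition_geometry(pixel_size = pixel_size)
  tirf_movie(array(value, c(H, W, nT)), geo, 0L)
}

test_that("time binning follows the 1-min / remainder rules", {
  # 27 min at 2 Hz, 1-min bins -> 27 bins of 120 frames
  bins <- bin_stack(fake_movie(27 * 120))
  expect_length(bins, 27L)
  expect_true(all(lengths(bins) == 120L))
  # bins are contiguous, ordered and cover every frame exactly once
  expect_equal(unlist(bins), 1:3240)
  # a 45-s movie is a single bin
  expect_equal(bin_stack(fake_movie(90)), list(1:90))
  # 150 frames: the 30-frame remainder (< half a bin) is merged
  expect_equal(bin_stack(fake_movie(150)), list(1:150))
  # 200 frames: the 80-frame remainder keeps its own bin
  expect_equal(bin_stack(fake_movie(200)), list(1:120, 121:200))
  expect_error(bin_stack(fake_movie(10), bin_duration = 0.5), "2 frames")
})

test_that("average-projection decomposition conserves intensity exactly", {
  # identical frames: everything is static
  sub <- array(rep(matrix(runif(36), 6, 6), 4), c(6, 6, 4))
  dec <- decompose_bin(sub)
  expect_equal(dec$mobile, array(0, c(6, 6, 4)))
  expect_identical(dec$static, sub)
  # single pulse of height h in one of N frames
  N <- 5; h <- 20
  sub <- array(0, c(3, 3, N)); sub[2, 2, 3] <- h
  dec <- decompose_bin(sub)
  expect_equal(dec$mobile[2, 2, 3], h * (1 - 1 / N))
  expect_equal(dec$static[2, 2, 3], h / N)
  expect_equal(sum(dec$mobile) + sum(dec$static), h)
  # random stack: reconstruction is bit-exact
  set.seed(9)
  sub <- array(runif(6 * 6 * 4, 0, 100), c(6, 6, 4))
  dec <- decompose_bin(sub)
  expect_identical(dec$mobile + dec$static, sub)
  expect_true(all(dec$mobile >= 0) && all(dec$static >= 0))
  expect_error(decompose_bin(sub[, , 1, drop = FALSE]), "2 frames")
})

test_that("foci detection enforces the three criteria", {
  expect_equal(nrow(detect_foci(matrix(0, 16, 16), peak_min = 1)), 0L)
  # a vesicle-scale spot passes all three criteria at its centre pixel
  spot <- gaussian_spot(31, 2.2, amp = 100)
  f <- detect_foci(spot, peak_min = 10)
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$row, f$col), c(16, 16))
  expect_true(f$contained_fraction >= 0.75)
  expect_equal(f[, c("row", "col")],
               oracle_foci(spot, 10)[, c("row", "col")])
  # a broad blob fails the 75% containment criterion
  blob <- gaussian_spot(61, 8, amp = 100)
  expect_equal(nrow(detect_foci(blob, peak_min = 10)), 0L)
  expect_equal(nrow(oracle_foci(blob, 10)), 0L)
  # a narrow spot fails the minimum-support criterion: its half-max
  # region is smaller than a radius-2 disk
  narrow <- gaussian_spot(31, 1.5, amp = 100)
  expect_equal(nrow(detect_foci(narrow, peak_min = 10)), 0L)
  expect_equal(nrow(oracle_foci(narrow, 10)), 0L)
})

test_that("foci detection agrees exactly with the brute-force oracle", {
  for (s in 1:12) {
    img <- make_test_raster(s, n_spots = s %% 3 + 1)
    got <- detect_foci(img, peak_min = 20)
    want <- oracle_foci(img, 20)
    expect_equal(nrow(got), nrow(want), label = sprintf("seed %d", s))
    if (nrow(want))
      expect_equal(got[, c("row", "col")], want[, c("row", "col")],
                   label = sprintf("seed %d", s))
  }
  # plateau: a flat-topped square resolves to its lexicographically
  # smallest pixel
  img <- matrix(0, 15, 15); img[7:9, 7:9] <- 50
  img <- despeckle(img + gaussian_spot(15, 3, amp = 10), 3)
  img[7:8, 7:8] <- 60
  got <- detect_foci(img, peak_min = 5, min_radius = 1)
  expect_equal(got[1, c("row", "col")],
               data.frame(row = 7L, col = 7L), ignore_attr = TRUE)
})

test_that("ROI counting uses half-open squares and physical areas", {
  rois <- auto_rois(c(100, 100), 0.2, n = 4)
  expect_equal(rois$size, rep(50L, 4))
  expect_equal((rois$size[1] * 0.2)^2, 100)
  foci <- data.frame(row = c(3, 10, 20, 60, 55, 20),
                     col = c(4, 12, 30, 70, 60, 80))
  counts <- count_in_rois(foci, rois, c(100, 100))
  expect_equal(counts, c(3L, 1L, 0L, 2L))
  expect_equal(count_in_rois(foci[0, ], rois), rep(0L, 4))
  # a focus on a shared edge is counted once, in the half-open interval
  # that contains it
  edge <- data.frame(row = 51, col = 1)
  expect_equal(count_in_rois(edge, rois), c(0L, 0L, 1L, 0L))
  expect_error(count_in_rois(foci, data.frame(roi_index = 1, row0 = 90,
                                              col0 = 1, size = 50),
                             c(100, 100)), "outside")
  expect_error(auto_rois(c(60, 60), 0.2, n = 4), "fits only")
  expect_error(auto_rois(c(100, 100), 0.23, n = 1), "within 1%")
})

test_that("run_dynamics separates static from mobile scenes", {
  geo <- acquisition_geometry(pixel_size = 0.2, psf_sigma = 2.2)
  base <- list(field_size = 100L, duration_pre = 60, duration_post = 120,
               transition_halftime = 0.5)
  dp <- dynamics_params(n_rois = 4)
  # static-only scene: mobile counts stay at the blank-scene level
  cfg <- do.call(sim_config, c(base, list(
    static_density_pre = 4, static_density_post = 4,
    mobile_density_pre = 0, mobile_density_post = 0, seed = 101)))
  sim <- simulate_tirf_movie(cfg, geo)
  clean <- preprocess_stack(sim$movie, preprocess_params(ball_radius = 8))
  counts <- run_dynamics(clean, dp)
  expect_lt(mean(counts$mobile_count), 0.3)
  expect_gt(mean(counts$static_count), 1)
  # determinism of the counting stage
  expect_identical(counts, run_dynamics(clean, dp))
  # pure-mobile scene of persistent fast walkers (dwell much longer than
  # the movie, motor-driven-scale diffusion): static counts do not exceed
  # the blank-movie false-positive level beyond counting noise
  cfg_m <- do.call(sim_config, c(base, list(
    static_density_pre = 0, static_density_post = 0,
    mobile_density_pre = 3 * 60 / 5400, mobile_density_post = 3 * 60 / 5400,
    dwell_time = 5400, diffusion_coeff = 0.5, seed = 102)))
  sim_m <- simulate_tirf_movie(cfg_m, geo)
  clean_m <- preprocess_stack(sim_m$movie, preprocess_params(ball_radius = 8))
  counts_m <- run_dynamics(clean_m, dp)
  cfg_b <- do.call(sim_config, c(base, list(
    static_density_pre = 0, static_density_post = 0,
    mobile_density_pre = 0, mobile_density_post = 0, seed = 103)))
  sim_b <- simulate_tirf_movie(cfg_b, geo)
  clean_b <- preprocess_stack(sim_b$movie, preprocess_params(ball_radius = 8))
  counts_b <- run_dynamics(clean_b, dp)
  expect_lte(mean(counts_m$static_count),
             mean(counts_b$static_count) + 0.3)
  # times are reported relative to insulin addition
  expect_lt(counts$t_min[1], 0)
  expect_gt(max(counts$t_min), 0)
})

test_that("recovered mobile counts increase with configured density", {
  geo <- acquisition_geometry(pixel_size = 0.2, psf_sigma = 2.2)
  means <- vapply(c(1, 2, 4), function(dens) {
    cfg <- sim_config(field_size = 100L, duration_pre = 0,
                      duration_post = 180,
                      static_density_pre = 0, static_density_post = 0,
                      mobile_density_pre = dens,
                      mobile_density_post = dens, seed = 7)
    sim <- simulate_tirf_movie(cfg, geo)
    clean <- preprocess_stack(sim$movie,
                              preprocess_params(ball_radius = 8))
    mean(run_dynamics(clean, dynamics_params(n_rois = 4))$mobile_count)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_gt(means[3], means[1])
})
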