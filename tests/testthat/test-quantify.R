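make_meas <- function(treatment, stimulation, ha, gfp, dapi = 1) {
  data.frame(field_id = sprintf("%s_%s_%02d", treatment, stimulation,
                                seq_along(ha)),
             treatment = treatment, stimulation = stimulation,
             mean_HA = ha, mean_GFP = gfp, mean_DAPI = dapi,
             stringsAsFactors = FALSE)
}

test_that("HA/GFP normalisation conventions match the screen design", {
  # basal fields only: normalised mean is exactly 1
  basal <- make_meas("SCR", "basal", ha = c(2, 3, 4), gfp = c(10, 10, 10))
  r <- ha_gfp_ratio(basal)
  expect_equal(mean(r$norm_ratio), 1)
  # noise-free simulated control with fold 3: insulin group reads 3.0
  fs <- simulate_translocation_fields(n_fields = 8,
                                      surface_fraction_basal = 0.1,
                                      fold = 3, noise = NULL, seed = 6)
  rr <- ha_gfp_ratio(measure_fields(fs))
  expect_equal(mean(rr$norm_ratio[rr$stimulation == "insulin"]), 3,
               tolerance = 1e-10)
  # VAMP2-like knockdown: basal surface elevated 2.7-fold, no insulin
  # increment.  The control-basal convention reads the elevation; the
  # per-group convention reads the (absent) insulin response.
  ctrl <- simulate_translocation_fields(8, 0.1, fold = 3, noise = NULL,
                                        seed = 7, treatment = "SCR")
  kd <- simulate_translocation_fields(8, 0.27, fold = 1, noise = NULL,
                                      seed = 8, treatment = "VAMP2")
  m <- rbind(measure_fields(ctrl), measure_fields(kd))
  cross <- ha_gfp_ratio(m, normalise = "control_basal", control = "SCR")
  kd_basal <- cross$norm_ratio[cross$treatment == "VAMP2" &
                                 cross$stimulation == "basal"]
  expect_equal(mean(kd_basal), 2.7, tolerance = 1e-10)
  per <- ha_gfp_ratio(m, normalise = "per_group")
  kd_fold <- per$norm_ratio[per$treatment == "VAMP2" &
                              per$stimulation == "insulin"]
  expect_equal(mean(kd_fold), 1, tolerance = 1e-10)
  # zero-GFP fields are excluded with a record
  bad <- rbind(basal, make_meas("SCR", "insulin", ha = c(5, 5),
                                gfp = c(10, 0)))
  expect_warning(rb <- ha_gfp_ratio(bad), "excluded")
  expect_equal(attr(rb, "excluded"), "SCR_insulin_02")
  expect_equal(nrow(rb), 4L)
})

test_that("GFP/DAPI abundance ratios normalise to the control group", {
  ctrl <- make_meas("SCR", "basal", ha = 1, gfp = c(10, 12, 11),
                    dapi = c(5, 6, 5.5))
  expect_equal(mean(gfp_dapi_ratio(ctrl)$norm_ratio), 1)
  # knockdown with 1.5x GFP, DAPI unchanged
  fs_c <- simulate_translocation_fields(4, 0.1, fold = 1, noise = NULL,
                                        seed = 3, treatment = "SCR")
  fs_k <- simulate_translocation_fields(4, 0.1, fold = 1, noise = NULL,
                                        seed = 3, treatment = "KD",
                                        gfp_scale = 1.5)
  m <- rbind(measure_fields(fs_c), measure_fields(fs_k))
  r <- gfp_dapi_ratio(m, control = "SCR")
  expect_equal(mean(r$norm_ratio[r$treatment == "KD"]), 1.5,
               tolerance = 1e-10)
  # zero-DAPI field excluded
  bad <- ctrl; bad$mean_DAPI[2] <- 0
  expect_warning(rb <- gfp_dapi_ratio(bad), "excluded")
  expect_equal(nrow(rb), 2L)
})

test_that("colocalisation coefficients match hand-computed sums", {
  set.seed(12)
  a <- matrix(runif(64, 0, 10), 8, 8)
  # identical channels: perfect correlation and containment
  cc <- coloc(a, a, thresholds = 0)
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$manders_m1, 1)
  expect_equal(cc$manders_m2, 1)
  # disjoint supports
  b1 <- matrix(0, 8, 8); b1[1:4, ] <- 5
  b2 <- matrix(0, 8, 8); b2[5:8, ] <- 7
  cc2 <- coloc(b1, b2, thresholds = 0)
  expect_equal(cc2$manders_m1, 0)
  expect_equal(cc2$manders_m2, 0)
  # printed 6x6 fixture against the arithmetic oracle
  ch1 <- matrix(c(0, 1, 2, 0, 0, 0,
                  1, 5, 3, 0, 0, 0,
                  0, 2, 1, 0, 0, 1,
                  0, 0, 0, 0, 2, 4,
                  0, 0, 0, 1, 6, 2,
                  0, 0, 0, 0, 3, 1), 6, 6, byrow = TRUE)
  ch2 <- matrix(c(0, 2, 1, 0, 0, 0,
                  2, 4, 2, 0, 0, 0,
                  1, 1, 0, 0, 0, 0,
                  0, 0, 0, 0, 0, 0,
                  0, 0, 0, 0, 1, 0,
                  0, 0, 0, 0, 0, 0), 6, 6, byrow = TRUE)
  thr <- c(0.5, 0.5)
  cc3 <- coloc(ch1, ch2, thresholds = thr)
  expect_equal(cc3$manders_m1, sum(ch1[ch2 > 0.5]) / sum(ch1))
  expect_equal(cc3$manders_m2, sum(ch2[ch1 > 0.5]) / sum(ch2))
  expect_equal(cc3$pearson_r, cor(as.vector(ch1), as.vector(ch2)))
  # symmetry: swapping channels swaps M1/M2 and preserves r
  cc3s <- coloc(ch2, ch1, thresholds = rev(thr))
  expect_equal(cc3s$manders_m1, cc3$manders_m2)
  expect_equal(cc3s$manders_m2, cc3$manders_m1)
  expect_equal(cc3s$pearson_r, cc3$pearson_r)
  # scaling the partner channel leaves a Manders coefficient unchanged
  cc4 <- coloc(ch1, ch2 * 7.3)
  expect_equal(cc4$manders_m1, coloc(ch1, ch2)$manders_m1)
  # bounds on random rasters
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(runif(100), 10, 10); y <- matrix(runif(100), 10, 10)
    cx <- coloc(x, y)
    expect_true(cx$manders_m1 >= 0 && cx$manders_m1 <= 1)
    expect_true(cx$manders_m2 >= 0 && cx$manders_m2 <= 1)
  }
  # a constant channel flags Pearson as undefined
  cc5 <- coloc(matrix(1, 4, 4), matrix(runif(16), 4, 4), thresholds = 0)
  expect_true(is.na(cc5$pearson_r))
  expect_match(cc5$flags, "constant")
  expect_error(coloc(matrix(0, 3, 3), matrix(0, 4, 4)), "equal shape")
})

test_that("group comparisons use Welch t and two-way ANOVA correctly", {
  # identical groups: t = 0, p = 1
  r0 <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # {1,2,3} vs {4,5,6}: closed-form Welch statistic
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  t_hand <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  df_hand <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  r <- compare_groups(list(a = a, b = b))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, df_hand)
  expect_equal(r$p, 2 * pt(t_hand, df_hand))
  # degenerate group flagged
  rd <- compare_groups(list(a = 1, b = c(2, 3)))
  expect_match(rd$flag, "degenerate")
  # two-way ANOVA returns main effects and interaction
  set.seed(99)
  df2 <- expand.grid(f1 = c("ctrl", "kd"), f2 = c("coloc", "level"),
                     rep = 1:5)
  df2$value <- rnorm(nrow(df2)) + (df2$f1 == "kd") * 2
  r2 <- compare_groups(df2, design = "two_way")
  expect_setequal(r2$term, c("f1", "f2", "f1:f2"))
  expect_lt(r2$p[r2$term == "f1"], 0.01)
  ref <- summary(aov(value ~ f1 * f2, data = df2))[[1]]
  expect_equal(r2$statistic, ref[["F value"]][1:3])
})

test_that("the t-test maintains its nominal type-I error rate", {
  set.seed(2024)
  reps <- 1000L
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(10); y <- rnorm(10)
    p[i] <- compare_groups(list(x, y))$p
  }
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.032)
  expect_lt(rate, 0.068)
})

test_that("a 0.3 vs 0.5 overlap difference is detected at n = 20 fields", {
  hits <- 0L
  reps <- 50L
  for (r in seq_len(reps)) {
    g1 <- simulate_coloc_fields(20, 0.3, seed = 1000 + r, noise_sd = 1)
    g2 <- simulate_coloc_fields(20, 0.5, seed = 2000 + r, noise_sd = 1)
    m1a <- vapply(g1, function(f)
      coloc(f$channels$ch1, f$channels$ch2, thresholds = 3)$manders_m1,
      numeric(1))
    m1b <- vapply(g2, function(f)
      coloc(f$channels$ch1, f$channels$ch2, thresholds = 3)$manders_m1,
      numeric(1))
    if (compare_groups(list(m1a, m1b))$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("ratio conventions are scale-invariant", {
  fs <- simulate_translocation_fields(4, 0.1, fold = 2.2,
                                      noise = list(cell_cv = 0.1),
                                      seed = 15)
  m <- measure_fields(fs)
  m2 <- m
  m2$mean_HA <- m2$mean_HA * 3.7
  m2$mean_GFP <- m2$mean_GFP * 3.7
  expect_equal(ha_gfp_ratio(m2)$norm_ratio, ha_gfp_ratio(m)$norm_ratio)
})
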