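# Naive reference implementations used as independent oracles.  All are
# deliberately written as plain per-pixel loops, independent of the
# package's vectorised / compiled code paths.

reflect_o <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# grayscale erosion/dilation with SE offsets (di, dj) and heights h
oracle_morph <- function(img, se, erode = TRUE) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- numeric(nrow(se))
    for (k in seq_len(nrow(se))) {
      if (erode) {
        ii <- reflect_o(i + se$di[k], H); jj <- reflect_o(j + se$dj[k], W)
        vals[k] <- img[ii, jj] - se$h[k]
      } else {
        ii <- reflect_o(i - se$di[k], H); jj <- reflect_o(j - se$dj[k], W)
        vals[k] <- img[ii, jj] + se$h[k]
      }
    }
    out[i, j] <- if (erode) min(vals) else max(vals)
  }
  out
}

oracle_ball_se <- function(radius) {
  g <- expand.grid(di = -floor(radius):floor(radius),
                   dj = -floor(radius):floor(radius))
  g <- g[g$di^2 + g$dj^2 <= radius^2, ]
  g$h <- sqrt(radius^2 - g$di^2 - g$dj^2)
  g
}

oracle_rolling_ball <- function(img, radius) {
  se <- oracle_ball_se(radius)
  opening <- oracle_morph(oracle_morph(img, se, TRUE), se, FALSE)
  pmax(img - opening, 0)
}

oracle_median_filter <- function(img, window) {
  r <- (window - 1) / 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, img[reflect_o(i + di, H), reflect_o(j + dj, W)])
    out[i, j] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

oracle_remove_outliers <- function(img, radius, threshold) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (di in -floor(radius):floor(radius))
      for (dj in -floor(radius):floor(radius))
        if (di^2 + dj^2 <= radius^2)
          vals <- c(vals, img[reflect_o(i + di, H), reflect_o(j + dj, W)])
    med <- stats::median(vals)
    if (abs(img[i, j] - med) > threshold) out[i, j] <- med
  }
  out
}

# Brute-force foci detector implementing the three criteria pixel by
# pixel: local maximum above peak_min, plateau resolved to the
# lexicographically smallest member, merge within the containment radius
# to the brighter peak, integrated-intensity containment and half-max
# support area.
oracle_foci <- function(img, peak_min, cr = 5, cf = 0.75, mr = 2) {
  H <- nrow(img); W <- ncol(img)
  cand <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- img[i, j]
    if (v < peak_min) next
    is_max <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
          img[ii, jj] > v) is_max <- FALSE
    }
    if (is_max) cand <- rbind(cand, c(i, j, v))
  }
  if (is.null(cand)) return(data.frame(row = integer(0), col = integer(0)))
  cand <- as.data.frame(cand); names(cand) <- c("row", "col", "value")
  # plateau: drop a candidate if an equal-valued candidate that is
  # lexicographically smaller is connected to it through equal-valued
  # candidate pixels
  keep <- rep(TRUE, nrow(cand))
  for (s in seq_len(nrow(cand))) {
    # BFS over equal-valued candidates
    comp <- s; queue <- s
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (t in seq_len(nrow(cand))) {
        if (t %in% comp) next
        if (cand$value[t] == cand$value[q] &&
            abs(cand$row[t] - cand$row[q]) <= 1 &&
            abs(cand$col[t] - cand$col[q]) <= 1) {
          comp <- c(comp, t); queue <- c(queue, t)
        }
      }
    }
    lex <- order(cand$row[comp], cand$col[comp])
    if (comp[lex[1]] != s) keep[s] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  # merge to the brighter peak
  ord <- order(-cand$value, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]
  kept <- c()
  for (s in seq_len(nrow(cand))) {
    ok <- TRUE
    for (t in kept)
      if (sqrt((cand$row[t] - cand$row[s])^2 +
                 (cand$col[t] - cand$col[s])^2) < cr) ok <- FALSE
    if (ok) kept <- c(kept, s)
  }
  cand <- cand[kept, , drop = FALSE]
  # criteria (ii) and (iii)
  res <- NULL
  disk_area <- 0
  for (di in -floor(mr):floor(mr)) for (dj in -floor(mr):floor(mr))
    if (di^2 + dj^2 <= mr^2) disk_area <- disk_area + 1
  for (s in seq_len(nrow(cand))) {
    i <- cand$row[s]; j <- cand$col[s]; v <- cand$value[s]
    # local background: median over the annulus (cr, 2cr]
    ann_vals <- c()
    for (di in -(2 * cr):(2 * cr)) for (dj in -(2 * cr):(2 * cr)) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      d2 <- di^2 + dj^2
      if (d2 > cr^2 && d2 <= (2 * cr)^2)
        ann_vals <- c(ann_vals, img[ii, jj])
    }
    bgl <- stats::median(ann_vals)
    # each pixel belongs to its nearest surviving peak (ties go to the
    # peak that ranks earlier in merge order, i.e. the brighter one)
    s_in <- 0; s_out <- 0
    for (di in -(2 * cr):(2 * cr)) for (dj in -(2 * cr):(2 * cr)) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      d2 <- di^2 + dj^2
      owned <- TRUE
      for (o in seq_len(nrow(cand))) {
        if (o == s) next
        d_o <- (ii - cand$row[o])^2 + (jj - cand$col[o])^2
        if (o < s && d_o <= d2) owned <- FALSE
        if (o > s && d_o < d2) owned <- FALSE
      }
      if (!owned) next
      w <- max(img[ii, jj] - bgl, 0)
      if (d2 <= (2 * cr)^2) s_out <- s_out + w
      if (d2 <= cr^2) s_in <- s_in + w
    }
    frac <- if (s_out > 0) s_in / s_out else 0
    # half-height region by repeated dilation of the seed
    mask <- img >= bgl + (v - bgl) / 2
    reg <- matrix(FALSE, H, W); reg[i, j] <- TRUE
    repeat {
      grew <- FALSE
      for (ii in seq_len(H)) for (jj in seq_len(W)) {
        if (reg[ii, jj] || !mask[ii, jj]) next
        for (di in -1:1) for (dj in -1:1) {
          ai <- ii + di; aj <- jj + dj
          if (ai >= 1 && ai <= H && aj >= 1 && aj <= W && reg[ai, aj]) {
            reg[ii, jj] <- TRUE; grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    if (frac >= cf && sum(reg) >= disk_area)
      res <- rbind(res, data.frame(row = i, col = j, value = v))
  }
  if (is.null(res)) data.frame(row = integer(0), col = integer(0)) else res
}

# small deterministic raster with smooth structure + spots for fixtures
make_test_raster <- function(seed, H = 16, W = 16, n_spots = 2,
                             sigma = 2.2, amp = 100) {
  set.seed(seed)
  img <- matrix(stats::runif(H * W, 0, 5), H, W)
  for (k in seq_len(n_spots)) {
    cy <- stats::runif(1, 4, H - 3); cx <- stats::runif(1, 4, W - 3)
    a <- amp * stats::runif(1, 0.5, 1.5)
    for (i in seq_len(H)) for (j in seq_len(W))
      img[i, j] <- img[i, j] +
        a * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2))
  }
  img
}

# render one centred Gaussian spot
gaussian_spot <- function(n, sigma, amp = 100, cy = (n + 1) / 2,
                          cx = (n + 1) / 2) {
  img <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    img[i, j] <- amp * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2))
  img
}
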