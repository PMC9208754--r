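# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Otsu oracle: exhaustive double loop over all histogram bins,
# recomputing the class weights and means from scratch at every candidate
# split. Independent of the package's cumulative-sum implementation.
otsu_brute_force <- function(frame) {
  v <- as.vector(frame)
  levels <- sort(unique(v))
  cnt <- tabulate(match(v, levels), nbins = length(levels))
  n <- length(v)
  best_val <- -Inf
  best_thr <- NA_real_
  for (i in seq_len(length(levels) - 1L)) {
    w0 <- 0; s0 <- 0; w1 <- 0; s1 <- 0
    for (j in seq_along(levels)) {
      if (j <= i) { w0 <- w0 + cnt[j]; s0 <- s0 + cnt[j] * levels[j] }
      else        { w1 <- w1 + cnt[j]; s1 <- s1 + cnt[j] * levels[j] }
    }
    sb <- (w0 / n) * (w1 / n) * (s0 / w0 - s1 / w1)^2
    if (sb > best_val) {
      best_val <- sb
      best_thr <- (levels[i] + levels[i + 1L]) / 2
    }
  }
  best_thr
}

# Straight ribbon mask: centreline from (r0,c0) at angle `ang`, geometric
# length `len`, stamped with disks of radius w/2.
ribbon_mask <- function(nr, nc, r0, c0, ang, len, w) {
  t <- seq(0, len, by = 1)
  pr <- r0 + t * sin(ang); pc <- c0 + t * cos(ang)
  idx <- wrinklekit:::stamp_polyline(pr, pc, w / 2, nr, nc)
  m <- matrix(FALSE, nr, nc); m[idx] <- TRUE
  m
}

# Tiny noiseless movie of one rigidly translating pattern (periodic),
# for the Fourier translation property of the structure function.
translating_movie <- function(nr = 64, frames = 16, shift_px = 2,
                              pixel_size_um = 1, seed = 5) {
  base <- wrinklekit:::with_seed(seed, matrix(runif(nr * nr), nr, nr))
  frames_l <- lapply(seq_len(frames) - 1L, function(t) {
    s <- (t * shift_px) %% nr
    if (s == 0) base else base[, c((nr - s + 1):nr, 1:(nr - s))]
  })
  image_stack(frames_l, pixel_size_um = pixel_size_um, frame_interval_s = 1)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
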