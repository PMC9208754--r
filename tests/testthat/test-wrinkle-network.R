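test_that("Otsu threshold equals the brute-force oracle", {
  set.seed(3)
  # bimodal, uniform, quantized, and small random frames
  frames <- list(
    matrix(sample(c(rep(10, 40), rep(200, 60))), 10, 10),
    matrix(sample(0:255, 400, replace = TRUE) / 255, 20, 20),
    matrix(c(rnorm(300, 0.3, 0.05), rnorm(100, 0.8, 0.05)), 20, 20),
    matrix(round(runif(256) * 15) / 15, 16, 16)
  )
  for (f in frames) {
    expect_equal(otsu_threshold(f), otsu_brute_force(f))
  }
  # two-valued frame: threshold separates the classes cleanly
  f2 <- matrix(c(rep(0, 30), rep(255, 34)), 8, 8)
  thr <- otsu_threshold(f2)
  expect_true(thr > 0 && thr < 255)
  expect_equal(sum(f2 < thr), 30)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate histogram")
})

test_that("binarization uses one fixed threshold from the reference frame", {
  set.seed(4)
  # blank bright stack with weak noise: nothing below the wrinkle threshold
  g <- generate_wrinkle_timelapse(seed = 11, return_masks = TRUE)
  bin <- binarize_stack(g$stack)
  # foreground equals ground-truth mask up to a 1-px boundary band
  for (t in c(10, 40, 64)) {
    truth <- g$truth$masks[[t]]
    got <- bin$masks[[t]]
    core <- EBImage::imageData(EBImage::erode(matrix(as.numeric(truth),
                                                     nrow(truth)),
                                              EBImage::makeBrush(3, "box"))) > 0.5
    grown <- EBImage::imageData(EBImage::dilate(matrix(as.numeric(truth),
                                                       nrow(truth)),
                                                EBImage::makeBrush(3, "box"))) > 0.5
    expect_true(all(got[core]))        # all interior truth recovered
    expect_true(all(!got[!grown]))     # nothing beyond the grown boundary
  }
  # reference frame is fixed: thresholding a drifting-background stack at
  # frame 1 vs the last frame gives different masks
  drift <- lapply(1:5, function(t) matrix(0.2 + 0.1 * t, 8, 8) +
                    matrix(seq(0, 0.3, length.out = 64), 8, 8))
  ds <- image_stack(drift, pixel_size_um = 1, frame_interval_s = 1)
  m_first <- binarize_stack(ds, reference = 1)$masks[[3]]
  m_last <- binarize_stack(ds, reference = "last")$masks[[3]]
  expect_false(identical(m_first, m_last))
  expect_error(binarize_stack(ds, reference = 99), "out of range")
})

test_that("clean_binary removes small objects then opens", {
  m <- matrix(FALSE, 40, 40)
  m[2:3, 2:3] <- TRUE                      # 4 px object: removed
  m[10:14, 10:19] <- TRUE                  # 50 px object: survives
  out <- clean_binary(m, min_size = 5)
  expect_false(any(out[2:3, 2:3]))
  expect_true(any(out[10:14, 10:19]))
  # empty in, empty out
  expect_equal(sum(clean_binary(matrix(FALSE, 5, 5))), 0)
  # isolated single pixels die by opening even with the size filter off
  m2 <- matrix(FALSE, 20, 20); m2[cbind(c(3, 9, 15), c(3, 9, 15))] <- TRUE
  expect_equal(sum(clean_binary(m2, min_size = 1)), 0)
})

test_that("skeletonization preserves topology and component lengths", {
  # two disjoint bars, widths 3, lengths 10 and 20
  m <- ribbon_mask(60, 60, 10, 10, 0, 10, 3) |
       ribbon_mask(60, 60, 40, 10, 0, 20, 3)
  sk <- skeletonize_and_label(m)
  expect_equal(sk$n_components, 2L)
  expect_equal(max(sk$sizes), 20, tolerance = 0.1)  # +-2 px end effects
  # empty mask
  expect_equal(skeletonize_and_label(matrix(FALSE, 10, 10))$n_components, 0L)
  # Y-shaped ribbon: one component, length ~ sum of the arms
  t <- seq(0, 20, by = 1)
  arms <- list(c(pi / 2), c(pi / 6), c(-pi / 6))
  idx <- unlist(lapply(arms, function(a) {
    wrinklekit:::stamp_polyline(40 + t * sin(a[1]), 40 + t * cos(a[1]), 2, 80, 80)
  }))
  y <- matrix(FALSE, 80, 80); y[unique(idx)] <- TRUE
  sky <- skeletonize_and_label(y)
  expect_equal(sky$n_components, 1L)
  expect_equal(sum(sky$sizes), 3 * 20, tolerance = 0.15)  # branch-point slack
  # skeleton is contained in the mask
  expect_true(all(y[sky$skeleton]))
})

test_that("8-connected labeling joins diagonals and partitions the skeleton", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[5, 5] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2L)               # diagonal pair is one component
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(all((lab > 0) == m))
})

test_that("wrinkle_metrics matches generator ground truth", {
  g <- generate_wrinkle_timelapse(seed = 21)
  wm <- wrinkle_metrics(g$stack)
  tr <- g$truth$per_frame
  expect_gte(mean(wm$N == tr$N_true), 0.95)
  nz <- tr$L_true_mm > 0
  rel <- abs(wm$L_mm[nz] - tr$L_true_mm[nz]) / tr$L_true_mm[nz]
  expect_gte(mean(rel <= 0.05), 0.95)
  # determinism: identical stack and config give identical metrics
  expect_identical(wm, wrinkle_metrics(g$stack))
  # L = 0 exactly when N = 0
  expect_true(all((wm$L_mm == 0) == (wm$N == 0)))
  # geodesic variant (Euclidean path length) stays within sqrt(2) of the
  # pixel-count length and is positive whenever wrinkles exist
  wg <- wrinkle_metrics(g$stack, length_method = "geodesic")
  sel <- wm$N > 0
  expect_true(all(wg$L_mm[sel] <= sqrt(2) * wm$L_mm[sel] + 1e-9))
  expect_true(all(wg$L_mm[sel] > 0))
})

test_that("merging two components decreases N and never shrinks the longest", {
  # constructed fixture: two bars that a third frame bridges
  bar1 <- ribbon_mask(50, 80, 25, 8, 0, 20, 3)
  bar2 <- ribbon_mask(50, 80, 25, 48, 0, 20, 3)
  bridge <- ribbon_mask(50, 80, 25, 26, 0, 24, 3)
  f_apart <- matrix(0.8, 50, 80); f_apart[bar1 | bar2] <- 0.2
  f_merged <- matrix(0.8, 50, 80); f_merged[bar1 | bar2 | bridge] <- 0.2
  st <- image_stack(list(f_apart, f_merged), pixel_size_um = 1,
                    frame_interval_s = 1)
  wm <- wrinkle_metrics(st, min_size = 1)
  expect_equal(wm$N, c(2L, 1L))
  expect_gte(wm$L_mm[2], wm$L_mm[1])
})

test_that("pure-merger dynamics give a non-decreasing longest wrinkle", {
  g <- generate_wrinkle_timelapse(seed = 8, pure_merger = TRUE, frames = 40)
  tr <- g$truth$per_frame
  # truth length never drops by more than junction-dedup jitter (~3 px)
  expect_true(all(diff(tr$L_true_mm) > -3 * g$stack$pixel_size_um / 1000))
  wm <- wrinkle_metrics(g$stack)
  # measured L may fluctuate by single pixels; allow a 3% dip
  expect_true(all(diff(wm$L_mm) > -0.03 * pmax(wm$L_mm[-nrow(wm)], 1e-9)))
  # merge events only reduce N after nucleation stops (all nucleate at t=1)
  expect_true(all(diff(tr$N_true) <= 0))
})

test_that("missing pixel size falls back to pixel units with a warning", {
  f <- matrix(0.8, 30, 30); f[10:20, 14:16] <- 0.2
  st <- image_stack(list(f), frame_interval_s = 1)  # no pixel size
  expect_warning(wm <- wrinkle_metrics(st), "pixel")
  expect_true("L_px" %in% names(wm))
})

test_that("stage segmentation recovers constructed boundaries", {
  sim <- simulate_wrinkle_metrics(seed = 2)
  seg <- segment_stages(sim$metrics)
  expect_true(seg$plateau_found)
  expect_lte(abs(seg$n_peak - sim$truth$stage1_end_frame), 2)
  expect_lte(abs(seg$plateau_onset - sim$truth$stage2_end_frame), 2)
  # stages are contiguous, ordered, non-overlapping
  lab <- seg$labels[!is.na(seg$labels)]
  expect_true(all(diff(lab) >= 0))
  expect_equal(sort(unique(lab)), 1:3)
  # paper-like timings: 6.5 h and 3.5 h at 5-min frames
  expect_equal(sim$truth$stage1_end_frame, 78L)
  expect_equal(sim$truth$stage2_end_frame, 120L)
  # degenerate case: N rising with no L plateau -> stage 3 empty, flagged
  mono <- data.frame(N = 1:30, L_mm = seq(0.1, 3, length.out = 30))
  seg2 <- segment_stages(mono)
  expect_false(seg2$plateau_found)
  expect_true(all(is.na(seg2$labels) | seg2$labels < 3))
  expect_error(segment_stages(data.frame(N = c(0, 0, 1), L_mm = c(0, 0, 1))),
               "no wrinkles")
})

test_that("effective thickness is the area-weighted top of the signal", {
  # uniform slab 0..40 um at 1 um steps
  slab <- z_stack(rep(list(matrix(1, 10, 10)), 40), z_step_um = 1)
  expect_equal(effective_thickness(slab, 0.5)$mean_um, 40)
  # buckled phantom: flat 15 um everywhere, hollow ridges to 60 um on 30%
  nz <- 60
  ridge <- matrix(FALSE, 10, 10); ridge[, 1:3] <- TRUE   # 30% of area
  slices <- lapply(seq_len(nz), function(z) {
    s <- matrix(0, 10, 10)
    if (z <= 15) s[] <- 1                      # flat film
    if (z >= 58) s[ridge] <- 1                 # thin roof of the ridge at 60
    s
  })
  ph <- z_stack(slices, z_step_um = 1)
  got <- effective_thickness(ph, 0.5)
  expect_equal(got$mean_um, 0.7 * 15 + 0.3 * 60)         # 28.5, exact
  # all-dark stack: zero with a warning
  dark <- z_stack(rep(list(matrix(0, 4, 4)), 5), z_step_um = 2)
  expect_warning(res <- effective_thickness(dark, 0.5), "threshold")
  expect_equal(res$mean_um, 0)
})
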