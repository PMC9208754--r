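# Unit-scale DDM tests run on small movies (64 x 64); full-scale parameter
# recovery lives in the acceptance suite.

test_that("ISF normalization and limits", {
  # f(q, 0) = 1 exactly for any parameters
  set.seed(6)
  for (i in 1:10) {
    expect_equal(isf_swimmer(runif(1, 0.1, 5), 0, runif(1, 1, 80),
                             runif(1, 0.5, 10), runif(1, 0, 5), runif(1)), 1)
  }
  # pure diffusion: exponential decay
  expect_equal(isf_swimmer(1, 0.3, 25, 2, 0.5, 0), exp(-1^2 * 0.5 * 0.3))
  # ISF decays monotonically for swimmers
  tau <- seq(0, 0.2, by = 0.004)
  f <- isf_swimmer(1.5, tau, 25, 2, 0.4, 0.7)
  expect_true(all(f <= 1 + 1e-12) && f[length(f)] < 0.3)
})

test_that("structure function: static movies and noise floors", {
  # identical frames: D is exactly 0
  still <- image_stack(rep(list(matrix(runif(64 * 64), 64, 64)), 10),
                       pixel_size_um = 0.5, frame_interval_s = 1e-3)
  sf0 <- image_structure_function(still, lags = c(1, 2), q_bins = 16)
  expect_true(all(abs(sf0$D) < 1e-20, na.rm = TRUE))
  # static + iid Gaussian noise: flat in tau at the analytic floor
  set.seed(7)
  base <- matrix(0.5, 64, 64)
  sigma <- 0.02
  noisy <- lapply(1:40, function(i) base + matrix(rnorm(64 * 64, 0, sigma), 64, 64))
  sn <- image_stack(noisy, pixel_size_um = 0.5, frame_interval_s = 1e-3)
  sfn <- image_structure_function(sn, lags = c(1, 3, 9), q_bins = 8)
  # expectation: |FFT(d)|^2/N averaged over modes = 2 sigma^2 at every lag
  expect_equal(mean(sfn$D, na.rm = TRUE), 2 * sigma^2, tolerance = 0.05)
  flat <- apply(sfn$D, 1, function(r) diff(range(r)) / mean(r))
  expect_lt(median(flat, na.rm = TRUE), 0.1)
})

test_that("Parseval consistency of the FFT normalization", {
  g <- generate_swimmer_movie(seed = 3, frames = 40, dim = c(64, 64),
                              n_particles = 40)
  sf <- image_structure_function(g$stack, lags = c(1, 5), q_bins = 16)
  expect_equal(sf$parseval_spectral, sf$parseval_real, tolerance = 1e-10)
})

test_that("structure function ignores constant intensity offsets", {
  g <- generate_swimmer_movie(seed = 4, frames = 30, dim = c(64, 64),
                              n_particles = 30, photons = Inf,
                              read_noise_sd = 0)
  sf1 <- image_structure_function(g$stack, lags = c(1, 4), q_bins = 12)
  shifted <- g$stack
  shifted$frames <- lapply(shifted$frames, function(f) f + 0.07)
  sf2 <- image_structure_function(shifted, lags = c(1, 4), q_bins = 12)
  expect_equal(sf1$D, sf2$D, tolerance = 1e-12)
})

test_that("rigid translation puts the first spectral zero at q v tau = 2 pi", {
  # single pattern translating 2 px/frame along +x; difference power along
  # the motion axis is 2 P(q) (1 - cos(q v tau)), zero first at q v tau = 2 pi
  mv <- translating_movie(nr = 64, frames = 12, shift_px = 2)
  f1 <- mv$frames[[1]]; f4 <- mv$frames[[4]]      # lag 3: shift 6 px
  pw <- Mod(stats::fft(f4 - f1))^2
  shift <- 6
  kx <- 0:(64 - 1)
  along <- pw[1, ]                                 # ky = 0 row varies with kx
  expected_zero <- which(abs((kx * shift) %% 64) < 1e-9)  # q v tau multiple of 2 pi
  expect_true(all(along[expected_zero] < 1e-12 * max(along)))
  nonzero <- along[-expected_zero][-1]
  expect_gt(min(nonzero) , 0)
})

test_that("movie-length and lag validation", {
  short <- image_stack(rep(list(matrix(0.5, 8, 8)), 5), pixel_size_um = 1)
  expect_error(image_structure_function(short, lags = 10), "lags must lie in 1..4")
  expect_error(image_structure_function(
    image_stack(list(matrix(0.5, 8, 8)), pixel_size_um = 1)), "2 frames")
})

test_that("swim_speed aggregates converged per-q estimates", {
  fake <- structure(list(
    table = data.frame(q = 1:5, v = c(20, 21, 22, NA, 40),
                       Z = 2, D_diff = 0.4, alpha = 0.7, A = 1, B = 0,
                       rss = 0, converged = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
    q_window = c(0.5, 2.2), global = NULL, sf = NULL), class = "ddm_fit")
  sp <- swim_speed(fake)
  expect_equal(sp$v_mean, 21)                     # flagged fits excluded
  expect_equal(sp$v_sd, sd(c(20, 21, 22)))
  expect_equal(sp$n_q, 3L)
  # all-identical speeds give sd 0
  fake$table$v <- 25; fake$table$converged <- TRUE
  expect_equal(swim_speed(fake)$v_sd, 0)
  # fewer than 3 valid fits is an error
  fake$table$converged <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_error(swim_speed(fake), "insufficient q coverage")
})

test_that("desk-scale parameter recovery on a reduced swimmer movie", {
  # 128 x 128, 800 frames: looser tolerances than the full-scale acceptance
  g <- generate_swimmer_movie(seed = 10, frames = 800, dim = c(128, 128),
                              n_particles = 120)
  sf <- image_structure_function(g$stack, max_pairs = 150)
  fit <- fit_swimmer_isf(sf)
  sp <- swim_speed(fit)
  expect_rel_error(sp$v_mean, 25, 0.15)
  expect_lt(abs(fit$global$alpha - 0.7), 0.2)
  # pure Brownian movie: motile fraction detected as small
  gb <- generate_swimmer_movie(seed = 11, frames = 800, dim = c(128, 128),
                               n_particles = 120, motile_fraction = 0)
  gl <- ddm_global_fit(image_structure_function(gb$stack, max_pairs = 150))
  expect_lt(gl$alpha, 0.1)
  expect_rel_error(gl$D_diff, 0.4, 0.25)
})
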