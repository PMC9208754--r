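#' Swimming-bacteria intermediate scattering function
#'
#' Normalized ISF of a mixed population: a fraction `alpha` of ballistic
#' swimmers with Schulz-distributed speeds (mean `v`, shape `Z`) and a
#' fraction `1 - alpha` of passive diffusers, all sharing diffusivity
#' `D_diff`:
#'
#' \deqn{f(q,\tau) = e^{-q^2 D \tau}\left[(1-\alpha) + \alpha\,
#'   \frac{Z+1}{Z q \bar v \tau}\,
#'   \frac{\sin(Z \tan^{-1}\Lambda)}{(1+\Lambda^2)^{Z/2}}\right],\quad
#'   \Lambda = \frac{q \bar v \tau}{Z+1}}
#'
#' `f(q, 0) = 1` for any parameters.
#'
#' @param q Wavenumber, um^-1.
#' @param tau Lag time(s), s (vectorized).
#' @param v Mean swimming speed, um/s.
#' @param Z Schulz shape parameter (> 0); speed sd is `v / sqrt(Z + 1)`.
#' @param D_diff Diffusivity, um^2/s.
#' @param alpha Motile fraction in `[0, 1]`.
#' @return ISF values in `[0, 1]` (up to numerical noise).
#' @export
isf_swimmer <- function(q, tau, v, Z, D_diff, alpha) {
  qvt <- q * v * tau
  lam <- qvt / (Z + 1)
  ball <- ifelse(qvt < 1e-9, 1,
                 (Z + 1) / (Z * pmax(qvt, 1e-300)) *
                   sin(Z * atan(lam)) / (1 + lam^2)^(Z / 2))
  exp(-q^2 * D_diff * tau) * ((1 - alpha) + alpha * ball)
}

# Default lag set: log-spaced frame lags over [1, n_frames/4].
default_lags <- function(n_frames, n_lags = 24L) {
  max_lag <- max(1L, n_frames %/% 4L)
  unique(round(exp(seq(log(1), log(max_lag), length.out = n_lags))))
}

#' Image structure function D(q, tau) of a movie
#'
#' Core DDM computation: for each frame lag tau, the squared modulus of the
#' 2-D Fourier transform of the image difference `I(t+tau) - I(t)`,
#' averaged over start times `t` and azimuthally averaged into radial
#' wavenumber bins. Because only differences enter, any static background
#' and the DC level drop out.
#'
#' Power is normalized as `|FFT|^2 / (nx*ny)` so that the sum of spectral
#' power over all pixels equals the real-space sum of squared differences
#' (Parseval); wavenumbers are physical, `q = 2 pi f / pixel_size` in
#' um^-1. The zero-frequency pixel is excluded from binning and bins are
#' linear up to the axial Nyquist wavenumber.
#'
#' @param movie An [image_stack()] with known pixel size.
#' @param lags Integer frame lags; default log-spaced over
#'   `[1, n_frames/4]`.
#' @param q_bins Number of radial wavenumber bins (default 64).
#' @param max_pairs Cap on start times averaged per lag (default 300);
#'   start times are spread evenly over the available range.
#' @return Object of class `structure_function`: matrix `D` (q_bins x
#'   n_lags), bin-centre `q` (um^-1), lag times `tau` (s), pair counts, and
#'   Parseval bookkeeping used by the validity checks.
#' @export
image_structure_function <- function(movie, lags = NULL, q_bins = 64L,
                                     max_pairs = 300L) {
  stopifnot(inherits(movie, "image_stack"))
  if (is.na(movie$pixel_size_um)) stop("movie needs a pixel size", call. = FALSE)
  nf <- n_frames(movie)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  if (is.null(lags)) lags <- default_lags(nf)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L) || any(lags >= nf)) {
    stop(sprintf("lags must lie in 1..%d (movie has %d frames)", nf - 1L, nf),
         call. = FALSE)
  }
  nr <- nrow(movie$frames[[1]]); nc <- ncol(movie$frames[[1]])
  px <- movie$pixel_size_um
  # physical wavenumber of every FFT pixel
  fr <- ifelse(seq_len(nr) - 1L > nr %/% 2, (seq_len(nr) - 1L) - nr, seq_len(nr) - 1L) / nr
  fc <- ifelse(seq_len(nc) - 1L > nc %/% 2, (seq_len(nc) - 1L) - nc, seq_len(nc) - 1L) / nc
  qmat <- 2 * pi * sqrt(outer(fr^2, fc^2, "+")) / px
  q_nyq <- pi / px
  edges <- seq(0, q_nyq, length.out = q_bins + 1L)
  bin <- findInterval(qmat, edges, rightmost.closed = TRUE)
  bin[qmat == 0 | qmat > q_nyq] <- 0L          # drop DC and corner bins
  binv <- as.vector(bin)
  counts <- tabulate(binv[binv > 0L], nbins = q_bins)
  D <- matrix(NA_real_, q_bins, length(lags))
  n_pairs <- integer(length(lags))
  pw_real <- pw_spec <- numeric(length(lags))
  npx <- nr * nc
  # mean single-frame power spectrum: its doubled value is the large-lag
  # plateau A(q) + B(q) of the structure function, which anchors the fits
  # when the movie is shorter than the slowest decay
  psample <- unique(round(seq(1L, nf, length.out = min(nf, 200L))))
  pacc <- matrix(0, nr, nc)
  for (t0 in psample) {
    fr0 <- movie$frames[[t0]]
    pacc <- pacc + Mod(stats::fft(fr0 - mean(fr0)))^2
  }
  pacc <- pacc / (length(psample) * npx)
  psums <- rowsum(as.vector(pacc)[binv > 0L], binv[binv > 0L])
  pbar <- rep(NA_real_, q_bins)
  pbar[as.integer(rownames(psums))] <- psums / counts[as.integer(rownames(psums))]
  for (li in seq_along(lags)) {
    lag <- lags[li]
    starts <- unique(round(seq(1L, nf - lag, length.out = min(max_pairs, nf - lag))))
    acc <- matrix(0, nr, nc)
    ssq <- 0
    for (t0 in starts) {
      d <- movie$frames[[t0 + lag]] - movie$frames[[t0]]
      acc <- acc + Mod(stats::fft(d))^2
      ssq <- ssq + sum(d^2)
    }
    acc <- acc / (length(starts) * npx)
    n_pairs[li] <- length(starts)
    pw_real[li] <- ssq / length(starts)
    pw_spec[li] <- sum(acc)
    sums <- rowsum(as.vector(acc)[binv > 0L], binv[binv > 0L])
    D[as.integer(rownames(sums)), li] <- sums / counts[as.integer(rownames(sums))]
  }
  structure(list(D = D, plateau = 2 * pbar,
                 q = (edges[-1] + edges[-(q_bins + 1L)]) / 2,
                 tau = lags * movie$frame_interval_s,
                 lags = lags, n_pairs = n_pairs,
                 parseval_real = pw_real, parseval_spectral = pw_spec,
                 fps = 1 / movie$frame_interval_s, pixel_size_um = px),
            class = "structure_function")
}

#' @export
print.structure_function <- function(x, ...) {
  cat(sprintf("<structure_function> %d q bins (%.2f..%.2f um^-1), %d lags (%.4g..%.4g s)\n",
              length(x$q), min(x$q), max(x$q), length(x$tau), min(x$tau), max(x$tau)))
  invisible(x)
}

#' @export
plot.structure_function <- function(x, q_select = NULL, ...) {
  if (is.null(q_select)) {
    q_select <- unique(round(seq(2, length(x$q) - 1, length.out = 6)))
  }
  graphics::matplot(x$tau, t(x$D[q_select, , drop = FALSE]), type = "b",
                    log = "x", pch = 1, lty = 1,
                    xlab = expression(tau ~ "(s)"),
                    ylab = expression(D(q, tau)), ...)
  graphics::legend("topleft", legend = sprintf("q = %.2f", x$q[q_select]),
                   col = seq_along(q_select), lty = 1, cex = 0.7)
  invisible(x)
}

#' Global Schulz-swimmer fit across the q window
#'
#' Fits a single set of population parameters (mean speed `v`, Schulz
#' shape `Z`, diffusivity `D_diff`, motile fraction `alpha`) jointly to
#' every wavenumber bin in `q_window`, with a per-q noise floor `B(q)` and
#' the per-q amplitude anchored to the frame-power plateau. Pooling across
#' q resolves the degeneracy between the Schulz tail, the motile fraction
#' and the diffusive branch that per-q fits suffer from on short movies:
#' ballistic decay rates scale with q while diffusive rates scale with
#' q^2, so only the joint fit separates them cleanly.
#'
#' @param sf A [image_structure_function()] result.
#' @param q_window Wavenumber window for the joint fit (default 0.5-3.2
#'   um^-1; the high-q bins pin the noise floor and the diffusive branch).
#' @return Object of class `ddm_global_fit` with fields `v`, `Z`,
#'   `D_diff`, `alpha`, `B` (per q), `q`, `q_window`, `rss`.
#' @export
ddm_global_fit <- function(sf, q_window = c(0.5, 3.2)) {
  stopifnot(inherits(sf, "structure_function"))
  qs <- which(sf$q >= q_window[1] & sf$q <= q_window[2] &
                apply(is.finite(sf$D), 1, all) & is.finite(sf$plateau))
  if (length(qs) < 3L) stop("q_window contains fewer than 3 computed q bins",
                            call. = FALSE)
  tau <- sf$tau
  nl <- length(tau)
  yn <- as.vector(t(sf$D[qs, , drop = FALSE] / sf$plateau[qs]))
  qvec <- rep(sf$q[qs], each = nl)
  tvec <- rep(tau, length(qs))
  qid <- rep(seq_along(qs), each = nl)
  resid_fn <- function(p) {
    bv <- p[4L + qid]
    (1 - bv) * (1 - isf_swimmer(qvec, tvec, p[1], p[2], p[3], p[4])) + bv - yn
  }
  start <- c(20, 2, 0.3, 0.5,
             vapply(split(yn, qid), min, numeric(1)))
  lower <- c(1, 0.5, 0, 0, rep(0, length(qs)))
  upper <- c(100, 10, 5, 1, rep(1, length(qs)))
  out <- minpack.lm::nls.lm(start, lower, upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  structure(list(v = out$par[1], Z = out$par[2], D_diff = out$par[3],
                 alpha = out$par[4], B = out$par[-(1:4)] * sf$plateau[qs],
                 q = sf$q[qs], q_window = q_window,
                 rss = sum(out$fvec^2), info = out$info),
            class = "ddm_global_fit")
}

#' @export
print.ddm_global_fit <- function(x, ...) {
  cat(sprintf("<ddm_global_fit> %d q bins in [%.2f, %.2f] um^-1\n",
              length(x$q), x$q_window[1], x$q_window[2]))
  cat(sprintf("  v = %.2f um/s, Z = %.2f, D = %.3f um^2/s, alpha = %.3f\n",
              x$v, x$Z, x$D_diff, x$alpha))
  invisible(x)
}

#' Fit the swimmer ISF to a structure function, one q at a time
#'
#' For every wavenumber bin inside `q_window` the model
#' `D(q, tau) = A(q) [1 - f(q, tau)] + B(q)` with the Schulz-swimmer ISF
#' [isf_swimmer()] is fitted by bounded Levenberg-Marquardt least squares.
#' Initial guesses come from the data (noise floor from the shortest lag,
#' plateau from the longest, speed from the half-decay lag); bounds are
#' `v` in `[1, 100]` um/s, `Z` in `[0.5, 10]`, `alpha` in `[0, 1]`,
#' `D_diff` in `[0, 5]` um^2/s. Non-convergent bins are flagged and
#' excluded downstream, not fatal.
#'
#' The Schulz shape Z is, by default, estimated once by the pooled
#' [ddm_global_fit()] and held fixed in the per-q fits: Z is weakly
#' identified from a single q bin and otherwise trades off against the
#' motile fraction and the diffusivity. Pass a numeric `shape` to fix Z at
#' a chosen value, or `shape = "free"` to fit Z per q.
#'
#' @param sf A [image_structure_function()] result.
#' @param q_window Wavenumber window `c(q_min, q_max)` in um^-1 (default
#'   0.5-2.2: low q is dominated by drift/advection, high q by the noise
#'   floor).
#' @param shape Schulz shape handling: `NULL` (default; global consensus
#'   from [ddm_global_fit()]), a number (held fixed), or `"free"`.
#' @return Object of class `ddm_fit`: per-q parameter table (`q`, `v`, `Z`,
#'   `D_diff`, `alpha`, `A`, `B`, `rss`, `converged`), the global fit used
#'   for the shape (if any), plus the fitted sf.
#' @export
fit_swimmer_isf <- function(sf, q_window = c(0.5, 2.2), shape = NULL) {
  stopifnot(inherits(sf, "structure_function"))
  qs <- which(sf$q >= q_window[1] & sf$q <= q_window[2] &
                apply(is.finite(sf$D), 1, all))
  if (length(qs) == 0L) stop("q_window contains no computed q bins", call. = FALSE)
  gl <- NULL
  if (is.null(shape)) {
    gl <- ddm_global_fit(sf)
    z_fix <- gl$Z
  } else if (is.numeric(shape)) {
    z_fix <- shape
  } else {
    z_fix <- NULL                       # "free": fit Z per q
  }
  tau <- sf$tau
  rows <- lapply(qs, function(qi) {
    q <- sf$q[qi]
    y <- sf$D[qi, ]
    plateau <- sf$plateau[qi]         # A + B from the frame power spectrum
    B0 <- max(min(y), 1e-12)
    A0 <- max(plateau - B0, 1e-12)
    half <- y >= B0 + A0 / 2
    tau_half <- if (any(half)) tau[which(half)[1]] else tau[length(tau)]
    v0 <- min(max(2 / (q * tau_half), 1.5), 90)
    fit <- tryCatch({
      if (is.null(z_fix)) {
        minpack.lm::nlsLM(
          y ~ (plateau - B) * (1 - isf_swimmer(q, tau, v, Z, D_diff, alpha)) + B,
          start = list(B = B0, v = v0, Z = 2, D_diff = 0.3, alpha = 0.7),
          lower = c(B = 0, v = 1, Z = 0.5, D_diff = 0, alpha = 0),
          upper = c(B = plateau, v = 100, Z = 10, D_diff = 5, alpha = 1),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        Zf <- z_fix
        minpack.lm::nlsLM(
          y ~ (plateau - B) * (1 - isf_swimmer(q, tau, v, Zf, D_diff, alpha)) + B,
          start = list(B = B0, v = v0, D_diff = 0.3, alpha = 0.7),
          lower = c(B = 0, v = 1, D_diff = 0, alpha = 0),
          upper = c(B = plateau, v = 100, D_diff = 5, alpha = 1),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(q = q, v = NA_real_, Z = NA_real_, D_diff = NA_real_,
                        alpha = NA_real_, A = NA_real_, B = NA_real_,
                        rss = NA_real_, converged = FALSE))
    }
    cf <- as.list(stats::coef(fit))
    zz <- if (is.null(z_fix)) cf$Z else z_fix
    data.frame(q = q, v = cf$v, Z = zz, D_diff = cf$D_diff, alpha = cf$alpha,
               A = plateau - cf$B, B = cf$B, rss = sum(stats::resid(fit)^2),
               converged = TRUE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, q_window = q_window, global = gl, sf = sf),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  ok <- x$table$converged
  cat(sprintf("<ddm_fit> %d/%d q bins converged in window [%.2f, %.2f] um^-1\n",
              sum(ok), nrow(x$table), x$q_window[1], x$q_window[2]))
  if (any(ok)) {
    cat(sprintf("  v = %.1f um/s, alpha = %.2f, D = %.2f um^2/s (medians over q)\n",
                stats::median(x$table$v[ok]), stats::median(x$table$alpha[ok]),
                stats::median(x$table$D_diff[ok])))
  }
  invisible(x)
}

#' @export
coef.ddm_fit <- function(object, ...) {
  as.matrix(object$table[, c("q", "v", "Z", "D_diff", "alpha", "A", "B")])
}

#' @export
summary.ddm_fit <- function(object, ...) {
  ok <- object$table$converged
  out <- list(table = object$table,
              v_median = stats::median(object$table$v[ok]),
              alpha_median = stats::median(object$table$alpha[ok]),
              D_median = stats::median(object$table$D_diff[ok]),
              n_ok = sum(ok))
  class(out) <- "summary.ddm_fit"
  out
}

#' @export
print.summary.ddm_fit <- function(x, ...) {
  cat(sprintf("ddm_fit: %d converged q bins\n", x$n_ok))
  cat(sprintf("  median v = %.2f um/s, alpha = %.3f, D = %.3f um^2/s\n",
              x$v_median, x$alpha_median, x$D_median))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
plot.ddm_fit <- function(x, n_curves = 4, ...) {
  ok <- which(x$table$converged)
  pick <- ok[unique(round(seq(1, length(ok), length.out = n_curves)))]
  tau <- x$sf$tau
  qi_all <- match(x$table$q, x$sf$q)
  graphics::matplot(tau, t(x$sf$D[qi_all[pick], , drop = FALSE]), log = "x",
                    pch = 1, xlab = expression(tau ~ "(s)"),
                    ylab = expression(D(q, tau)), ...)
  tt <- exp(seq(log(min(tau)), log(max(tau)), length.out = 100))
  for (k in seq_along(pick)) {
    p <- x$table[pick[k], ]
    graphics::lines(tt, p$A * (1 - isf_swimmer(p$q, tt, p$v, p$Z, p$D_diff, p$alpha)) + p$B,
                    col = k)
  }
  invisible(x)
}

#' Mean swimming speed over the q window
#'
#' Aggregates the per-q speed estimates of a [fit_swimmer_isf()] into a
#' single swim-speed estimate: mean and standard deviation of `v(q)` over
#' the converged wavenumber bins.
#'
#' @param fits A `ddm_fit` object.
#' @return Object of class `speed_estimate` with fields `v_mean`, `v_sd`
#'   (um/s), `n_q`, `q_window`, and the per-q `table`.
#' @export
swim_speed <- function(fits) {
  stopifnot(inherits(fits, "ddm_fit"))
  tab <- fits$table[fits$table$converged, ]
  if (nrow(tab) < 3L) stop("insufficient q coverage: fewer than 3 valid fits",
                           call. = FALSE)
  structure(list(v_mean = mean(tab$v), v_sd = stats::sd(tab$v),
                 alpha_mean = mean(tab$alpha), D_mean = mean(tab$D_diff),
                 n_q = nrow(tab), q_window = fits$q_window, table = tab),
            class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf("swim speed: %.1f +/- %.1f um/s (n = %d q bins, q in [%.2f, %.2f] um^-1)\n",
              x$v_mean, x$v_sd, x$n_q, x$q_window[1], x$q_window[2]))
  invisible(x)
}
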