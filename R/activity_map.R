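# Block-mean over b x b tiles; input is cropped to a whole number of tiles
# by the caller.
block_mean <- function(m, b) {
  nbr <- nrow(m) %/% b
  nbc <- ncol(m) %/% b
  s <- rowsum(m, rep(seq_len(nbr), each = b), reorder = FALSE)
  t(rowsum(t(s), rep(seq_len(nbc), each = b), reorder = FALSE)) / (b * b)
}

#' Degree of correlation of one region of interest between two frames
#'
#' The ROI-level intensity correlation
#' \deqn{c_I = \frac{\langle I_p(t)\, I_p(t+\tau)\rangle_r}
#'   {\langle I_p(t)\rangle_r\,\langle I_p(t+\tau)\rangle_r} - 1}
#' where the averages run over the pixels of the ROI. For identical frames
#' this is the squared coefficient of variation of the ROI texture; for
#' frames whose intensities have become statistically independent it is 0.
#'
#' @param frame_t,frame_t_plus_tau Numeric matrices of identical shape.
#' @param rows,cols Integer index vectors selecting the ROI.
#' @return Scalar raw correlation, or `NA` (flagged ROI) when either ROI
#'   mean is not positive.
#' @export
roi_correlation <- function(frame_t, frame_t_plus_tau, rows, cols) {
  stopifnot(all(dim(frame_t) == dim(frame_t_plus_tau)))
  a <- frame_t[rows, cols]
  b <- frame_t_plus_tau[rows, cols]
  ma <- mean(a); mb <- mean(b)
  if (ma <= 0 || mb <= 0) return(NA_real_)
  mean(a * b) / (ma * mb) - 1
}

#' Spatially resolved activity map from intensity correlation
#'
#' Subdivides each frame into square regions of interest, computes the raw
#' degree of correlation between frame pairs separated by `tau_s`, averages
#' over `n_pairs` pairs, and normalizes. Motile bacteria decorrelate the
#' intensity within a ROI on the timescale of their swimming, so a low
#' normalized correlation marks an active region while static biofilm
#' stays near 1.
#'
#' Normalization: the averaged correlation at lag `tau_s` is divided by the
#' averaged correlation at a one-frame lag and clamped to `[0, 1]`. The
#' one-frame reference carries the full static-texture contrast
#' (variance/mean^2) of the ROI, so the ratio removes texture contrast and
#' leaves only the fraction of correlation surviving to `tau_s`.
#'
#' @param movie An [image_stack()] with pixel size and frame interval set.
#' @param tau_s Correlation lag in seconds (default 1). Must be an integer
#'   number of frames at the movie's frame rate.
#' @param n_pairs Number of frame pairs averaged (default 200), taken as
#'   the first valid `(t, t + tau)` pairs stepping t by one frame.
#' @param roi_um ROI edge length in micrometres (default 2.5); rounded to
#'   the nearest even pixel count, minimum 2. Frames are cropped to an
#'   integer ROI grid.
#' @return Object of class `activity_map`: `normalized` matrix in
#'   `[0, 1]` (one value per ROI), `raw_tau`, `raw_ref` (one-frame lag),
#'   ROI geometry and averaging metadata.
#' @export
activity_map <- function(movie, tau_s = 1, n_pairs = 200L, roi_um = 2.5) {
  stopifnot(inherits(movie, "image_stack"))
  if (is.na(movie$pixel_size_um)) stop("movie needs a pixel size", call. = FALSE)
  dt <- movie$frame_interval_s
  tau_frames <- tau_s / dt
  if (abs(tau_frames - round(tau_frames)) > 1e-6) {
    stop(sprintf("tau = %g s is not a whole number of frames at %g fps; nearest representable tau is %g s",
                 tau_s, 1 / dt, round(tau_frames) * dt), call. = FALSE)
  }
  tau_frames <- max(1L, as.integer(round(tau_frames)))
  nf <- n_frames(movie)
  avail <- nf - tau_frames
  if (avail < 1L) stop("movie shorter than the correlation lag", call. = FALSE)
  if (avail < n_pairs) {
    n_pairs <- avail
    warning(sprintf("movie supports only %d pairs at this lag; using all of them", avail))
  }
  b <- max(2L, 2L * as.integer(round(roi_um / movie$pixel_size_um / 2)))
  nbr <- nrow(movie$frames[[1]]) %/% b
  nbc <- ncol(movie$frames[[1]]) %/% b
  if (nbr < 1L || nbc < 1L) stop("ROI larger than the frame", call. = FALSE)
  rows <- seq_len(nbr * b); cols <- seq_len(nbc * b)
  pair_corr <- function(lag, t0) {
    a <- movie$frames[[t0]][rows, cols]
    bb <- movie$frames[[t0 + lag]][rows, cols]
    num <- block_mean(a * bb, b)
    d1 <- block_mean(a, b)
    d2 <- block_mean(bb, b)
    out <- num / (d1 * d2) - 1
    out[d1 <= 0 | d2 <= 0] <- NA_real_
    out
  }
  acc_tau <- matrix(0, nbr, nbc); acc_ref <- matrix(0, nbr, nbc)
  for (t0 in seq_len(n_pairs)) {
    acc_tau <- acc_tau + pair_corr(tau_frames, t0)
    acc_ref <- acc_ref + pair_corr(1L, t0)
  }
  raw_tau <- acc_tau / n_pairs
  raw_ref <- acc_ref / n_pairs
  norm <- raw_tau / raw_ref
  norm[!is.finite(norm) | raw_ref <= 0] <- NA_real_
  norm <- pmin(pmax(norm, 0), 1)
  structure(list(normalized = norm, raw_tau = raw_tau, raw_ref = raw_ref,
                 roi_px = b, roi_um = b * movie$pixel_size_um,
                 tau_s = tau_frames * dt, n_pairs = n_pairs),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map> %d x %d ROIs of %d px (%.2f um), tau = %g s, %d pairs\n",
              nrow(x$normalized), ncol(x$normalized), x$roi_px, x$roi_um,
              x$tau_s, x$n_pairs))
  cat(sprintf("  normalized correlation: median %.2f, min %.2f\n",
              stats::median(x$normalized, na.rm = TRUE),
              min(x$normalized, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.activity_map <- function(x, ...) {
  graphics::image(t(x$normalized)[, rev(seq_len(nrow(x$normalized)))],
                  zlim = c(0, 1), col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = nrow(x$normalized) / ncol(x$normalized),
                  main = "normalized degree of correlation", ...)
  invisible(x)
}

#' Classify ROIs as active or static
#'
#' Thresholds the normalized correlation map: ROIs below `threshold` are
#' active (motile bacteria), the rest static.
#'
#' @param map An [activity_map()].
#' @param threshold Classification threshold on the normalized correlation
#'   (default 0.5).
#' @return Logical matrix, `TRUE` = active ROI.
#' @export
classify_activity <- function(map, threshold = 0.5) {
  stopifnot(inherits(map, "activity_map"))
  map$normalized < threshold
}
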