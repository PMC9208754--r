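#' Otsu intensity threshold of a grayscale frame
#'
#' Computes the threshold maximizing the between-class variance of the
#' frame's gray-level histogram. The returned value is the midpoint between
#' the two gray levels straddling the optimal split, so the class
#' assignment is unambiguous regardless of comparison convention.
#'
#' @param frame Numeric matrix with at least two distinct values.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(frame) {
  v <- as.vector(frame)
  levels <- sort(unique(v))
  k <- length(levels)
  if (k < 2L) stop("degenerate histogram: frame has a single gray level", call. = FALSE)
  counts <- tabulate(match(v, levels), nbins = k)
  p <- counts / length(v)
  w <- cumsum(p)                 # class-0 weight after splitting below level i
  mu <- cumsum(p * levels)
  mu_t <- mu[k]
  # between-class variance for split after level i (i = 1..k-1)
  i <- seq_len(k - 1L)
  sigma_b <- (mu_t * w[i] - mu[i])^2 / (w[i] * (1 - w[i]))
  best <- which.max(sigma_b)
  (levels[best] + levels[best + 1L]) / 2
}

#' Binarize every frame of a stack with one fixed threshold
#'
#' The threshold is determined once, by Otsu's method on a single reference
#' frame (by default the last frame, where the wrinkle network is fully
#' developed and the histogram most clearly bimodal), and applied unchanged
#' to all frames. Foreground is the wrinkle phase: dark pixels under the
#' default polarity.
#'
#' @param stack An [image_stack()].
#' @param reference Frame index used for thresholding, or `"last"`.
#' @param polarity `"dark"` (wrinkles darker than background, default) or
#'   `"bright"` for inverted-contrast input.
#' @return Object of class `binary_stack`: list of logical masks plus the
#'   threshold and metadata.
#' @export
binarize_stack <- function(stack, reference = "last",
                           polarity = c("dark", "bright")) {
  stopifnot(inherits(stack, "image_stack"))
  polarity <- match.arg(polarity)
  nf <- n_frames(stack)
  ref <- if (identical(reference, "last")) nf else as.integer(reference)
  if (is.na(ref) || ref < 1L || ref > nf) {
    stop(sprintf("reference frame %s out of range 1..%d", reference, nf),
         call. = FALSE)
  }
  thr <- otsu_threshold(stack$frames[[ref]])
  masks <- lapply(stack$frames, function(f) {
    if (polarity == "dark") f < thr else f > thr
  })
  structure(list(masks = masks, threshold = thr, reference = ref,
                 polarity = polarity,
                 pixel_size_um = stack$pixel_size_um,
                 frame_interval_s = stack$frame_interval_s),
            class = "binary_stack")
}

#' Clean a binary wrinkle mask
#'
#' Removes connected foreground objects smaller than `min_size` pixels
#' (8-connected), then applies a binary morphological opening with a 3x3
#' square structuring element. This is the standard despeckling step
#' between thresholding and skeletonization.
#'
#' @param mask Logical matrix.
#' @param min_size Minimum object size in pixels kept (default 5: objects
#'   smaller than 5 px are removed).
#' @param opening Logical; apply the 3x3 opening (default `TRUE`).
#' @return Cleaned logical matrix.
#' @export
clean_binary <- function(mask, min_size = 5L, opening = TRUE) {
  mask <- mask > 0
  if (min_size > 1L && any(mask)) {
    lab <- label_components(mask)
    sizes <- component_sizes(lab)
    keep <- which(sizes >= min_size)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (opening && any(mask)) {
    opened <- EBImage::opening(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                               EBImage::makeBrush(3L, shape = "box"))
    mask <- EBImage::imageData(opened) > 0.5
  }
  mask
}

#' Skeletonize a cleaned mask and label its connected wrinkles
#'
#' Thins the mask to a 1-px skeleton ([skeletonize()]), labels its
#' 8-connected components, and records per-component pixel counts. Each
#' component is one isolated wrinkle (or one connected wrinkle cluster).
#'
#' @param mask Cleaned logical matrix.
#' @return Object of class `skeleton_graph` with fields `skeleton`
#'   (logical matrix), `labels` (integer matrix), `sizes` (pixel count per
#'   component) and `n_components`.
#' @export
skeletonize_and_label <- function(mask) {
  skel <- skeletonize(mask)
  lab <- label_components(skel)
  sizes <- component_sizes(lab)
  structure(list(skeleton = skel, labels = lab, sizes = sizes,
                 n_components = length(sizes)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d components, %d skeleton px\n",
              x$n_components, sum(x$sizes)))
  invisible(x)
}

# Approximate geodesic diameter (longest shortest path, in px length units)
# of one labelled skeleton component, via a double-sweep Dijkstra on the
# pixel graph with orthogonal weight 1 and diagonal weight sqrt(2). Exact on
# tree-shaped skeletons; a lower bound on skeletons with cycles.
geodesic_diameter <- function(labels, component) {
  idx <- which(labels == component)
  if (length(idx) < 2L) return(as.numeric(length(idx) > 0L))
  nr <- nrow(labels)
  id <- integer(length(labels)); id[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  inset <- matrix(FALSE, nr, ncol(labels)); inset[idx] <- TRUE
  edges <- NULL; w <- NULL
  shifts <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))
  for (s in shifts) {
    ok <- rows + s[1] >= 1L & rows + s[1] <= nr & cols + s[2] <= ncol(labels)
    src <- idx[ok]; dst <- src + s[1] + s[2] * nr
    conn <- inset[dst]
    if (any(conn)) {
      edges <- rbind(edges, cbind(id[src[conn]], id[dst[conn]]))
      w <- c(w, rep(s[3], sum(conn)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::E(g)$weight <- w
  d1 <- igraph::distances(g, v = 1)
  u <- which.max(d1)
  d2 <- igraph::distances(g, v = u)
  max(d2)
}

#' Per-frame wrinkle count and longest-wrinkle length
#'
#' Runs the full quantification pipeline on a timelapse: one fixed Otsu
#' threshold from the reference frame, per-frame cleaning (small-object
#' removal + opening), skeletonization and 8-connected labeling. For each
#' frame it reports `N`, the number of isolated wrinkles (skeleton
#' components), and `L`, the length of the longest connected wrinkle.
#'
#' `L` is, by default, the total skeleton length of the largest component
#' (pixel count times pixel size) — what component labeling of a branched
#' network naturally yields. `length_method = "geodesic"` instead reports
#' the end-to-end geodesic diameter of that component, for comparison.
#'
#' @param stack An [image_stack()].
#' @param min_size Small-object threshold in px (see [clean_binary()]).
#' @param reference Thresholding reference frame (see [binarize_stack()]).
#' @param polarity Wrinkle contrast polarity (see [binarize_stack()]).
#' @param length_method `"total"` (default) or `"geodesic"`.
#' @return A data.frame of class `wrinkle_metrics` with columns `frame`,
#'   `time_s`, `N`, `L_mm` (or `L_px` when the stack has no pixel size,
#'   with a warning).
#' @export
wrinkle_metrics <- function(stack, min_size = 5L, reference = "last",
                            polarity = "dark",
                            length_method = c("total", "geodesic")) {
  length_method <- match.arg(length_method)
  bin <- binarize_stack(stack, reference = reference, polarity = polarity)
  nf <- length(bin$masks)
  N <- integer(nf); L_px <- numeric(nf)
  for (i in seq_len(nf)) {
    res <- tryCatch({
      cleaned <- clean_binary(bin$masks[[i]], min_size = min_size)
      skeletonize_and_label(cleaned)
    }, error = function(e) {
      stop(sprintf("frame %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
    N[i] <- res$n_components
    if (res$n_components > 0L) {
      big <- which.max(res$sizes)
      L_px[i] <- if (length_method == "total") {
        res$sizes[big]
      } else {
        geodesic_diameter(res$labels, big)
      }
    }
  }
  px <- stack$pixel_size_um
  out <- data.frame(frame = seq_len(nf),
                    time_s = (seq_len(nf) - 1L) * stack$frame_interval_s,
                    N = N)
  if (is.na(px)) {
    warning("stack has no pixel size; lengths reported in pixels (L_px)")
    out$L_px <- L_px
  } else {
    out$L_mm <- L_px * px / 1000
  }
  attr(out, "threshold") <- bin$threshold
  attr(out, "length_method") <- length_method
  class(out) <- c("wrinkle_metrics", "data.frame")
  out
}

#' Segment wrinkle-metric time series into the three growth stages
#'
#' The wrinkling process proceeds in three stages: (1) nucleation — the
#' number of isolated wrinkles N rises steeply while the longest wrinkle
#' stays short; (2) merging — wrinkles connect, N falls and the longest
#' connected wrinkle L grows rapidly; (3) steady state — L plateaus and N
#' stays low. Boundaries are placed at the peak of a smoothed N(t) and at
#' the onset of the L plateau.
#'
#' @param metrics A [wrinkle_metrics()] data.frame (or any data.frame with
#'   columns `N` and `L_mm`/`L_px`).
#' @param plateau_frac L is "at plateau" when within this fraction of its
#'   final value (default 0.05).
#' @param plateau_frames Number of consecutive at-plateau frames required
#'   to call the stage-2/3 boundary (default 5).
#' @param smooth_window Centered moving-average window for N(t), frames
#'   (default 5).
#' @return Object of class `stage_segmentation`: per-frame stage labels
#'   (NA before the first wrinkle), the three boundary frame indices, and
#'   `plateau_found` (FALSE when L never plateaus; stage 3 is then empty).
#' @export
segment_stages <- function(metrics, plateau_frac = 0.05, plateau_frames = 5L,
                           smooth_window = 5L) {
  N <- metrics$N
  L <- if (!is.null(metrics$L_mm)) metrics$L_mm else metrics$L_px
  nf <- length(N)
  if (sum(N > 0) < 3L) stop("no wrinkles detected: N has fewer than 3 nonzero frames",
                            call. = FALSE)
  start <- which(N > 0)[1]
  Nsm <- moving_average(N, smooth_window)
  peak <- which.max(Nsm)
  if (peak < start) peak <- start
  L_final <- L[nf]
  at_plateau <- abs(L - L_final) <= plateau_frac * L_final
  onset <- NA_integer_
  if (plateau_frames <= nf) {
    run <- cumsum_runs(at_plateau)
    cand <- which(run >= plateau_frames)
    cand <- cand[cand >= peak]
    if (length(cand) > 0L) onset <- cand[1] - plateau_frames + 1L
    if (!is.na(onset) && onset <= peak) onset <- peak + 1L
    if (!is.na(onset) && onset >= nf) onset <- NA_integer_
  }
  labels <- rep(NA_integer_, nf)
  if (is.na(onset)) {
    labels[start:peak] <- 1L
    if (peak < nf) labels[(peak + 1L):nf] <- 2L
    plateau_found <- FALSE
  } else {
    labels[start:peak] <- 1L
    labels[(peak + 1L):onset] <- 2L
    if (onset < nf) labels[(onset + 1L):nf] <- 3L
    plateau_found <- TRUE
  }
  structure(list(labels = labels, stage1_start = start, n_peak = peak,
                 plateau_onset = onset, plateau_found = plateau_found),
            class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat("<stage_segmentation>\n")
  cat(sprintf("  stage 1: frames %d..%d (nucleation)\n", x$stage1_start, x$n_peak))
  if (x$plateau_found) {
    cat(sprintf("  stage 2: frames %d..%d (merging)\n", x$n_peak + 1L, x$plateau_onset))
    cat(sprintf("  stage 3: frames %d.. (steady state)\n", x$plateau_onset + 1L))
  } else {
    cat("  stage 2: frames", x$n_peak + 1L, "..end (no L plateau; stage 3 empty)\n")
  }
  invisible(x)
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, window) {
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Length of the TRUE-run ending at each position.
cumsum_runs <- function(x) {
  out <- integer(length(x))
  run <- 0L
  for (i in seq_along(x)) {
    run <- if (x[i]) run + 1L else 0L
    out[i] <- run
  }
  out
}

#' Confocal z-stack
#'
#' Ordered 2-D slices from substrate (z = 0) upward; slice `i` samples the
#' height `i * z_step_um`.
#'
#' @param slices List of numeric matrices, substrate first.
#' @param z_step_um Slice spacing in micrometres (> 0).
#' @return Object of class `z_stack`.
#' @export
z_stack <- function(slices, z_step_um) {
  stopifnot(is.list(slices), length(slices) > 0L)
  check_positive(z_step_um, "z_step_um")
  structure(list(slices = slices, z_step_um = z_step_um), class = "z_stack")
}

#' Effective biofilm thickness from a confocal z-stack
#'
#' For every (x, y) position the thickness is the height of the topmost
#' slice whose intensity exceeds `signal_threshold` — the distance from the
#' substrate to the top of the (possibly buckled, hollow-channel) biofilm.
#' Voids under a buckled roof therefore count toward the effective
#' thickness, which is exactly why channel-forming biofilms show a larger
#' effective thickness than flat ones.
#'
#' @param zstack A [z_stack()], substrate-first.
#' @param signal_threshold Intensity above which a voxel counts as biofilm.
#' @return List with `mean_um` (field-of-view mean thickness) and
#'   `map_um` (per-pixel thickness matrix). Warns and returns 0 when no
#'   voxel is above threshold.
#' @export
effective_thickness <- function(zstack, signal_threshold) {
  stopifnot(inherits(zstack, "z_stack"))
  nz <- length(zstack$slices)
  top <- matrix(0L, nrow(zstack$slices[[1]]), ncol(zstack$slices[[1]]))
  for (z in seq_len(nz)) {
    above <- zstack$slices[[z]] > signal_threshold
    top[above] <- z
  }
  if (all(top == 0L)) {
    warning("no voxel above signal threshold; thickness is 0")
  }
  map <- top * zstack$z_step_um
  list(mean_um = mean(map), map_um = map)
}
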