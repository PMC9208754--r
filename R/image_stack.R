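#' Time-ordered grayscale image stack
#'
#' Container for timelapse / high-speed microscopy data: an ordered list of
#' equally sized 2-D grayscale matrices plus the physical metadata every
#' downstream analysis needs (pixel size and frame interval). Intensities
#' are stored as numeric matrices in `[0, 1]` regardless of bit depth; the
#' `bit_depth` field records the acquisition depth and controls TIFF output.
#'
#' @param frames List of numeric matrices, all of the same dimensions,
#'   values in `[0, 1]`.
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0), or `NA`
#'   when unknown (length-dependent results are then reported in pixels,
#'   with a warning at the point of use).
#' @param frame_interval_s Time between consecutive frames in seconds (> 0).
#' @param bit_depth 8 or 16.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um = NA_real_,
                        frame_interval_s = 1, bit_depth = 8L) {
  if (!is.list(frames) || length(frames) == 0L ||
      !all(vapply(frames, is.matrix, logical(1)))) {
    stop("'frames' must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have identical dimensions", call. = FALSE)
  }
  if (!is.na(pixel_size_um)) check_positive(pixel_size_um, "pixel_size_um")
  check_positive(frame_interval_s, "frame_interval_s")
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16", call. = FALSE)
  structure(list(frames = frames,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, %s-bit\n",
              length(x$frames), d[1], d[2], x$bit_depth))
  cat(sprintf("  pixel size: %s um/px, frame interval: %g s\n",
              ifelse(is.na(x$pixel_size_um), "unknown",
                     format(x$pixel_size_um)), x$frame_interval_s))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Read a multi-page TIFF into an image stack
#'
#' Frames are loaded in page order. Pixel size is taken from the config
#' argument when given, otherwise from the TIFF x-resolution tag when the
#' file carries one (assumed pixels per centimetre); if neither is
#' available the stack is returned with unknown pixel size.
#'
#' @param path Path to a multi-page grayscale TIFF (8- or 16-bit).
#' @param pixel_size_um Pixel size override in um/px (wins over TIFF tags).
#' @param frame_interval_s Frame interval in seconds (TIFF has no standard
#'   tag for this; default 1 s).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) {
                      stop(sprintf("failed to read TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    m <- as.matrix(p)
    attributes(m) <- attributes(m)["dim"]
    m
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed frame shapes in TIFF; refusing to load", call. = FALSE)
  }
  bps <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bps)) bps <- 8L
  ps <- pixel_size_um
  if (is.null(ps)) {
    xres <- attr(pages[[1]], "x.resolution")  # px per cm, when tagged
    ps <- if (!is.null(xres) && length(xres) == 1L && is.finite(xres) &&
              xres > 0) 1e4 / xres else NA_real_
  }
  image_stack(frames, pixel_size_um = ps, frame_interval_s = frame_interval_s,
              bit_depth = as.integer(bps))
}

#' Write an image stack to a multi-page TIFF
#'
#' Intensities are clamped to `[0, 1]` and quantized to the stack's bit
#' depth, so a write/read round trip is lossless for data already on the
#' 8- or 16-bit grid. Physical metadata (pixel size, frame interval) is
#' not embedded in the TIFF; pass it explicitly to [read_stack()] or keep
#' it in the run configuration.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = stack$bit_depth,
                  reduce = TRUE)
  invisible(path)
}

#' Quantize stack intensities to the bit-depth grid
#'
#' Snaps every pixel to the nearest representable 8- or 16-bit level, which
#' makes TIFF round trips exactly lossless. Generators call this before
#' returning stacks.
#'
#' @param stack An [image_stack()].
#' @return The quantized [image_stack()].
#' @export
quantize_stack <- function(stack) {
  levels <- 2^stack$bit_depth - 1
  stack$frames <- lapply(stack$frames, function(f) {
    round(pmin(pmax(f, 0), 1) * levels) / levels
  })
  stack
}

#' Crop every frame of a stack to a pixel rectangle
#'
#' @param stack An [image_stack()].
#' @param rect `c(r0, r1, c0, c1)` pixel rectangle (inclusive).
#' @return The cropped [image_stack()].
#' @export
crop_stack <- function(stack, rect) {
  stopifnot(inherits(stack, "image_stack"), length(rect) == 4L)
  d <- dim(stack$frames[[1]])
  if (rect[1] < 1 || rect[2] > d[1] || rect[3] < 1 || rect[4] > d[2] ||
      rect[1] > rect[2] || rect[3] > rect[4]) {
    stop("crop rectangle out of bounds", call. = FALSE)
  }
  stack$frames <- lapply(stack$frames, function(f) f[rect[1]:rect[2], rect[3]:rect[4]])
  stack
}
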