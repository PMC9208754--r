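# Unit helpers. Everything inside the package is SI (m, s, Pa, Pa.s);
# user-facing constructors and the CLI accept the microscopy-friendly units
# (um, mm/s, ml/h, mPa.s) and convert at the boundary.

#' Unit conversions used at the package boundary
#'
#' @param x Numeric value(s) to convert.
#' @return Converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6
#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6
#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3
#' @rdname units
#' @export
ml_per_h_to_m3_per_s <- function(x) x * 1e-6 / 3600
#' @rdname units
#' @export
mPas_to_Pas <- function(x) x * 1e-3
deg_to_rad <- function(x) x * pi / 180
rad_to_deg <- function(x) x * 180 / pi

# Validation helper: every validation error names the offending field.
check_positive <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite number", field), call. = FALSE)
  }
  if (strict && any(x <= 0)) {
    stop(sprintf("'%s' must be > 0", field), call. = FALSE)
  }
  if (!strict && any(x < 0)) {
    stop(sprintf("'%s' must be >= 0", field), call. = FALSE)
  }
  invisible(x)
}
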