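#' Probe-liquid surface-tension table
#'
#' The three probe liquids used for Owens-Wendt surface-energy estimation
#' on PDMS, with their total surface tensions and the dispersive/polar
#' split the two-component model requires. Totals follow the standard
#' tabulations (water 72.8, nitromethane 36.8, hexadecane 26.35 mN/m); the
#' splits are documented literature defaults (hexadecane: an alkane, fully
#' dispersive; water: majority polar, 21.8 + 51.0; nitromethane: mixed,
#' 22.0 + 14.8). The table ships as data
#' (`inst/extdata/probe_liquids.csv`) and can be replaced wholesale.
#'
#' @param path Optional path to a CSV with columns
#'   `name,gamma_total,gamma_d,gamma_p` (mN/m) replacing the default table.
#' @return data.frame with columns `name`, `gamma_total`, `gamma_d`,
#'   `gamma_p`.
#' @export
probe_liquids <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "probe_liquids.csv", package = "wrinklekit")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "gamma_total", "gamma_d", "gamma_p")
  if (!all(need %in% names(tab))) {
    stop("liquid table must have columns name,gamma_total,gamma_d,gamma_p",
         call. = FALSE)
  }
  bad <- abs(tab$gamma_d + tab$gamma_p - tab$gamma_total) > 1e-6
  if (any(bad)) {
    stop(sprintf("gamma_d + gamma_p != gamma_total for: %s",
                 paste(tab$name[bad], collapse = ", ")), call. = FALSE)
  }
  if (any(tab$gamma_d < 0 | tab$gamma_p < 0)) {
    stop("surface-tension components must be >= 0", call. = FALSE)
  }
  tab
}

#' Owens-Wendt surface free energy fit
#'
#' Estimates the dispersive and polar components of a solid's surface free
#' energy from contact angles of probe liquids. The Owens-Wendt relation
#' linearizes to
#' \deqn{\frac{\gamma_L(1+\cos\theta)}{2\sqrt{\gamma_L^d}} =
#'   \sqrt{\gamma_S^p}\sqrt{\frac{\gamma_L^p}{\gamma_L^d}} +
#'   \sqrt{\gamma_S^d}}
#' so an ordinary least-squares line through the per-liquid points
#' `(x, y)` gives `gamma_S^p = slope^2` and `gamma_S^d = intercept^2`.
#' A negative fitted slope or intercept is unphysical (the square root of
#' a surface-energy component); the corresponding component is clamped to
#' 0 with a warning.
#'
#' @param angles data.frame with columns `liquid` (matching `name` in the
#'   liquid table) and `theta_deg` in `[0, 180]`.
#' @param liquids Liquid table as from [probe_liquids()].
#' @param dispersive_only If `TRUE`, fit only the dispersive component
#'   (intercept-only model); required when every probe liquid is purely
#'   dispersive, in which case the polar component is unidentifiable and
#'   the default fit refuses.
#' @return Object of class `owens_wendt` with `gamma_d`, `gamma_p`,
#'   `gamma_total` (mN/m), the underlying `lm` fit, and the regression
#'   points.
#' @export
owens_wendt_fit <- function(angles, liquids = probe_liquids(),
                            dispersive_only = FALSE) {
  stopifnot(is.data.frame(angles), all(c("liquid", "theta_deg") %in% names(angles)))
  if (any(angles$theta_deg < 0 | angles$theta_deg > 180)) {
    stop("'theta_deg' must lie in [0, 180]", call. = FALSE)
  }
  m <- match(angles$liquid, liquids$name)
  if (anyNA(m)) {
    stop(sprintf("unknown liquid(s): %s",
                 paste(angles$liquid[is.na(m)], collapse = ", ")), call. = FALSE)
  }
  liq <- liquids[m, ]
  if (any(liq$gamma_d <= 0)) {
    stop("every probe liquid needs gamma_d > 0", call. = FALSE)
  }
  theta <- deg_to_rad(angles$theta_deg)
  y <- liq$gamma_total * (1 + cos(theta)) / (2 * sqrt(liq$gamma_d))
  x <- sqrt(liq$gamma_p / liq$gamma_d)
  all_dispersive <- all(liq$gamma_p == 0)
  if (dispersive_only || all_dispersive) {
    if (!dispersive_only) {
      stop("polar component unidentifiable: all probe liquids are purely dispersive",
           call. = FALSE)
    }
    fit <- stats::lm(y ~ 1)
    intercept <- stats::coef(fit)[[1]]
    slope <- 0
  } else {
    if (nrow(angles) < 2L) stop("need at least 2 liquids", call. = FALSE)
    fit <- stats::lm(y ~ x)
    intercept <- stats::coef(fit)[[1]]
    slope <- stats::coef(fit)[[2]]
  }
  if (intercept < 0) {
    warning("negative fitted sqrt(gamma_S^d); dispersive component clamped to 0")
    intercept <- 0
  }
  if (slope < 0) {
    warning("negative fitted sqrt(gamma_S^p); polar component clamped to 0")
    slope <- 0
  }
  structure(list(gamma_d = intercept^2, gamma_p = slope^2,
                 gamma_total = intercept^2 + slope^2,
                 slope = slope, intercept = intercept, fit = fit,
                 points = data.frame(liquid = angles$liquid, x = x, y = y,
                                     theta_deg = angles$theta_deg)),
            class = "owens_wendt")
}

#' @export
print.owens_wendt <- function(x, ...) {
  cat("Owens-Wendt surface free energy\n")
  cat(sprintf("  gamma_S = %.2f mN/m (dispersive %.2f + polar %.2f)\n",
              x$gamma_total, x$gamma_d, x$gamma_p))
  cat(sprintf("  fit: intercept %.4f, slope %.4f, %d liquids\n",
              x$intercept, x$slope, nrow(x$points)))
  invisible(x)
}

#' @export
coef.owens_wendt <- function(object, ...) {
  c(gamma_d = object$gamma_d, gamma_p = object$gamma_p,
    gamma_total = object$gamma_total)
}

#' @export
plot.owens_wendt <- function(x, ...) {
  graphics::plot(x$points$x, x$points$y,
                 xlab = expression(sqrt(gamma[L]^p / gamma[L]^d)),
                 ylab = expression(gamma[L] * (1 + cos(theta)) / (2 * sqrt(gamma[L]^d))),
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope)
  graphics::text(x$points$x, x$points$y, x$points$liquid, pos = 3, cex = 0.8)
  invisible(x)
}

#' Forward Owens-Wendt contact-angle prediction
#'
#' Predicts the contact angle of a probe liquid on a solid with known
#' surface-energy components:
#' \deqn{\cos\theta = \frac{2\sqrt{\gamma_S^d\gamma_L^d} +
#'   2\sqrt{\gamma_S^p\gamma_L^p}}{\gamma_L} - 1}
#' An implied cosine above 1 is reported as complete wetting (theta = 0)
#' and below -1 as complete dewetting (theta = 180), each flagged.
#'
#' @param solid An `owens_wendt` object or a list/vector with `gamma_d`
#'   and `gamma_p` (mN/m).
#' @param liquids Liquid table rows to predict for (default: the shipped
#'   probe liquids).
#' @return data.frame with columns `liquid`, `theta_deg`, `flag`
#'   (`"ok"`, `"complete_wetting"` or `"dewetting"`).
#' @export
predict_contact_angle <- function(solid, liquids = probe_liquids()) {
  gd <- if (inherits(solid, "owens_wendt")) solid$gamma_d else solid[["gamma_d"]]
  gp <- if (inherits(solid, "owens_wendt")) solid$gamma_p else solid[["gamma_p"]]
  check_positive(gd, "gamma_d", strict = FALSE)
  check_positive(gp, "gamma_p", strict = FALSE)
  cth <- (2 * sqrt(gd * liquids$gamma_d) + 2 * sqrt(gp * liquids$gamma_p)) /
    liquids$gamma_total - 1
  flag <- ifelse(cth > 1, "complete_wetting", ifelse(cth < -1, "dewetting", "ok"))
  theta <- rad_to_deg(acos(pmin(pmax(cth, -1), 1)))
  data.frame(liquid = liquids$name, theta_deg = theta, flag = flag,
             stringsAsFactors = FALSE)
}

#' @export
predict.owens_wendt <- function(object, liquids = probe_liquids(), ...) {
  predict_contact_angle(object, liquids)
}
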