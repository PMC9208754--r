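#' Elastic description of an adherent biofilm layer
#'
#' Bundles the mechanical parameters of the biofilm treated as a thin,
#' isotropic elastic film adhering to a rigid substrate: Young's modulus
#' `E_f`, Poisson's ratio `nu_f` and film thickness `h`.
#'
#' Biofilm rheology papers usually report the shear-modulus magnitude
#' (~1 kPa for *P. aeruginosa*); following common practice in the
#' buckling-delamination literature this magnitude is plugged directly into
#' the formulas as `youngs_modulus` without a shear-to-Young conversion.
#'
#' @param youngs_modulus Young's modulus of the film, Pa. Must be > 0.
#' @param poisson_ratio Poisson's ratio, dimensionless, in `[0, 0.5)`.
#' @param thickness Film thickness in metres (use [um_thickness()] for
#'   micrometre input). Must be > 0.
#' @return An object of class `elastic_film`.
#' @examples
#' film <- elastic_film(youngs_modulus = 1000, poisson_ratio = 0.45,
#'                      thickness = 15e-6)
#' @export
elastic_film <- function(youngs_modulus, poisson_ratio, thickness) {
  check_positive(youngs_modulus, "youngs_modulus")
  if (!is.numeric(poisson_ratio) || !is.finite(poisson_ratio) ||
      poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop("'poisson_ratio' must lie in [0, 0.5)", call. = FALSE)
  }
  check_positive(thickness, "thickness")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 thickness = thickness),
            class = "elastic_film")
}

#' @rdname elastic_film
#' @param thickness_um Film thickness in micrometres.
#' @export
um_thickness <- function(thickness_um) um_to_m(thickness_um)

#' Circular delaminated blister
#'
#' A circular region of radius `R` where the film has lost adhesion to the
#' substrate; its radius sets the critical buckling stress.
#'
#' @param radius Blister radius in metres. Must be > 0.
#' @return An object of class `blister`.
#' @export
blister <- function(radius) {
  check_positive(radius, "radius")
  structure(list(radius = radius), class = "blister")
}

#' Uniform equi-biaxial compressive stress state
#'
#' @param compressive_stress Compressive stress in Pa, >= 0. Growth of the
#'   confined film generates this stress.
#' @return An object of class `stress_state`.
#' @export
stress_state <- function(compressive_stress) {
  check_positive(compressive_stress, "compressive_stress", strict = FALSE)
  structure(list(compressive_stress = compressive_stress),
            class = "stress_state")
}

#' Interface toughness of the film-substrate bond
#'
#' Resistance to interface-crack propagation, proportional to the adhesive
#' strength between biofilm and substrate. The mode-mix angle `psi` is kept
#' as descriptive metadata only: in this system the deformation mode stays
#' essentially constant, so no functional dependence on `psi` is modelled.
#'
#' @param toughness Interface toughness Gamma in J m^-2, >= 0.
#' @param mode_mix_angle Optional mode-mix angle in radians (metadata).
#' @return An object of class `interface_toughness`.
#' @export
interface_toughness <- function(toughness, mode_mix_angle = NULL) {
  check_positive(toughness, "toughness", strict = FALSE)
  structure(list(toughness = toughness, mode_mix_angle = mode_mix_angle),
            class = "interface_toughness")
}

#' Rectangular microchannel flow
#'
#' Describes pressure-driven flow of culture medium through the rectangular
#' microfluidic channel in which the biofilm grows.
#'
#' @param width Channel width in metres.
#' @param height Channel height in metres.
#' @param flow_rate Volumetric flow rate in m^3 s^-1
#'   (use [ml_per_h_flow()] for ml/h input). May be 0.
#' @param viscosity Dynamic viscosity in Pa s (default: water at room
#'   temperature, 1.0 mPa s).
#' @return An object of class `channel_flow`.
#' @examples
#' flow <- channel_flow(width = 500e-6, height = 100e-6,
#'                      flow_rate = ml_per_h_flow(0.3))
#' @export
channel_flow <- function(width, height, flow_rate, viscosity = 1e-3) {
  check_positive(width, "width")
  check_positive(height, "height")
  check_positive(flow_rate, "flow_rate", strict = FALSE)
  check_positive(viscosity, "viscosity")
  structure(list(width = width, height = height,
                 flow_rate = flow_rate, viscosity = viscosity),
            class = "channel_flow")
}

#' @rdname channel_flow
#' @param q_ml_per_h Flow rate in millilitres per hour.
#' @export
ml_per_h_flow <- function(q_ml_per_h) ml_per_h_to_m3_per_s(q_ml_per_h)

#' Critical buckling stress of a delaminated circular blister
#'
#' The compressive stress above which an adherent elastic film buckles away
#' from the substrate over a circular delaminated region of radius `R`:
#'
#' \deqn{\sigma_c = 1.2235 \, \frac{E_f}{1-\nu_f^2}\left(\frac{h}{R}\right)^2}
#'
#' The quadratic dependence on `h/R` means a smaller initial blister requires
#' a quadratically larger stress to buckle: shrinking `R` tenfold raises
#' the critical stress by a factor of 100, which is why strongly adhering
#' biofilms (blisters down to single-cell size) never buckle.
#'
#' @param film An [elastic_film()].
#' @param blister A [blister()].
#' @return Critical stress in Pa.
#' @examples
#' film <- elastic_film(1000, 0.45, um_thickness(15))
#' critical_stress(film, blister(um_to_m(10)))  # ~3.45 kPa
#' @export
critical_stress <- function(film, blister) {
  stopifnot(inherits(film, "elastic_film"), inherits(blister, "blister"))
  1.2235 * film$youngs_modulus / (1 - film$poisson_ratio^2) *
    (film$thickness / blister$radius)^2
}

#' Elastic energy per unit area stored in the unbuckled film
#'
#' \deqn{G_0 = (1-\nu_f)\, h\, \sigma^2 / E_f}
#'
#' This is the upper bound that the energy release rate of the interface
#' crack approaches at large overstress.
#'
#' @param film An [elastic_film()].
#' @param stress A [stress_state()].
#' @return Energy per unit area in J m^-2.
#' @export
baseline_energy_release <- function(film, stress) {
  stopifnot(inherits(film, "elastic_film"), inherits(stress, "stress_state"))
  (1 - film$poisson_ratio) * film$thickness *
    stress$compressive_stress^2 / film$youngs_modulus
}

#' Normalized energy release rate of the buckle-driven interface crack
#'
#' For stresses above the critical buckling stress the crack driving force,
#' normalized by the stored elastic energy \eqn{G_0}, is
#'
#' \deqn{G/G_0 = c^2\left[1-(\sigma_c/\sigma)^2\right], \quad
#'       c^2 = \left[1 + 0.9021(1-\nu_f)\right]^{-1}}
#'
#' Below the critical stress the film is unbuckled and the energy release
#' rate is exactly zero; this is reported as a state (`buckled = FALSE`,
#' ratio 0), not an error, so that sweeps over a growing stress history are
#' convenient.
#'
#' @param stress A [stress_state()] (or numeric stress in Pa); vectorized.
#' @param critical Critical buckling stress in Pa (> 0), e.g. from
#'   [critical_stress()].
#' @param poisson_ratio Poisson's ratio of the film.
#' @return A data.frame with columns `stress`, `ratio` (G/G0) and `buckled`.
#' @export
normalized_energy_release <- function(stress, critical, poisson_ratio) {
  sigma <- if (inherits(stress, "stress_state")) stress$compressive_stress else stress
  check_positive(sigma, "stress", strict = FALSE)
  check_positive(critical, "critical")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop("'poisson_ratio' must lie in [0, 0.5)", call. = FALSE)
  }
  c2 <- 1 / (1 + 0.9021 * (1 - poisson_ratio))
  buckled <- sigma >= critical
  ratio <- ifelse(buckled, c2 * (1 - (critical / sigma)^2), 0)
  data.frame(stress = sigma, ratio = ratio, buckled = buckled)
}

#' Does the delamination crack grow or arrest?
#'
#' The interface crack advances only while the driving force G exceeds the
#' interface toughness Gamma; at G = Gamma (and below) the crack is
#' arrested. Raising the substrate surface free energy raises Gamma and is
#' the experimental handle that suppresses channel formation.
#'
#' @param g Energy release rate G in J m^-2, >= 0.
#' @param toughness An [interface_toughness()] (or numeric Gamma in J m^-2).
#' @return `"grows"` or `"arrested"`.
#' @export
delamination_verdict <- function(g, toughness) {
  gamma <- if (inherits(toughness, "interface_toughness")) toughness$toughness else toughness
  check_positive(g, "g", strict = FALSE)
  check_positive(gamma, "toughness", strict = FALSE)
  ifelse(g > gamma, "grows", "arrested")
}

#' Smallest blister radius that buckles at a given stress
#'
#' Inverts the critical-stress relation: returns the radius `R` at which the
#' critical buckling stress equals the supplied compressive stress. Any
#' larger blister has a lower critical stress and therefore buckles.
#'
#' @param film An [elastic_film()].
#' @param stress A [stress_state()] with stress > 0. A zero stress has no
#'   finite buckling radius and returns `Inf`.
#' @return Radius in metres (`Inf` when stress is 0).
#' @export
min_buckling_radius <- function(film, stress) {
  stopifnot(inherits(film, "elastic_film"), inherits(stress, "stress_state"))
  sigma <- stress$compressive_stress
  if (sigma == 0) return(Inf)
  film$thickness * sqrt(1.2235 * film$youngs_modulus /
                          ((1 - film$poisson_ratio^2) * sigma))
}

#' Mean flow velocity in the channel
#'
#' Volumetric flow rate divided by the rectangular cross-section.
#'
#' @param flow A [channel_flow()].
#' @return Mean velocity in m s^-1.
#' @examples
#' mean_velocity(channel_flow(500e-6, 100e-6, ml_per_h_flow(0.3)))  # ~1.7 mm/s
#' @export
mean_velocity <- function(flow) {
  stopifnot(inherits(flow, "channel_flow"))
  area <- flow$width * flow$height
  if (area <= 0) stop("'width' and 'height' must give a positive area", call. = FALSE)
  flow$flow_rate / area
}

#' Average wall shear stress in the channel
#'
#' Uses the laminar infinite-parallel-plate profile,
#' \eqn{\tau_w = 6 \mu U / h}, appropriate for the 5:1 width-to-height
#' aspect ratio of the device; the exact rectangular-duct series solution is
#' deliberately not used.
#'
#' @param flow A [channel_flow()].
#' @return Wall shear stress in Pa.
#' @export
wall_shear_stress <- function(flow) {
  6 * flow$viscosity * mean_velocity(flow) / flow$height
}

#' Full mechanics report for one configuration
#'
#' Convenience wrapper evaluating the buckling-delamination model and the
#' channel hydrodynamics in one call; this is what the `mechanics` CLI
#' subcommand prints.
#'
#' @param film An [elastic_film()].
#' @param blister A [blister()].
#' @param stress A [stress_state()]; defaults to the critical stress so
#'   that `g_ratio` is 0.
#' @param toughness Optional [interface_toughness()] for the verdict.
#' @param flow Optional [channel_flow()].
#' @return A one-row data.frame with columns `sigma_c_Pa`, `G0_J_m2`,
#'   `g_ratio`, `buckled`, `verdict`, `U_mm_s`, `tau_wall_Pa`.
#' @export
mechanics_report <- function(film, blister, stress = NULL, toughness = NULL,
                             flow = NULL) {
  sc <- critical_stress(film, blister)
  if (is.null(stress)) stress <- stress_state(sc)
  g0 <- baseline_energy_release(film, stress)
  nr <- normalized_energy_release(stress, sc, film$poisson_ratio)
  g <- nr$ratio * g0
  verdict <- if (is.null(toughness)) NA_character_ else delamination_verdict(g, toughness)
  u <- if (is.null(flow)) NA_real_ else mean_velocity(flow)
  tau <- if (is.null(flow)) NA_real_ else wall_shear_stress(flow)
  data.frame(sigma_c_Pa = sc, G0_J_m2 = g0, g_ratio = nr$ratio,
             buckled = nr$buckled, verdict = verdict,
             U_mm_s = m_to_mm(u), tau_wall_Pa = tau)
}
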