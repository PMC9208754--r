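# Seeded synthetic-data generators. Every generator uses only forward
# models (particle kinematics, ribbon geometry, the Owens-Wendt relation)
# and emits machine-readable ground truth beside the data, so the analysis
# modules can be validated without raw microscopy. None of them call into
# the analysis code.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Schulz speed distribution
#'
#' The Schulz (generalized exponential) distribution used for swimming-speed
#' polydispersity: a gamma distribution with shape `Z + 1` and mean
#' `mean_speed`, so the speed standard deviation is
#' `mean_speed / sqrt(Z + 1)`.
#'
#' @param n Number of draws.
#' @param mean_speed Mean speed (um/s).
#' @param shape Schulz shape parameter Z (> 0).
#' @return `rschulz`: `n` random speeds. `dschulz`/`pschulz`: density /
#'   distribution function at `x`.
#' @export
rschulz <- function(n, mean_speed, shape) {
  stats::rgamma(n, shape = shape + 1, rate = (shape + 1) / mean_speed)
}

#' @rdname rschulz
#' @param x Quantiles.
#' @export
dschulz <- function(x, mean_speed, shape) {
  stats::dgamma(x, shape = shape + 1, rate = (shape + 1) / mean_speed)
}

#' @rdname rschulz
#' @export
pschulz <- function(x, mean_speed, shape) {
  stats::pgamma(x, shape = shape + 1, rate = (shape + 1) / mean_speed)
}

# Accumulate Gaussian spots (periodic boundaries) onto a frame vector.
# pr/pc are fractional pixel positions; returns a numeric nr*nc vector.
render_spots <- function(nr, nc, pr, pc, amplitude, sigma_px) {
  out <- numeric(nr * nc)
  np <- length(pr)
  if (np == 0L) return(out)
  rad <- ceiling(3 * sigma_px)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  no <- nrow(off)
  base_r <- floor(pr); base_c <- floor(pc)
  R <- rep(off$dr, times = np) + rep(base_r, each = no)
  C <- rep(off$dc, times = np) + rep(base_c, each = no)
  w <- amplitude * exp(-((R - rep(pr, each = no))^2 +
                           (C - rep(pc, each = no))^2) / (2 * sigma_px^2))
  Rw <- ((R - 1) %% nr) + 1
  Cw <- ((C - 1) %% nc) + 1
  idx <- Rw + (Cw - 1) * nr
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# Camera model: shot noise (Poisson at `photons` full-scale counts) plus
# additive Gaussian read noise.
camera_noise <- function(img, photons, read_sd) {
  v <- as.vector(img)
  if (is.finite(photons) && photons > 0) {
    v <- stats::rpois(length(v), lambda = pmax(v, 0) * photons) / photons
  }
  if (read_sd > 0) v <- v + stats::rnorm(length(v), 0, read_sd)
  matrix(pmin(pmax(v, 0), 1), nrow(img), ncol(img))
}

#' Synthetic high-speed movie of swimmers and diffusers
#'
#' Generates a brightfield-like movie of point particles rendered as
#' Gaussian spots on a uniform background with Poisson shot noise and
#' Gaussian read noise, with periodic boundaries. A fraction
#' `motile_fraction` of the particles moves ballistically with
#' Schulz-distributed speeds and uniform random directions; the rest
#' diffuse with diffusivity `diffusivity_um2_s`; swimmers carry the same
#' thermal diffusion on top of their ballistic motion, matching the
#' intermediate-scattering-function model fitted by the DDM module.
#'
#' When `active_rect` is given, the swimmer/diffuser population is
#' confined to that rectangle (wrapping inside it) and the remainder of
#' the field is filled, at matched number density, with tracer particles
#' advected uniformly at `external_flow_um_s` along +x — emulating a
#' closed channel populated by motile bacteria and surrounded by external
#' nutrient flow that does not penetrate it.
#'
#' Defaults are a desk-scale stand-in for high-speed acquisition of
#' swimming bacteria: 256 x 256 px at 0.33 um/px, 2000 frames at 2000 fps,
#' mean speed 25 um/s with Schulz shape 2, diffusivity 0.4 um^2/s,
#' motile fraction 0.7.
#'
#' @param n_particles Particles inside the field (or inside `active_rect`).
#' @param mean_speed_um_s,schulz_shape Swimmer speed distribution.
#' @param diffusivity_um2_s Diffuser diffusivity.
#' @param motile_fraction Fraction of particles that swim.
#' @param frames,fps,pixel_size_um,dim Acquisition geometry.
#' @param spot_sigma_um,spot_amplitude,background Rendering model.
#' @param active_rect Optional `c(r0, r1, c0, c1)` pixel rectangle.
#' @param external_flow_um_s Advection speed outside `active_rect`.
#' @param photons Full-scale photon count of the shot-noise model
#'   (`Inf` disables shot noise).
#' @param read_noise_sd Gaussian read-noise sd (intensity units).
#' @param seed RNG seed; the generator is seed-deterministic.
#' @return List with `stack` (an [image_stack()], 16-bit grid) and
#'   `truth` (all parameters, the sampled swimmer speeds, and the active
#'   mask).
#' @export
generate_swimmer_movie <- function(n_particles = 300,
                                   mean_speed_um_s = 25,
                                   schulz_shape = 2,
                                   diffusivity_um2_s = 0.4,
                                   motile_fraction = 0.7,
                                   frames = 2000, fps = 2000,
                                   pixel_size_um = 0.33,
                                   dim = c(256, 256),
                                   spot_sigma_um = 0.5,
                                   spot_amplitude = 0.25,
                                   background = 0.4,
                                   active_rect = NULL,
                                   external_flow_um_s = 0,
                                   photons = 300, read_noise_sd = 0.005,
                                   seed = 1) {
  nr <- dim[1]; nc <- dim[2]
  dt <- 1 / fps
  if (mean_speed_um_s / fps / pixel_size_um > min(nr, nc)) {
    stop("undersampled dynamics: mean displacement per frame exceeds the field",
         call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(active_rect)) {
      rect <- c(1, nr, 1, nc)
      n_out <- 0L
    } else {
      rect <- active_rect
      area_in <- (rect[2] - rect[1] + 1) * (rect[4] - rect[3] + 1)
      n_out <- round(n_particles * (nr * nc - area_in) / area_in)
    }
    hr <- rect[2] - rect[1] + 1; hc <- rect[4] - rect[3] + 1
    n_sw <- round(motile_fraction * n_particles)
    n_df <- n_particles - n_sw
    # swimmers: ballistic, Schulz speeds, directions uniform on the 3-D
    # sphere; the camera records the in-plane projection (the 3-D isotropic
    # orientation average is what gives the sinc kernel inside the ISF)
    sp <- rschulz(n_sw, mean_speed_um_s, schulz_shape)
    phi <- stats::runif(n_sw, 0, 2 * pi)
    cth <- stats::runif(n_sw, -1, 1)
    sth <- sqrt(1 - cth^2)
    vr <- sp * sth * sin(phi) / fps / pixel_size_um   # px per frame
    vc <- sp * sth * cos(phi) / fps / pixel_size_um
    t_idx <- 0:(frames - 1)
    Rs <- outer(t_idx, vr) + rep(stats::runif(n_sw, 0, hr), each = frames)
    Cs <- outer(t_idx, vc) + rep(stats::runif(n_sw, 0, hc), each = frames)
    # diffusers: Gaussian steps, sd sqrt(2 D dt) per axis
    sd_px <- sqrt(2 * diffusivity_um2_s * dt) / pixel_size_um
    rw <- function(n) {
      if (n == 0L) return(matrix(0, frames, 0))
      apply(matrix(stats::rnorm((frames - 1) * n, 0, sd_px), frames - 1, n),
            2, cumsum)
    }
    Rd <- rbind(0, rw(n_df)) + rep(stats::runif(n_df, 0, hr), each = frames)
    Cd <- rbind(0, rw(n_df)) + rep(stats::runif(n_df, 0, hc), each = frames)
    # swimmers share the thermal diffusion (the ISF model multiplies both
    # populations by the same diffusive factor)
    if (n_sw > 0L) {
      Rs <- Rs + rbind(0, rw(n_sw))
      Cs <- Cs + rbind(0, rw(n_sw))
    }
    R_in <- (cbind(Rs, Rd) %% hr) + rect[1]
    C_in <- (cbind(Cs, Cd) %% hc) + rect[3]
    # external tracers: uniform advection along +x (columns), full-frame wrap
    if (n_out > 0L) {
      u_px <- external_flow_um_s / fps / pixel_size_um
      # rejection-sample initial positions outside the rectangle
      ro <- stats::runif(3 * n_out, 0, nr); co <- stats::runif(3 * n_out, 0, nc)
      outside <- !(ro >= rect[1] & ro <= rect[2] & co >= rect[3] & co <= rect[4])
      ro <- ro[outside][seq_len(n_out)]; co <- co[outside][seq_len(n_out)]
      Ro <- matrix(ro, frames, n_out, byrow = TRUE)
      Co <- (outer(t_idx, rep(u_px, n_out)) + rep(co, each = frames))
    } else {
      Ro <- matrix(0, frames, 0); Co <- matrix(0, frames, 0)
    }
    sigma_px <- spot_sigma_um / pixel_size_um
    mask <- matrix(FALSE, nr, nc)
    mask[rect[1]:rect[2], rect[3]:rect[4]] <- TRUE
    out_frames <- vector("list", frames)
    for (t in seq_len(frames)) {
      pr <- c(R_in[t, ], ((Ro[t, ] - 1) %% nr) + 1)
      pc <- c(C_in[t, ], ((Co[t, ] - 1) %% nc) + 1)
      img <- matrix(background + render_spots(nr, nc, pr, pc,
                                              spot_amplitude, sigma_px),
                    nr, nc)
      out_frames[[t]] <- camera_noise(img, photons, read_noise_sd)
    }
    stack <- quantize_stack(image_stack(out_frames,
                                        pixel_size_um = pixel_size_um,
                                        frame_interval_s = dt,
                                        bit_depth = 16L))
    list(stack = stack,
         truth = list(mean_speed_um_s = mean_speed_um_s,
                      schulz_shape = schulz_shape,
                      diffusivity_um2_s = diffusivity_um2_s,
                      motile_fraction = motile_fraction,
                      n_particles = n_particles,
                      speeds = sp,
                      active_rect = rect, active_mask = mask,
                      external_flow_um_s = external_flow_um_s,
                      seed = seed))
  })
}

#' Synthetic movie with spatially segregated activity
#'
#' Emulates a biofilm field of view in which motile bacteria are confined
#' to a channel region while the surrounding biofilm is static: swimmers
#' (rendered as Gaussian spots) move inside `active_rect`; outside it a
#' fixed random spot texture provides static contrast. From `switch_frame`
#' onward the swimmers freeze in place, emulating the loss of motility in
#' a maturing biofilm — the previously active region then reads as static.
#'
#' @param dim Frame size in px.
#' @param active_rect `c(r0, r1, c0, c1)` rectangle holding the swimmers.
#' @param frames,fps,pixel_size_um Acquisition geometry (defaults: 20 fps
#'   desk-scale stand-in for high-speed acquisition).
#' @param n_swimmers Swimmers inside the rectangle.
#' @param mean_speed_um_s,schulz_shape Swimmer speeds.
#' @param texture_density Static spots per pixel outside the rectangle
#'   (dense enough that every ROI carries texture contrast).
#' @param switch_frame Frame after which swimmers freeze (`Inf`: never).
#' @param spot_sigma_um,spot_amplitude,background,photons,read_noise_sd
#'   Rendering and camera model (see [generate_swimmer_movie()]).
#' @param seed RNG seed.
#' @return List with `stack` and `truth` (active mask, switch frame,
#'   parameters).
#' @export
generate_activity_movie <- function(dim = c(192, 192),
                                    active_rect = c(1, 192, 1, 96),
                                    frames = 240, fps = 20,
                                    pixel_size_um = 0.5,
                                    n_swimmers = 800,
                                    mean_speed_um_s = 25,
                                    schulz_shape = 2,
                                    texture_density = 0.08,
                                    switch_frame = Inf,
                                    spot_sigma_um = 0.6,
                                    spot_amplitude = 0.3,
                                    background = 0.4,
                                    photons = 1000, read_noise_sd = 0.004,
                                    seed = 1) {
  nr <- dim[1]; nc <- dim[2]
  rect <- active_rect
  hr <- rect[2] - rect[1] + 1; hc <- rect[4] - rect[3] + 1
  dt <- 1 / fps
  with_seed(seed, {
    sp <- rschulz(n_swimmers, mean_speed_um_s, schulz_shape)
    phi <- stats::runif(n_swimmers, 0, 2 * pi)
    vr <- sp * sin(phi) / fps / pixel_size_um
    vc <- sp * cos(phi) / fps / pixel_size_um
    t_idx <- 0:(frames - 1)
    t_eff <- pmin(t_idx, switch_frame - 1)       # freeze after the switch
    Rs <- outer(t_eff, vr) + rep(stats::runif(n_swimmers, 0, hr), each = frames)
    Cs <- outer(t_eff, vc) + rep(stats::runif(n_swimmers, 0, hc), each = frames)
    Rs <- (Rs %% hr) + rect[1]
    Cs <- (Cs %% hc) + rect[3]
    # static texture outside the active rectangle
    n_tex <- round(texture_density * (nr * nc - hr * hc))
    ro <- stats::runif(4 * n_tex, 0, nr); co <- stats::runif(4 * n_tex, 0, nc)
    outside <- !(ro >= rect[1] & ro <= rect[2] & co >= rect[3] & co <= rect[4])
    ro <- ro[outside][seq_len(n_tex)]; co <- co[outside][seq_len(n_tex)]
    sigma_px <- spot_sigma_um / pixel_size_um
    tex <- matrix(render_spots(nr, nc, ro, co, spot_amplitude, sigma_px), nr, nc)
    mask <- matrix(FALSE, nr, nc)
    mask[rect[1]:rect[2], rect[3]:rect[4]] <- TRUE
    out_frames <- vector("list", frames)
    for (t in seq_len(frames)) {
      img <- background + tex +
        matrix(render_spots(nr, nc, Rs[t, ], Cs[t, ], spot_amplitude, sigma_px),
               nr, nc)
      out_frames[[t]] <- camera_noise(img, photons, read_noise_sd)
    }
    stack <- quantize_stack(image_stack(out_frames,
                                        pixel_size_um = pixel_size_um,
                                        frame_interval_s = dt,
                                        bit_depth = 16L))
    list(stack = stack,
         truth = list(active_rect = rect, active_mask = mask,
                      switch_frame = switch_frame,
                      mean_speed_um_s = mean_speed_um_s,
                      n_swimmers = n_swimmers, seed = seed))
  })
}

# Disk-stamp a polyline (dense points, px units) with radius r; returns
# unique linear pixel indices.
stamp_polyline <- function(pts_r, pts_c, radius, nr, nc) {
  rad <- ceiling(radius)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  no <- nrow(off)
  np <- length(pts_r)
  R <- rep(off$dr, times = np) + rep(round(pts_r), each = no)
  C <- rep(off$dc, times = np) + rep(round(pts_c), each = no)
  ok <- R >= 1 & R <= nr & C >= 1 & C <= nc
  unique(R[ok] + (C[ok] - 1) * nr)
}

#' Synthetic wrinkle-network timelapse with ground truth
#'
#' Emulates a phase-contrast timelapse of biofilm wrinkling: dark
#' curvilinear ribbons nucleate on a bright noisy background, elongate
#' along random-walk centrelines, widen, and merge into a connected
#' network. Nucleation happens during the first `nucleation_frac` of the
#' movie; each wrinkle then elongates at a constant tip speed until it
#' reaches its final length, after which the pattern is a steady state —
#' the three stages of wrinkle development. Initial wrinkle diameters are
#' drawn from 10-30 um and final ribbon widths from 20-30 um.
#'
#' Ground truth is computed from the generator's own geometry: per frame,
#' wrinkles whose ribbons touch (8-connectivity) are clustered by
#' union-find, giving the true number of isolated wrinkles `N_true` and
#' the total centreline length of the largest connected cluster `L_true`
#' (in mm). No analysis-module code is involved.
#'
#' @param n_wrinkles Number of wrinkles nucleated.
#' @param dim Frame size, px.
#' @param pixel_size_um Pixel size (default 2 um/px).
#' @param frames Number of frames.
#' @param frame_interval_s Frame interval (default 300 s = 5 min).
#' @param nucleation_frac Fraction of the movie over which nucleation
#'   extends.
#' @param growth_um_per_frame Tip elongation speed, um per frame.
#' @param length_range_um Final centreline length range (uniform draw).
#' @param snr Contrast-to-noise ratio: (background - ribbon) intensity
#'   over the Gaussian noise sd. Must give ribbon widths >= 3 px.
#' @param pure_merger If `TRUE`, all wrinkles nucleate in frame 1 and the
#'   dynamics are growth/merging only (so the largest-cluster length never
#'   decreases).
#' @param return_masks If `TRUE`, include the per-frame true foreground
#'   masks in the truth.
#' @param seed RNG seed.
#' @return List with `stack` (8-bit [image_stack()]) and `truth`:
#'   data.frame `per_frame` (`frame`, `N_true`, `L_true_mm`), stage
#'   boundary frames, per-wrinkle geometry, and optionally `masks`.
#' @export
generate_wrinkle_timelapse <- function(n_wrinkles = 30,
                                       dim = c(256, 256),
                                       pixel_size_um = 3,
                                       frames = 64,
                                       frame_interval_s = 300,
                                       nucleation_frac = 0.45,
                                       growth_um_per_frame = 36,
                                       length_range_um = c(150, 400),
                                       snr = 10,
                                       pure_merger = FALSE,
                                       return_masks = FALSE,
                                       seed = 1) {
  nr <- dim[1]; nc <- dim[2]
  if (10 / pixel_size_um < 3) {
    stop("ribbon width < 3 px: skeleton fidelity is not guaranteed; increase pixel resolution",
         call. = FALSE)
  }
  n1 <- max(1L, round(nucleation_frac * frames))
  bg <- 0.8; fg <- 0.25
  noise_sd <- (bg - fg) / snr
  with_seed(seed, {
    # Latent planar network: wrinkles are the edges of a random geometric
    # graph and merge at its vertices. Junction angles are kept >= 35 deg
    # and non-incident edges well separated, so every merge is transversal
    # and the network's centreline length is the sum of edge centrelines
    # (up to pixel-level dedup at junctions) -- an exactly computable truth.
    margin <- 14
    min_sep <- 45                                   # node separation, px
    nodes <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(nodes) < 60L && tries < 3000L) {
      tries <- tries + 1L
      p <- c(stats::runif(1, margin, nr - margin),
             stats::runif(1, margin, nc - margin))
      if (nrow(nodes) == 0L ||
          min(sqrt((nodes[, 1] - p[1])^2 + (nodes[, 2] - p[2])^2)) >= min_sep) {
        nodes <- rbind(nodes, p)
      }
    }
    lmin <- length_range_um[1] / pixel_size_um
    lmax <- length_range_um[2] / pixel_size_um
    nn <- nrow(nodes)
    cand <- which(upper.tri(matrix(TRUE, nn, nn)), arr.ind = TRUE)
    dists <- sqrt((nodes[cand[, 1], 1] - nodes[cand[, 2], 1])^2 +
                    (nodes[cand[, 1], 2] - nodes[cand[, 2], 2])^2)
    keep <- dists >= lmin & dists <= lmax
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    seg_angle <- function(u, v) {            # acute angle between directions
      a <- abs(atan2(u[1], u[2]) - atan2(v[1], v[2])) %% pi
      min(a, pi - a)
    }
    seg_min_dist <- function(a1, a2, b1, b2) {
      pts <- function(p1, p2) {
        tt <- seq(0, 1, length.out = 24)
        cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2]))
      }
      A <- pts(a1, a2); B <- pts(b1, b2)
      min(sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2))
    }
    min_angle <- 35 * pi / 180
    sel <- matrix(integer(0), 0, 2)
    for (e in seq_len(nrow(cand))) {
      if (nrow(sel) >= n_wrinkles) break
      i <- cand[e, 1]; j <- cand[e, 2]
      d_new <- nodes[j, ] - nodes[i, ]
      ok <- TRUE
      for (s in seq_len(nrow(sel))) {
        a <- sel[s, 1]; b <- sel[s, 2]
        d_old <- nodes[b, ] - nodes[a, ]
        shared <- length(intersect(c(i, j), c(a, b))) > 0L
        if (shared) {
          if (seg_angle(d_new, d_old) < min_angle) { ok <- FALSE; break }
        } else {
          dmin <- seg_min_dist(nodes[i, ], nodes[j, ], nodes[a, ], nodes[b, ])
          if (dmin < 14) {
            # non-incident edges may only meet in a proper, steep crossing
            if (dmin > 1e-9 || seg_angle(d_new, d_old) < min_angle) {
              ok <- FALSE; break
            }
          }
        }
      }
      if (ok) sel <- rbind(sel, c(i, j))
    }
    K <- nrow(sel)
    if (K < 3L) stop("network construction failed; enlarge the field", call. = FALSE)
    t_nuc <- if (pure_merger) rep(1L, K) else sort(sample.int(n1, K, replace = TRUE))
    d0_px <- stats::runif(K, 10, 30) / pixel_size_um        # initial diameter
    wf_px <- pmax(stats::runif(K, 20, 30) / pixel_size_um, d0_px)
    if (any(d0_px < 3)) stop("ribbon width < 3 px: increase pixel resolution",
                             call. = FALSE)
    g_px <- growth_um_per_frame / pixel_size_um
    # straight edge centrelines sampled at 1 px spacing, plus short
    # extensions beyond each endpoint: once a junction vertex has been
    # reached by two or more arms, their ribbons overshoot it by ~w/2 so
    # arms cross the vertex transversally (as merged wrinkles do) instead
    # of tip-meeting there; the truth always counts the nominal edge only
    paths <- vector("list", K)
    ext_lo <- ext_hi <- vector("list", K)
    len_px <- integer(K)
    s0 <- numeric(K)                                        # nucleation site
    emax <- ceiling(wf_px / 2) + 2L
    for (i in seq_len(K)) {
      p1 <- nodes[sel[i, 1], ]; p2 <- nodes[sel[i, 2], ]
      len <- sqrt(sum((p2 - p1)^2))
      tt <- seq(0, 1, length.out = max(2L, ceiling(len)))
      paths[[i]] <- cbind(p1[1] + tt * (p2[1] - p1[1]),
                          p1[2] + tt * (p2[2] - p1[2]))
      len_px[i] <- nrow(paths[[i]])
      s0[i] <- stats::runif(1, 0.3, 0.7)
      d <- (p2 - p1) / len
      ee <- seq_len(emax[i])
      ext_lo[[i]] <- cbind(p1[1] - ee * d[1], p1[2] - ee * d[2])
      ext_hi[[i]] <- cbind(p2[1] + ee * d[1], p2[2] + ee * d[2])
    }
    n2 <- max(t_nuc + ceiling(pmax(s0, 1 - s0) * len_px / g_px))
    nbr_off <- c(-1, 0, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
    per_frame <- data.frame(frame = seq_len(frames),
                            N_true = 0L, L_true_mm = 0)
    masks <- if (return_masks) vector("list", frames) else NULL
    out_frames <- vector("list", frames)
    prev_geom <- NULL
    for (t in seq_len(frames)) {
      active <- which(t_nuc <= t)
      if (t <= n2 || is.null(prev_geom)) {
        rib <- cent <- vector("list", K)
        cheb <- numeric(K)
        span <- matrix(0L, K, 2L)
        for (i in active) {
          age <- t - t_nuc[i]
          mid <- s0[i] * len_px[i]
          lo <- max(1L, ceiling(mid - g_px * age))
          hi <- min(len_px[i], floor(mid + g_px * age))
          if (hi < lo) { lo <- hi <- max(1L, min(len_px[i], round(mid))) }
          span[i, ] <- c(lo, hi)
        }
        arrivals <- integer(nrow(nodes))
        for (i in active) {
          if (span[i, 1] == 1L) {
            v <- sel[i, 1]; arrivals[v] <- arrivals[v] + 1L
          }
          if (span[i, 2] == len_px[i]) {
            v <- sel[i, 2]; arrivals[v] <- arrivals[v] + 1L
          }
        }
        for (i in active) {
          lo <- span[i, 1]; hi <- span[i, 2]
          f <- (hi - lo + 1) / len_px[i]
          w <- d0_px[i] + (wf_px[i] - d0_px[i]) * f
          p <- paths[[i]][lo:hi, , drop = FALSE]
          e <- min(emax[i], round(w / 2) + 1L)
          if (lo == 1L && arrivals[sel[i, 1]] >= 2L) {
            p <- rbind(ext_lo[[i]][seq_len(e), , drop = FALSE], p)
          }
          if (hi == len_px[i] && arrivals[sel[i, 2]] >= 2L) {
            p <- rbind(p, ext_hi[[i]][seq_len(e), , drop = FALSE])
          }
          rib[[i]] <- stamp_polyline(p[, 1], p[, 2], w / 2, nr, nc)
          pn <- paths[[i]][lo:hi, , drop = FALSE]
          cent[[i]] <- unique(round(pn[, 1]) + (round(pn[, 2]) - 1) * nr)
          # centreline length in digital (Chebyshev) units: the pixel count
          # of an ideal 8-connected rasterization of the centreline
          cheb[i] <- if (nrow(pn) > 1L) {
            sum(pmax(abs(diff(pn[, 1])), abs(diff(pn[, 2])))) + 1
          } else 1
        }
        # union-find over ribbons that touch (8-connectivity of the union)
        parent <- seq_len(K)
        findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        if (length(active) > 1L) {
          bbox <- lapply(active, function(i) {
            r <- ((rib[[i]] - 1) %% nr) + 1; c <- ((rib[[i]] - 1) %/% nr) + 1
            c(min(r), max(r), min(c), max(c))
          })
          for (a in seq_along(active)) {
            i <- active[a]
            dil <- NULL
            for (b in seq_len(a - 1L)) {
              j <- active[b]
              bi <- bbox[[a]]; bj <- bbox[[b]]
              if (bi[1] > bj[2] + 2 || bj[1] > bi[2] + 2 ||
                  bi[3] > bj[4] + 2 || bj[3] > bi[4] + 2) next
              if (is.null(dil)) dil <- unique(as.vector(outer(rib[[i]], nbr_off, "+")))
              if (any(rib[[j]] %in% dil)) {
                ri <- findp(i); rj <- findp(j)
                if (ri != rj) parent[ri] <- rj
              }
            }
          }
        }
        roots <- vapply(active, findp, integer(1))
        geom <- list(rib = rib, cent = cent, cheb = cheb, roots = roots,
                     active = active)
        prev_geom <- geom
      } else {
        geom <- prev_geom
      }
      # truth metrics
      if (length(geom$active) > 0L) {
        clusters <- split(geom$active, geom$roots)
        per_frame$N_true[t] <- length(clusters)
        # cluster centreline length = sum of member Chebyshev lengths,
        # deduplicated where rounded centrelines share pixels
        clen <- vapply(clusters, function(ids) {
          overlap <- sum(lengths(geom$cent[ids])) -
            length(unique(unlist(geom$cent[ids])))
          sum(geom$cheb[ids]) - overlap
        }, numeric(1))
        per_frame$L_true_mm[t] <- max(clen) * pixel_size_um / 1000
      }
      # render
      img <- matrix(bg, nr, nc)
      all_idx <- unique(unlist(geom$rib[geom$active]))
      if (length(all_idx) > 0L) img[all_idx] <- fg
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      out_frames[[t]] <- pmin(pmax(img, 0), 1)
      if (return_masks) {
        m <- matrix(FALSE, nr, nc); m[all_idx] <- TRUE
        masks[[t]] <- m
      }
    }
    stack <- quantize_stack(image_stack(out_frames,
                                        pixel_size_um = pixel_size_um,
                                        frame_interval_s = frame_interval_s,
                                        bit_depth = 8L))
    truth <- list(per_frame = per_frame,
                  stage1_end_frame = n1, stage2_end_frame = n2,
                  t_nucleation = t_nuc,
                  final_width_px = wf_px, final_length_px = len_px,
                  seed = seed)
    if (return_masks) truth$masks <- masks
    list(stack = stack, truth = truth)
  })
}

#' Synthetic wrinkle-metric time series with known stage boundaries
#'
#' Builds an N(t)/L(t) series directly at the metrics level, with the
#' three-stage phenomenology and stage durations given in hours: N rises
#' to a peak during stage 1 (while L stays below ~0.65 mm), falls during
#' stage 2 as wrinkles merge while L rises steeply to its final value
#' (~8 mm), and both plateau in stage 3. Defaults follow the observed
#' stage durations (6.5 h nucleation, 3.5 h merging) at a 5-minute frame
#' interval. Used to validate stage segmentation against exactly known
#' boundaries without running the image pipeline.
#'
#' @param stage_durations_h Durations of stages 1 and 2, hours.
#' @param steady_h Duration of the steady state recorded after stage 2.
#' @param frame_interval_min Frame interval, minutes.
#' @param N_peak,N_final Wrinkle count at the stage-1 peak / steady state.
#' @param L_stage1_mm,L_final_mm Longest-wrinkle length at the end of
#'   stage 1 and at steady state.
#' @param noise Relative jitter applied to N (default 0.02).
#' @param seed RNG seed.
#' @return List with `metrics` (a `wrinkle_metrics` data.frame) and
#'   `truth` (`stage1_end_frame`, `stage2_end_frame`).
#' @export
simulate_wrinkle_metrics <- function(stage_durations_h = c(6.5, 3.5),
                                     steady_h = 5,
                                     frame_interval_min = 5,
                                     N_peak = 120, N_final = 8,
                                     L_stage1_mm = 0.5, L_final_mm = 8,
                                     noise = 0.02, seed = 1) {
  fpm <- 60 / frame_interval_min
  n1 <- round(stage_durations_h[1] * fpm)
  n2 <- round(stage_durations_h[2] * fpm)
  n3 <- round(steady_h * fpm)
  nf <- n1 + n2 + n3
  with_seed(seed, {
    N <- numeric(nf)
    N[1:n1] <- 1 + (N_peak - 1) * (seq_len(n1) / n1)^1.5
    N[(n1 + 1):(n1 + n2)] <- N_final + (N_peak - N_final) *
      (1 - seq_len(n2) / n2)^1.2
    N[(n1 + n2 + 1):nf] <- N_final
    jitter <- stats::rnorm(nf, 0, noise * N_peak)
    N <- round(pmax(N + jitter, 1))
    N[n1] <- max(N) + 2L                      # the true peak stays the argmax
    u <- seq_len(n2) / n2
    L <- c(L_stage1_mm * (seq_len(n1) / n1),
           L_stage1_mm + (L_final_mm - L_stage1_mm) * (0.95 * u^3 + 0.05 * u^6),
           rep(L_final_mm, n3))
    out <- data.frame(frame = seq_len(nf),
                      time_s = (seq_len(nf) - 1) * frame_interval_min * 60,
                      N = as.integer(N), L_mm = L)
    class(out) <- c("wrinkle_metrics", "data.frame")
    list(metrics = out,
         truth = list(stage1_end_frame = n1, stage2_end_frame = n1 + n2))
  })
}

#' Synthetic contact-angle table from a known solid
#'
#' Generates probe-liquid contact angles from the forward Owens-Wendt
#' relation for a solid with known surface-energy components, optionally
#' perturbed by Gaussian noise — the round-trip oracle for
#' [owens_wendt_fit()].
#'
#' @param gamma_d,gamma_p True solid surface-energy components (mN/m).
#' @param liquids Liquid table (see [probe_liquids()]).
#' @param noise_deg Gaussian angle noise sd, degrees.
#' @param seed RNG seed.
#' @return data.frame with columns `liquid`, `theta_deg`, `flag`
#'   (wetting/dewetting saturation flags propagated from the forward
#'   model).
#' @export
generate_contact_angles <- function(gamma_d, gamma_p,
                                    liquids = probe_liquids(),
                                    noise_deg = 0, seed = 1) {
  base <- predict_contact_angle(list(gamma_d = gamma_d, gamma_p = gamma_p),
                                liquids)
  with_seed(seed, {
    theta <- base$theta_deg +
      if (noise_deg > 0) stats::rnorm(nrow(base), 0, noise_deg) else 0
    data.frame(liquid = base$liquid,
               theta_deg = pmin(pmax(theta, 0), 180),
               flag = base$flag, stringsAsFactors = FALSE)
  })
}
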