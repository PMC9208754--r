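film_ref <- elastic_film(youngs_modulus = 1000, poisson_ratio = 0.45,
                         thickness = um_thickness(15))

test_that("critical buckling stress matches the closed form and its scalings", {
  # worked example: E_f = 1 kPa, nu = 0.45, h = 15 um, R = 10 um
  sc <- critical_stress(film_ref, blister(um_to_m(10)))
  expect_equal(sc, 1.2235 * 1000 / (1 - 0.45^2) * (15 / 10)^2)
  expect_equal(sc, 3451.88, tolerance = 1e-4)
  # unit inputs give the bare prefactor
  expect_equal(critical_stress(elastic_film(1, 0, 1), blister(1)), 1.2235)
  # quadratic scaling in h/R: halving R quadruples sigma_c, R/10 gives x100
  expect_equal(critical_stress(film_ref, blister(um_to_m(5))) / sc, 4)
  expect_equal(critical_stress(film_ref, blister(um_to_m(1))) / sc, 100)
  # homogeneity: degree 1 in E_f, degree 2 in h/R (random sweep)
  set.seed(1)
  for (i in 1:20) {
    E <- runif(1, 10, 1e5); nu <- runif(1, 0, 0.49)
    h <- runif(1, 1e-6, 1e-4); R <- runif(1, 1e-6, 1e-4); k <- runif(1, 0.5, 3)
    f1 <- elastic_film(E, nu, h); f2 <- elastic_film(k * E, nu, h)
    expect_equal(critical_stress(f2, blister(R)), k * critical_stress(f1, blister(R)))
    f3 <- elastic_film(E, nu, k * h)
    expect_equal(critical_stress(f3, blister(k * R)), critical_stress(f1, blister(R)))
  }
  # monotonicity: decreasing in R, increasing in h
  expect_gt(critical_stress(film_ref, blister(9e-6)),
            critical_stress(film_ref, blister(10e-6)))
  expect_gt(critical_stress(elastic_film(1000, 0.45, 16e-6), blister(10e-6)),
            critical_stress(film_ref, blister(10e-6)))
})

test_that("input validation names the offending field", {
  expect_error(elastic_film(-1, 0.45, 1e-6), "youngs_modulus")
  expect_error(elastic_film(1000, 0.5, 1e-6), "poisson_ratio")
  expect_error(elastic_film(1000, 0.45, 0), "thickness")
  expect_error(blister(0), "radius")
  expect_error(stress_state(-1), "compressive_stress")
  expect_error(channel_flow(0, 1e-4, 1e-9), "width")
})

test_that("stored elastic energy G0 follows (1-nu) h sigma^2 / E", {
  expect_equal(baseline_energy_release(film_ref, stress_state(0)), 0)
  g0 <- baseline_energy_release(film_ref, stress_state(3500))
  expect_equal(g0, 0.55 * 15e-6 * 3500^2 / 1000)   # hand evaluation
  expect_equal(baseline_energy_release(film_ref, stress_state(7000)), 4 * g0)
})

test_that("normalized energy release rate has the Eq-2 shape", {
  sc <- critical_stress(film_ref, blister(um_to_m(10)))
  c2 <- 1 / (1 + 0.9021 * (1 - 0.45))
  # zero exactly at the critical stress, buckled flag set
  at_c <- normalized_energy_release(sc, sc, 0.45)
  expect_equal(at_c$ratio, 0)
  expect_true(at_c$buckled)
  # below critical: unbuckled state, ratio 0, not an error
  below <- normalized_energy_release(0.5 * sc, sc, 0.45)
  expect_equal(below$ratio, 0)
  expect_false(below$buckled)
  # direct substitution at sigma = 2 sigma_c
  expect_equal(normalized_energy_release(2 * sc, sc, 0.45)$ratio, c2 * 3 / 4)
  # asymptote sigma >> sigma_c
  expect_equal(normalized_energy_release(1e9 * sc, sc, 0.45)$ratio, c2,
               tolerance = 1e-9)
  # strictly monotone, bounded by c^2
  sweep <- normalized_energy_release(sc * seq(1, 50, length.out = 100), sc, 0.45)
  expect_true(all(diff(sweep$ratio) > 0))
  expect_true(all(sweep$ratio >= 0 & sweep$ratio < c2))
})

test_that("delamination verdict: crack grows only when G exceeds toughness", {
  expect_equal(delamination_verdict(1, interface_toughness(2)), "arrested")
  expect_equal(delamination_verdict(2, interface_toughness(1)), "grows")
  expect_equal(delamination_verdict(1, interface_toughness(1)), "arrested") # tie
  expect_error(delamination_verdict(-1, interface_toughness(1)))
})

test_that("minimum buckling radius inverts the critical stress", {
  R <- um_to_m(10)
  sc <- critical_stress(film_ref, blister(R))
  expect_equal(min_buckling_radius(film_ref, stress_state(sc)), R)
  # sqrt scaling: 100x stress -> R / 10
  expect_equal(min_buckling_radius(film_ref, stress_state(100 * sc)), R / 10)
  # paper-like magnitudes: ~10 um at ~3.5 kPa
  expect_equal(m_to_um(min_buckling_radius(film_ref, stress_state(3500))),
               10, tolerance = 0.01)
  expect_equal(min_buckling_radius(film_ref, stress_state(0)), Inf)
})

test_that("channel hydrodynamics reproduce the device operating point", {
  fl <- channel_flow(width = um_to_m(500), height = um_to_m(100),
                     flow_rate = ml_per_h_flow(0.3), viscosity = mPas_to_Pas(1))
  U <- mean_velocity(fl)
  expect_equal(m_to_mm(U), 1.7, tolerance = 0.03)       # ~1.7 mm/s
  expect_equal(wall_shear_stress(fl), 0.1, tolerance = 0.05)  # ~0.1 Pa
  # zero flow
  fl0 <- channel_flow(um_to_m(500), um_to_m(100), 0)
  expect_equal(mean_velocity(fl0), 0)
  expect_equal(wall_shear_stress(fl0), 0)
  # doubling width halves velocity
  fl2 <- channel_flow(um_to_m(1000), um_to_m(100), ml_per_h_flow(0.3))
  expect_equal(mean_velocity(fl2), U / 2)
  # definitional consistency: tau from U equals tau from Q
  expect_equal(wall_shear_stress(fl), 6 * fl$viscosity * U / fl$height)
})

test_that("mechanics_report bundles the quantities coherently", {
  rep <- mechanics_report(film_ref, blister(um_to_m(10)),
                          stress = stress_state(7000),
                          toughness = interface_toughness(1e-3),
                          flow = channel_flow(um_to_m(500), um_to_m(100),
                                              ml_per_h_flow(0.3)))
  expect_true(rep$buckled)
  expect_true(rep$g_ratio > 0)
  expect_true(rep$verdict %in% c("grows", "arrested"))
  expect_equal(rep$U_mm_s, 1.6667, tolerance = 1e-3)
})
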