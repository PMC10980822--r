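test_that("separation statistics reproduce the complex geometry", {
  # defaults: l0 = 2.5 + 1.5 + 4 = 8 nm, population sd of projections 1 nm
  s <- derive_separation_stats(complex_geometry())
  expect_equal(s$l0, 8, tolerance = 1e-8)
  expect_equal(s$sigma, 1, tolerance = 1e-8)

  # no offsets, single untilted estimate: projection is the full axis
  s <- derive_separation_stats(complex_geometry(b = 0, a = 0,
                                                tilt_angles_deg = 0))
  expect_equal(s$l0, 4.8)
  expect_equal(s$sigma, 0)

  # hand arithmetic: projections {4.8, 2.4}, mean 3.6, population sd 1.2
  s <- derive_separation_stats(complex_geometry(tilt_angles_deg = c(0, 60)))
  expect_equal(s$l0, 7.6, tolerance = 1e-12)
  expect_equal(s$sigma, 1.2, tolerance = 1e-12)

  expect_error(complex_geometry(tilt_angles_deg = numeric(0)),
               "tilt_angles_deg")
  expect_error(complex_geometry(b = -1), "non-negative")
  expect_error(complex_geometry(tilt_angles_deg = 95), "degrees")
})

test_that("particle model derives wrap radius and area per site", {
  p <- particle_model()
  expect_equal(p$r, 23)
  expect_equal(p$A, 37, tolerance = 0.005) # 4*pi*23^2/180 = 36.93
  expect_gt(p$r, p$Rp)
  expect_error(particle_model(Rp = 0), "Rp")
  expect_error(particle_model(l0 = 0), "l0")
})

test_that("adhesion strength follows the affinity map and clamps at zero", {
  A <- particle_model()$A
  # at the printed threshold affinity, U matches 2*kappa/r^2 within 0.1%
  expect_equal(adhesion_strength(1000, 16300, A),
               wrapping_threshold(20, 23), tolerance = 1e-3)
  expect_equal(adhesion_strength(16300, 16300, A), 0) # ln(1) = 0
  # scalar evaluation ln(16300)/36.9243
  expect_equal(adhesion_strength(1, 16300, 36.9243), 0.262670,
               tolerance = 1e-5)
  # no net attraction above rho: clamped, not negative
  expect_equal(adhesion_strength(2e4, 16300, A), 0)
  expect_error(adhesion_strength(-1, 16300, A), "positive")
})

test_that("Gaussian potential peaks at the preferred separation", {
  pot <- adhesion_potential(U = 0.1)
  expect_equal(potential_value(8, pot), -0.1)
  expect_equal(potential_value(9, pot), -0.1 * exp(-0.5), tolerance = 1e-12)
  expect_equal(potential_value(7, pot), potential_value(9, pot)) # symmetric
  expect_lt(abs(potential_value(50, pot)), 1e-10)
  l <- seq(0, 20, by = 0.01)
  expect_equal(l[which.min(potential_value(l, pot))], 8)
})

test_that("wrapping threshold is 2*kappa/r^2", {
  expect_equal(wrapping_threshold(20, 23), 40 / 529)
  expect_equal(wrapping_threshold(0, 23), 0) # zero-rigidity limit
  expect_equal(wrapping_threshold(40, 23), 2 * wrapping_threshold(20, 23))
  expect_error(wrapping_threshold(20, 0), "r > 0")
})

test_that("threshold affinity reproduces the ~1000 nM crossover", {
  expect_equal(round(threshold_affinity() / 100) * 100, 1000)
  expect_equal(threshold_affinity(kappa = 0), 16300) # zero bending cost
  expect_equal(threshold_affinity(kappa = 40), 61.2, tolerance = 1e-3)
  expect_lt(threshold_affinity(), 16300) # always below rho
})

test_that("threshold affinity and adhesion strength are mutually inverse", {
  for (kappa in c(10, 20, 40)) {
    for (rho in c(5e3, 16300, 5e4)) {
      p <- particle_model()
      kd_star <- threshold_affinity(rho, kappa, p$r, p$A)
      expect_equal(adhesion_strength(kd_star, rho, p$A),
                   wrapping_threshold(kappa, p$r), tolerance = 1e-10)
    }
  }
})

test_that("monotonicity of the affinity map", {
  A <- particle_model()$A
  kds <- 10^seq(-2, 4, length.out = 30)
  U <- adhesion_strength(kds, 16300, A)
  expect_true(all(diff(U) < 0)) # strictly decreasing below rho
  rhos <- c(5e3, 1e4, 2e4, 5e4)
  expect_true(all(diff(vapply(rhos, function(r)
    threshold_affinity(rho = r), numeric(1))) > 0))
  kappas <- c(10, 20, 30, 40)
  expect_true(all(diff(vapply(kappas, function(k)
    threshold_affinity(kappa = k), numeric(1))) < 0))
})

test_that("binding condition bundles derived quantities consistently", {
  cond <- binding_condition(600)
  expect_equal(cond$U, adhesion_strength(600))
  expect_equal(cond$U_t, wrapping_threshold(20, 23))
  expect_true(cond$U > cond$U_t) # 600 nM is in the wrapped regime
  expect_equal(cond$potential$l0, 8)
  unwrapped <- binding_condition(3800)
  expect_true(unwrapped$U < unwrapped$U_t)
  expect_output(print(cond), "wrapped")
  expect_error(binding_condition(-5), "positive")
  expect_error(membrane_model(tension = 0.1), "tension")
  expect_error(membrane_model(spontaneous_curvature = 0.1), "curvature")
})

test_that("YAML config round-trips model parameters", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kappa: 30", "Rp: 12", "rho_nM: 10000"), path)
  cfg <- read_wrap_config(path)
  expect_equal(cfg$membrane$kappa, 30)
  expect_equal(cfg$particle$r, 12 + 8)
  cond <- cfg$condition(500)
  expect_equal(cond$rho, 10000)
  expect_equal(cond$U, adhesion_strength(500, 10000, cfg$particle$A))
})
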