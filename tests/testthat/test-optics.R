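geom_typical <- function(kappa = 250e6)
  cavity_geometry(length = 10e-6, roc = 33e-6, refractive_index = 1.33,
                  wavelength = 640e-9, linewidth = kappa)

test_that("longitudinal mode number follows the resonance condition", {
  expect_equal(mode_number(geom_typical()), 41.5625, tolerance = 1e-12)
  # fundamental mode: L = lambda/(2n) gives m = 1 for any lambda, n
  for (p in list(c(1.0, 640e-9), c(1.33, 660e-9), c(1.5, 500e-9))) {
    g <- cavity_geometry(length = p[2] / (2 * p[1]), roc = 33e-6,
                         refractive_index = p[1], wavelength = p[2])
    expect_equal(mode_number(g), 1.0)
  }
  expect_error(cavity_geometry(length = -1e-6), "positive")
  expect_error(cavity_geometry(wavelength = 0), "positive")
})

test_that("figures of merit match the printed finesse and Q ranges", {
  f250 <- cavity_figures(geom_typical(250e6))
  f190 <- cavity_figures(geom_typical(190e6))
  expect_equal(f250$finesse, 45081.57, tolerance = 1e-6)
  expect_equal(f190$finesse, 59317.86, tolerance = 1e-6)
  expect_equal(f250$q_factor, 1873703, tolerance = 1e-6)
  expect_equal(f190$q_factor, 2465399, tolerance = 1e-6)
  expect_equal(f250$photon_lifetime, 6.366198e-10, tolerance = 1e-6)
  expect_error(cavity_geometry(linewidth = 0), "positive")
})

test_that("exact identities hold over randomized geometries", {
  set.seed(42)
  for (i in 1:25) {
    g <- cavity_geometry(length = runif(1, 2e-6, 50e-6),
                         roc = runif(1, 30e-6, 100e-6),
                         refractive_index = runif(1, 1, 1.6),
                         wavelength = runif(1, 400e-9, 800e-9),
                         linewidth = runif(1, 5e7, 5e8))
    f <- cavity_figures(g)
    expect_equal(f$finesse * g$linewidth, f$fsr, tolerance = 1e-12)
    # Q = m * F with the real-valued mode number
    expect_equal(f$q_factor, f$mode_number * f$finesse, tolerance = 1e-6)
  }
})

test_that("Gaussian mode reproduces the typical waist and mode volume", {
  m <- gaussian_mode(geom_typical())
  expect_equal(m$waist, 1.552555e-6, tolerance = 1e-6)
  expect_equal(m$mode_volume * 1e18, 18.93146, tolerance = 1e-6)
  expect_gt(m$mode_volume * 1e18, 14)
  expect_lt(m$mode_volume * 1e18, 20)
  # planar limit: waist grows without bound as ROC -> infinity
  w_big <- gaussian_mode(cavity_geometry(roc = 1))$waist
  expect_gt(w_big, 10 * m$waist)
  expect_error(gaussian_mode(cavity_geometry(length = 70e-6, roc = 33e-6)),
               "unstable")
})

test_that("transmission lineshape is a unit-peak Lorentzian, even in detuning", {
  expect_equal(cavity_transmission(0, 250e6), 1.0)
  expect_equal(cavity_transmission(125e6, 250e6), 0.5)
  expect_equal(cavity_transmission(-125e6, 250e6), 0.5)
  set.seed(7)
  d <- runif(50, -1e9, 1e9)
  expect_equal(cavity_transmission(d, 2e8), cavity_transmission(-d, 2e8))
  expect_true(all(cavity_transmission(d, 2e8) >= 0 &
                  cavity_transmission(d, 2e8) <= 1))
})

test_that("PDH error signal is odd, linear at lock, peaked at kappa/(2 sqrt 3)", {
  kappa <- 250e6
  expect_equal(pdh_error(0, kappa), 0)
  set.seed(8)
  d <- runif(50, -1e9, 1e9)
  expect_equal(pdh_error(-d, kappa), -pdh_error(d, kappa))
  # unit slope in x = 2 delta / kappa near the lock point
  eps <- kappa * 1e-7
  expect_equal(pdh_error(eps, kappa) / (2 * eps / kappa), 1, tolerance = 1e-6)
  # numeric maximization of the adopted dispersive form
  opt <- optimize(function(dd) abs(pdh_error(dd, kappa)), c(0, kappa),
                  maximum = TRUE)
  expect_equal(opt$maximum, kappa / (2 * sqrt(3)), tolerance = 1e-4)
  # decay far from resonance
  expect_lt(abs(pdh_error(20 * kappa, kappa)), 0.01 * pdh_error(kappa / 4, kappa))
})
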