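test_that("Stokes-Einstein diffusion matches the closed form and scalings", {
  env <- environment_conditions(temperature = 293, viscosity = 1e-3)
  expect_equal(stokes_einstein_diffusion(0.34e-9, env), 6.312056e-10,
               tolerance = 1e-6)
  expect_equal(stokes_einstein_diffusion(0.68e-9, env),
               stokes_einstein_diffusion(0.34e-9, env) / 2)
  env2 <- environment_conditions(temperature = 293, viscosity = 2e-3)
  expect_equal(stokes_einstein_diffusion(0.34e-9, env2),
               stokes_einstein_diffusion(0.34e-9, env) / 2)
  expect_error(stokes_einstein_diffusion(0), "positive")
})

test_that("packaged analyte table is ordered by excess polarizability", {
  tab <- default_analytes()
  expect_setequal(names(tab),
                  c("glycine", "alanine", "threonine", "histidine",
                    "tryptophan", "o-phospho-threonine", "myc-tag"))
  a <- vapply(tab[c("glycine", "alanine", "threonine", "histidine",
                    "tryptophan", "o-phospho-threonine", "myc-tag")],
              function(x) x$alpha_prime, numeric(1))
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 1 & a <= 50))
  expect_equal(tab$glycine$molecular_weight, 75.07)
})

test_that("perturbative shift obeys the sub-1e-5 linewidth bound and scalings", {
  geom <- cavity_geometry(linewidth = 190e6)
  an5 <- analyte("probe", alpha_prime = 5, hydrodynamic_radius = 0.3e-9)
  ps <- peak_shift(an5, geom)
  expect_equal(ps$shift_hz, 439.44, tolerance = 1e-3)  # V = 18.93 um^3
  expect_lt(ps$ratio, 1e-5)
  # inverse proportionality to mode volume: longer cavity, bigger V
  geom2 <- cavity_geometry(length = 20e-6, linewidth = 190e6)
  v_ratio <- gaussian_mode(geom2)$mode_volume / gaussian_mode(geom)$mode_volume
  expect_equal(peak_shift(an5, geom2)$shift_hz * v_ratio, ps$shift_hz,
               tolerance = 1e-10)
  # proportional to alpha'
  an10 <- analyte("probe2", alpha_prime = 10, hydrodynamic_radius = 0.3e-9)
  expect_equal(peak_shift(an10, geom)$shift_hz, 2 * ps$shift_hz)
})

test_that("mode intensity is normalized Gaussian in rho with axial spread", {
  mode <- gaussian_mode(cavity_geometry())
  expect_equal(mode_intensity(c(0, 0, 0), mode), 1.0)
  expect_equal(mode_intensity(c(mode$waist, 0, 0), mode), exp(-2))
  expect_lt(mode_intensity(c(50 * mode$waist, 0, 0), mode), 1e-100)
  # on-axis at one Rayleigh range the intensity halves
  expect_equal(mode_intensity(c(0, 0, mode$rayleigh_range), mode), 0.5)
  # matrix input matches row-wise scalar evaluation
  pts <- matrix(rnorm(15, sd = 1e-6), ncol = 3)
  expect_equal(mode_intensity(pts, mode),
               apply(pts, 1, function(p) mode_intensity(p, mode)))
})

test_that("Brownian trajectories are reproducible and match 6Dt MSD", {
  t1 <- brownian_trajectory(6e-10, 1e-5, 1e-3, seed = 3)
  t2 <- brownian_trajectory(6e-10, 1e-5, 1e-3, seed = 3)
  expect_identical(t1$positions, t2$positions)
  t0 <- brownian_trajectory(0, 1e-5, 1e-3, start = c(1, 2, 3) * 1e-6, seed = 1)
  expect_true(all(t0$positions[, 1] == 1e-6))
  # ensemble MSD at final time vs 6 D t within 3 standard errors
  set.seed(99)
  D <- 5e-10; tend <- 5e-4
  r2 <- replicate(1200, {
    p <- brownian_trajectory(D, 5e-5, tend)$positions
    sum(p[nrow(p), ]^2)
  })
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 6 * D * tend), 3 * se)
})

test_that("transit arrivals follow the Smoluchowski rate, linear in C", {
  trp <- analyte("trp", 25, 0.38e-9, diffusion_constant = 6e-10)
  env <- environment_conditions(concentration = 5e-12)
  arr <- transit_arrivals(env, trp, 1.5e-6, duration = 1, seed = 1)
  expect_equal(arr$rate, 34.0544, tolerance = 1e-5)
  expect_true(all(arr$times >= 0 & arr$times <= 1))
  # starts lie on the sensing-sphere surface
  expect_equal(sqrt(rowSums(arr$starts^2)),
               rep(1.5e-6, nrow(arr$starts)))
  env0 <- environment_conditions(concentration = 0)
  expect_length(transit_arrivals(env0, trp, 1.5e-6, 10, seed = 1)$times, 0)
  # linearity: mean counts over repeated draws scale with C within 5%
  set.seed(11)
  cs <- c(2.5e-12, 5e-12, 10e-12)
  means <- vapply(cs, function(C) {
    e <- environment_conditions(concentration = C)
    mean(replicate(120, length(transit_arrivals(e, trp, 1.5e-6, 1)$times)))
  }, numeric(1))
  fit <- lm(means ~ 0 + cs)
  expect_equal(unname(coef(fit)[1]) * 5e-12, 34.0544, tolerance = 0.05)
})
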