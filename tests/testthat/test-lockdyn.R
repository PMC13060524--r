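test_that("configuration constructors validate their invariants", {
  expect_error(lock_config(f_lp = 0), "positive")
  expect_error(thermal_config(tau_th = -1), "positive")
  expect_error(noise_config(detuning_sigma = -1))
  expect_error(pulse_schedule(c(-1e6, 5e6)), ">= 0")
  expect_error(pulse_schedule(5e6, width = 0.6, rate = 2), "width")
  expect_error(sensor_settings(cavity_geometry(), lock_config(f_lp = 5e4),
                               thermal_config(), noise_config()),
               "dt too coarse")
  expect_equal(lowpass_cutoff_from_resistance(10e3), 1591.549, tolerance = 1e-6)
  expect_equal(lowpass_cutoff_from_resistance(20e3),
               lowpass_cutoff_from_resistance(10e3) / 2)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  s <- test_settings()
  t1 <- simulate_trace(s, duration = 1, seed = 12)
  t2 <- simulate_trace(s, duration = 1, seed = 12)
  expect_identical(t1$transmission, t2$transmission)
  env <- environment_conditions(concentration = 10e-12)
  trp <- default_analytes()$tryptophan
  m1 <- simulate_trace(s, transit_program(env, trp), duration = 2, seed = 5)
  m2 <- simulate_trace(s, transit_program(env, trp), duration = 2, seed = 5)
  expect_identical(m1$transmission, m2$transmission)
  expect_error(simulate_trace(s, duration = 1), "seed")
})

test_that("noise-free lock settles to the set-point transmission exactly", {
  s <- test_settings()
  s$noise <- noise_config(0, 1e-3, 0)
  tr <- simulate_trace(s, duration = 3, seed = 1)
  tail_x <- tail(tr$transmission, 2e4)
  # equilibrium: e(x*) = e_set on the inner slope
  xstar <- uniroot(function(x) x / (1 + x^2)^2 - s$lock$e_set, c(0, 0.5))$root
  expect_equal(mean(tail_x), 1 / (1 + xstar^2), tolerance = 1e-6)
  expect_lt(sd(tail_x), 1e-7)
  expect_false(tr$lock_break)
})

test_that("blank-trace variance is explained by the injected detector noise", {
  s <- test_settings()
  tr <- simulate_trace(s, duration = 6, seed = 21)
  x <- tr$transmission[-(1:(1.5 * s$sample_rate))]
  expect_lt(abs(sd(x) - s$noise$detector_sigma) / s$noise$detector_sigma, 0.2)
  expect_true(all(x >= -0.05 & x <= 1.05))
  expect_false(tr$lock_break)
})

test_that("without thermal feedback a pulse gives one smooth dip, no burst", {
  s <- test_settings()
  s$thermal <- thermal_config(k_T = 0)
  s$noise <- noise_config(0, 1e-3, 0)
  A <- 50e6
  tr <- simulate_trace(s, pulse_program(A, t0 = 1, rate = 0.5), duration = 2,
                       seed = 2)
  x <- tr$transmission
  i_pulse <- round(1 * s$sample_rate):round(1.2 * s$sample_rate)
  # dip bounded below by the open-loop Lorentzian at the full kick
  xstar <- uniroot(function(x) x / (1 + x^2)^2 - s$lock$e_set, c(0, 0.5))$root
  floor_T <- 1 / (1 + (xstar + 2 * A / s$geom$linewidth)^2)
  expect_gte(min(x[i_pulse]), floor_T - 1e-6)
  # single excursion: after 100 ms the trace is back at baseline for good
  i_after <- round(1.1 * s$sample_rate):length(x)
  expect_true(all(x[i_after] > 0.98))
})

test_that("super-threshold pulses fire saturating multi-spike bursts", {
  s <- test_settings()
  n_multi <- 0; n_events <- 0; minima <- c()
  for (r in 1:10) {
    tr <- simulate_trace(s, pulse_program(45e6, t0 = 1, rate = 0.5),
                         duration = 3, seed = 400 + r)
    ev <- detect_events(tr)
    n_events <- n_events + nrow(ev)
    n_multi <- n_multi + sum(ev$spike_count >= 2)
    minima <- c(minima, unlist(attr(ev, "spike_minima")))
    expect_false(tr$lock_break)
  }
  expect_gte(n_events, 8)
  expect_gt(n_multi / n_events, 0.7)          # bursts, not single dips
  expect_lt(sd(minima) / mean(minima), 0.12)  # saturating spike floor
  expect_lt(mean(minima), 0.85)               # deep drops, not noise chatter
})

test_that("tryptophan transits at 5 pM produce detection events in 33 s", {
  s <- test_settings()
  env <- environment_conditions(concentration = 5e-12)
  trp <- default_analytes()$tryptophan
  tr <- simulate_trace(s, transit_program(env, trp), duration = 33, seed = 8)
  ev <- detect_events(tr)
  expect_gte(nrow(ev), 1)
  expect_false(tr$lock_break)
  # blank of the same length stays quiet
  tb <- simulate_trace(s, duration = 33, seed = 8)
  expect_lte(nrow(detect_events(tb)), 1)
})

test_that("overdriven operating points flag loss of lock", {
  s <- test_settings(input_power = 100e-6, f_lp = 150)
  tr <- simulate_trace(s, pulse_program(80e6, t0 = 1), duration = 3, seed = 1)
  expect_true(tr$lock_break)
})
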