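test_that("the standard schedule spans 5-65 MHz in 13 even steps", {
  sch <- make_schedule()
  expect_length(sch$amplitudes, 13)
  expect_equal(sch$amplitudes, seq(5e6, 65e6, by = 5e6))
  expect_equal(sch$width, 1e-3)
  expect_equal(sch$rate, 2)
  expect_equal(sch$repeats_per_amplitude, 48L)
  expect_equal(make_schedule(n_amplitudes = 2)$amplitudes, c(5e6, 65e6))
  expect_error(make_schedule(min_amp = 65e6, max_amp = 5e6), "exceed")
  # a 6.5-s trace at 2 Hz starting after settling holds 12 pulse onsets
  s <- test_settings()
  tr <- simulate_trace(s, pulse_program(30e6, t0 = 0.75, rate = 2),
                       duration = 6.5, seed = 1)
  expect_length(tr$onsets, 12)
  expect_false(is.null(tr$pulse_channel))
})

test_that("pulse scoring applies the exclusion and spurious-signal rules", {
  fake_trace <- function(onsets) {
    structure(list(sample_rate = 1000, transmission = rep(0.9, 7000),
                   pulse_channel = rep(0, 7000), onsets = onsets,
                   lock_break = FALSE, settle_time = 0.5, metadata = list()),
              class = "transmission_trace")
  }
  onsets <- seq(1, 6.5, by = 0.5)  # 12 pulses
  ev <- function(starts, ends) {
    data.frame(start_time = starts, end_time = ends,
               minimum_transmission = 0.1,
               spike_count = 1L)
  }
  # 9 of 12 pulses answered within the response window
  events <- ev(onsets[1:9] + 0.05, onsets[1:9] + 0.1)
  sc <- score_pulse_responses(fake_trace(onsets), events)
  expect_equal(sc$n_counted, 12L)
  expect_equal(sc$n_detected, 9L)
  expect_equal(sc$fraction, 0.75)
  # an event still ringing into the look-back window excludes that pulse
  events2 <- ev(c(onsets[2] - 0.2, onsets[5] + 0.05),
                c(onsets[2] - 0.05, onsets[5] + 0.1))
  sc2 <- score_pulse_responses(fake_trace(onsets), events2)
  expect_equal(sc2$n_counted, 11L)
  expect_equal(sc2$n_detected, 1L)
  # spurious events between pulses do not count as responses
  events3 <- ev(onsets[3] + 0.4, onsets[3] + 0.45)
  sc3 <- score_pulse_responses(fake_trace(onsets), events3)
  expect_equal(sc3$n_detected, 0L)
  expect_equal(sc3$n_counted, 11L)  # spurious event rings into pulse 4
  # missing pulse channel refuses
  tr <- fake_trace(onsets); tr$pulse_channel <- NULL
  expect_error(score_pulse_responses(tr, events), "pulse channel")
})

test_that("sigmoid fitting recovers known parameters from binomial data", {
  a <- seq(5e6, 65e6, length.out = 13)
  set.seed(10)
  for (i in 1:5) {
    k <- rbinom(13, 48, 1 / (1 + exp(-(a - 30e6) / 5e6)))
    f <- fit_sigmoid(data.frame(amplitude_hz = a, n = 48, detected = k))
    expect_lt(abs(f$a50 - 30e6), 2e6)
    expect_lt(abs(f$scale - 5e6), 2e6)
  }
  # perfectly symmetric fractions center the midpoint
  ks <- round(48 / (1 + exp(-(a - 35e6) / 5e6)))
  stopifnot(all(ks + rev(ks) == 48))  # symmetric about 35 MHz by design
  fs <- fit_sigmoid(data.frame(amplitude_hz = a, n = 48, detected = ks))
  expect_equal(fs$a50, 35e6, tolerance = 1e-4)
  expect_error(fit_sigmoid(data.frame(amplitude_hz = a, n = 48,
                                      detected = rep(0, 13))),
               "non-identifiable")
  expect_error(fit_sigmoid(data.frame(amplitude_hz = a, n = 48,
                                      detected = rep(48, 13))),
               "non-identifiable")
  expect_warning(fit_sigmoid(data.frame(amplitude_hz = a, n = 48,
                                        detected = rev(ks))),
                 "negative")
})

test_that("piezo conversion is recovered and is scan-speed invariant", {
  sc <- synthetic_piezo_scan(10e9, slope = 10, seed = 4)
  pc <- piezo_conversion(sc)
  expect_lt(abs(pc$hz_per_volt - 10e9) / 10e9, 0.01)
  # doubling the ramp slope halves the peak separation, conversion unchanged
  sc2 <- synthetic_piezo_scan(10e9, slope = 20, seed = 4)
  pc2 <- piezo_conversion(sc2)
  expect_lt(abs(pc2$hz_per_volt - pc$hz_per_volt) / pc$hz_per_volt, 0.01)
  expect_lt(abs(diff(pc2$peak_times)[1] - diff(pc$peak_times)[1] / 2), 1e-3)
  # downward ramps work too
  sc3 <- synthetic_piezo_scan(8e9, slope = -10, seed = 4)
  expect_lt(abs(piezo_conversion(sc3)$hz_per_volt - 8e9) / 8e9, 0.01)
  # featureless scan refuses
  flat <- list(times = seq(0, 1, 1e-3), transmission = rep(0.1, 1001),
               drive_voltage = seq(0, 10, 1e-2), sideband_frequency = 1e9)
  expect_error(piezo_conversion(flat), "peaks")
})

test_that("simulator-driven calibration yields a rising, fittable curve", {
  s <- test_settings()
  sched <- make_schedule(min_amp = 15e6, max_amp = 55e6, n_amplitudes = 5,
                         repeats_per_amplitude = 12)
  cal <- run_calibration(s, sched, trace_length = 6.5, seed = 31)
  expect_true(all(cal$curve$detected <= cal$curve$n))
  expect_true(all(cal$curve$fraction >= 0 & cal$curve$fraction <= 1))
  expect_lt(cal$curve$fraction[1], 0.2)
  expect_gt(cal$curve$fraction[5], 0.8)
  expect_true(is.finite(cal$a50))
  expect_gt(cal$a50, 15e6)
  expect_lt(cal$a50, 55e6)
})
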