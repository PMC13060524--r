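#' Build a calibration pulse schedule
#'
#' Evenly spaced pulse amplitudes between two endpoints, inclusive; the
#' standard internal-calibration program is 13 amplitudes from 5 to 65 MHz,
#' 1-ms pulses at 2 Hz, 48 repeats per amplitude (four 6-s traces of 12
#' pulses each).
#'
#' @param min_amp,max_amp Amplitude endpoints (Hz), `max_amp > min_amp`.
#' @param n_amplitudes Number of amplitudes (>= 2).
#' @param width Pulse width (s).
#' @param rate Repetition rate (Hz).
#' @param repeats_per_amplitude Pulses per amplitude.
#' @return A [pulse_schedule()].
#' @export
#' @examples
#' make_schedule()$amplitudes / 1e6  # 5, 10, ..., 65
make_schedule <- function(min_amp = 5e6, max_amp = 65e6, n_amplitudes = 13,
                          width = 1e-3, rate = 2,
                          repeats_per_amplitude = 48) {
  if (max_amp <= min_amp) stop("max_amp must exceed min_amp", call. = FALSE)
  if (n_amplitudes < 2) stop("need at least 2 amplitudes", call. = FALSE)
  pulse_schedule(seq(min_amp, max_amp, length.out = n_amplitudes),
                 width = width, rate = rate,
                 repeats_per_amplitude = repeats_per_amplitude)
}

#' Score pulse responses against detected events
#'
#' Applies the pulse-counting rules of the internal calibration: a pulse
#' enters the denominator only if the cavity is not still oscillating from a
#' previous burst when it arrives — no detected event may overlap the
#' look-back window before the onset; a counted pulse is detected if an
#' event starts within the response window after its onset; events not
#' matched to any pulse are spurious and ignored.
#'
#' @param trace A `transmission_trace` with a pulse channel.
#' @param events `detection_events` from [detect_events()] on that trace.
#' @param response_window Seconds after onset within which an event start
#'   counts as a response (default 0.25 s; pulses at 2 Hz are 0.5 s apart).
#' @param lookback Baseline-precedence window before onset (s).
#' @return List: `n_counted`, `n_detected`, `fraction` (NA when nothing
#'   counted).
#' @export
score_pulse_responses <- function(trace, events, response_window = 0.25,
                                  lookback = 0.1) {
  stopifnot(inherits(trace, "transmission_trace"))
  if (is.null(trace$pulse_channel))
    stop("trace has no pulse channel; was it simulated with a pulse program?",
         call. = FALSE)
  onsets <- trace$onsets
  n_counted <- 0L
  n_detected <- 0L
  for (t_on in onsets) {
    busy <- any(events$end_time >= t_on - lookback &
                events$start_time < t_on)
    if (busy) next  # oscillating before the pulse
    n_counted <- n_counted + 1L
    hit <- any(events$start_time >= t_on &
               events$start_time <= t_on + response_window)
    if (hit) n_detected <- n_detected + 1L
  }
  list(n_counted = n_counted, n_detected = n_detected,
       fraction = if (n_counted) n_detected / n_counted else NA_real_)
}

#' Run a full pulse-response calibration
#'
#' Simulates traces for every amplitude in a schedule at the supplied sensor
#' settings, detects events, scores pulse responses, and fits the sigmoid
#' sensitivity curve. The A50 midpoint is the sensitivity threshold used to
#' compare operating points across experiments.
#'
#' @param settings A [sensor_settings()], e.g. [burst_regime()].
#' @param schedule A [pulse_schedule()] from [make_schedule()].
#' @param trace_length Length of each simulated trace (s); pulses start
#'   after the settling window.
#' @param seed Integer seed; per-trace seeds are derived from it.
#' @param drop_fraction Passed to [detect_events()].
#' @param min_gap Clustering gap used when matching responses to pulses (s).
#'   Pulses arrive every `1/rate` seconds, so responses are clustered with a
#'   gap short enough to keep consecutive pulse responses distinct (default
#'   0.2 s at the standard 2 Hz); the 0.5-s independence rule is for
#'   free-running molecular data, not pulse-locked responses.
#' @param fit Fit the sigmoid (set `FALSE` to return counts only).
#' @return Object of class `calibration_curve`: data.frame `curve`
#'   (amplitude_hz, n, detected, fraction) plus `a50`, `scale` when fitted.
#' @export
run_calibration <- function(settings, schedule = make_schedule(),
                            trace_length = 6.5, seed = 1,
                            drop_fraction = 0.5, min_gap = 0.2, fit = TRUE) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  t0 <- settings$settle_time + 0.25
  pulses_per_trace <- floor((trace_length - t0) * schedule$rate)
  n_traces <- ceiling(schedule$repeats_per_amplitude / pulses_per_trace)
  amps <- schedule$amplitudes
  n <- det <- integer(length(amps))
  for (a in seq_along(amps)) {
    for (j in seq_len(n_traces)) {
      tr <- simulate_trace(settings,
                           pulse_program(amps[a], width = schedule$width,
                                         rate = schedule$rate, t0 = t0),
                           duration = trace_length,
                           seed = seed + 1000L * a + j)
      ev <- detect_events(tr, drop_fraction = drop_fraction,
                          min_gap = min_gap)
      sc <- score_pulse_responses(tr, ev)
      n[a] <- n[a] + sc$n_counted
      det[a] <- det[a] + sc$n_detected
    }
  }
  curve <- data.frame(amplitude_hz = amps, n = n, detected = det,
                      fraction = ifelse(n > 0, det / n, NA_real_))
  out <- list(curve = curve, a50 = NA_real_, scale = NA_real_)
  if (fit) {
    f <- tryCatch(fit_sigmoid(curve), error = function(e) NULL)
    if (!is.null(f)) { out$a50 <- f$a50; out$scale <- f$scale }
  }
  structure(out, class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  print(transform(x$curve, amplitude_mhz = amplitude_hz / 1e6)[
    c("amplitude_mhz", "n", "detected", "fraction")])
  if (is.finite(x$a50))
    cat(sprintf("sigmoid fit: A50 = %.2f MHz, scale = %.2f MHz\n",
                x$a50 / 1e6, x$scale / 1e6))
  invisible(x)
}

#' Fit the sigmoid sensitivity curve
#'
#' Binomial maximum-likelihood fit of
#' `f(A) = 1 / (1 + exp(-(A - A50)/s))` to fraction-detected data — i.e.
#' logistic regression of detected counts on amplitude, with
#' `A50 = -b0/b1` and `s = 1/b1`. Points are weighted by their pulse counts,
#' which an unweighted least-squares fit would ignore.
#'
#' @param curve data.frame with columns `amplitude_hz`, `n`, `detected`
#'   (as produced by [run_calibration()]), or `fraction` plus `n`.
#' @return List: `a50` (Hz), `scale` (Hz), `fitted` (function of amplitude).
#'   Errors on all-0/all-1 fractions (non-identifiable) and flags negative
#'   slope (monotone-decreasing input).
#' @export
#' @examples
#' a <- seq(5e6, 65e6, length.out = 13)
#' f <- 1 / (1 + exp(-(a - 30e6) / 5e6))
#' fit_sigmoid(data.frame(amplitude_hz = a, n = 48, detected = round(48 * f)))
fit_sigmoid <- function(curve) {
  stopifnot(is.data.frame(curve), "amplitude_hz" %in% names(curve))
  if (!"detected" %in% names(curve) && "fraction" %in% names(curve))
    curve$detected <- round(curve$fraction * curve$n)
  ok <- is.finite(curve$detected) & curve$n > 0
  curve <- curve[ok, ]
  if (nrow(curve) < 4)
    stop("need at least 4 amplitude points with counts", call. = FALSE)
  if (all(curve$detected == 0) || all(curve$detected == curve$n))
    stop("non-identifiable: all fractions are 0 or 1", call. = FALSE)
  A <- curve$amplitude_hz / 1e6  # fit in MHz for conditioning
  # glm warns when fractions saturate at 0/1; that is the normal shape of a
  # steep calibration curve, and identifiability is checked explicitly
  m <- suppressWarnings(stats::glm(cbind(detected, n - detected) ~ A,
                                   family = stats::binomial(), data = curve))
  b <- stats::coef(m)
  if (!is.finite(b[2]) || b[2] == 0)
    stop("non-identifiable sigmoid (zero slope)", call. = FALSE)
  if (b[2] < 0)
    warning("negative sigmoid slope: fraction-detected decreases with amplitude")
  a50 <- -b[1] / b[2] * 1e6
  s <- 1 / b[2] * 1e6
  list(a50 = unname(a50), scale = unname(s),
       fitted = function(amplitude_hz)
         1 / (1 + exp(-(amplitude_hz - a50) / s)))
}

#' Piezo frequency-conversion calibration
#'
#' Recovers the Hz-per-volt conversion of a length-tuning piezo from a scan
#' in which a triangle voltage ramp sweeps the cavity across a
#' phase-modulated resonance: the carrier and its two sidebands (at a known
#' modulation frequency) appear as three transmission peaks; the
#' carrier-to-sideband time separation together with the fitted ramp slope
#' gives `conversion = sideband_frequency / (dt * slope)`.
#'
#' @param scan List of class `piezo_scan` (see [synthetic_piezo_scan()]):
#'   `times` (s), `transmission`, `drive_voltage` (V), `sideband_frequency`
#'   (Hz).
#' @return List: `hz_per_volt`, `slope_v_per_s`, `peak_times` (carrier,
#'   lower, upper).
#' @export
piezo_conversion <- function(scan) {
  stopifnot(all(c("times", "transmission", "drive_voltage",
                  "sideband_frequency") %in% names(scan)))
  # fit the monotone ramp segment around the peaks
  slope <- stats::coef(stats::lm(scan$drive_voltage ~ scan$times))[2]
  x <- scan$transmission
  # peaks: local maxima above 20% of range, separated by at least 5 samples
  thr <- min(x) + 0.2 * diff(range(x))
  cand <- which(x > thr &
                x >= c(-Inf, head(x, -1)) &
                x >= c(tail(x, -1), -Inf))
  # collapse plateaus / near-duplicates
  if (length(cand)) {
    keep <- cand[c(TRUE, diff(cand) > 5)]
  } else keep <- integer(0)
  if (length(keep) < 3)
    stop("could not resolve carrier and sideband peaks (need 3)",
         call. = FALSE)
  # three tallest well-separated peaks, in time order
  ord <- keep[order(x[keep], decreasing = TRUE)][1:3]
  ord <- sort(ord)
  t_peaks <- scan$times[ord]
  dt <- mean(diff(t_peaks))  # carrier-to-sideband separation
  list(hz_per_volt = unname(scan$sideband_frequency / (dt * abs(slope))),
       slope_v_per_s = unname(slope),
       peak_times = t_peaks)
}

#' Generate a synthetic piezo calibration scan
#'
#' Builds a `piezo_scan` with a known ground-truth conversion: a linear
#' voltage ramp sweeps the resonance plus phase-modulation sidebands across
#' the pump, producing three Lorentzian peaks. Used for round-trip testing
#' and fixtures.
#'
#' @param hz_per_volt Ground-truth conversion (Hz/V).
#' @param slope Ramp slope (V/s).
#' @param sideband_frequency Modulation frequency (Hz).
#' @param linewidth Resonance linewidth (Hz).
#' @param sample_rate Scan sampling rate (Hz).
#' @param duration Scan length (s).
#' @param noise_sd Additive Gaussian noise on the transmission.
#' @param seed Optional seed for the noise.
#' @return List of class `piezo_scan`.
#' @export
#' @examples
#' sc <- synthetic_piezo_scan(8e9)
#' piezo_conversion(sc)$hz_per_volt / 1e9  # ~8
synthetic_piezo_scan <- function(hz_per_volt = 8e9, slope = 10,
                                 sideband_frequency = 1e9,
                                 linewidth = 60e6, sample_rate = 50e3,
                                 duration = 0.05, noise_sd = 0.002,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration, by = 1 / sample_rate)
  volts <- slope * (times - duration / 2)
  freq <- hz_per_volt * volts  # pump-resonance detuning swept by the ramp
  x <- cavity_transmission(freq, linewidth) +
    0.3 * cavity_transmission(freq - sideband_frequency, linewidth) +
    0.3 * cavity_transmission(freq + sideband_frequency, linewidth)
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), sd = noise_sd)
  structure(list(times = times, transmission = x, drive_voltage = volts,
                 sideband_frequency = sideband_frequency),
            class = "piezo_scan")
}
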