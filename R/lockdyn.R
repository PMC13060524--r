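#' Servo (PDH lock) configuration
#'
#' Parameters of the PI servo that holds the cavity on resonance. The servo
#' acts on the low-pass-filtered PDH error signal relative to a set point;
#' a positive set point parks the lock slightly off the fringe top, which is
#' the sensitized operating point of the burst-firing regime.
#'
#' @param g_p Proportional gain (dimensionless).
#' @param g_i Integral gain (1/s).
#' @param e_set Error-signal set point (dimensionless, in units of the
#'   unit-slope PDH error signal). 0 locks dead-center; the usable range is
#'   below the error-signal extremum ~0.325.
#' @param f_lp Servo low-pass cutoff (Hz); lower cutoffs mean lower locking
#'   bandwidth and higher sensitivity to fast perturbations.
#' @param k_act Actuator gain (Hz of detuning per unit servo output).
#' @param pdh_mod_freq Phase-modulation frequency (Hz); metadata only.
#' @return Object of class `lock_config`.
#' @export
lock_config <- function(g_p = 0.0, g_i = 10000, e_set = 0.05, f_lp = 200,
                        k_act = 2e8, pdh_mod_freq = 1e9) {
  if (!is.finite(f_lp) || f_lp <= 0) stop("f_lp must be positive", call. = FALSE)
  if (!all(is.finite(c(g_p, g_i, e_set, k_act))))
    stop("gains and set point must be finite", call. = FALSE)
  structure(list(g_p = g_p, g_i = g_i, e_set = e_set, f_lp = f_lp,
                 k_act = k_act, pdh_mod_freq = pdh_mod_freq),
            class = "lock_config")
}

#' Photothermal configuration
#'
#' Single-pole thermal model of the mirror region: absorbed intracavity power
#' heats with coefficient `c_abs`, the offset relaxes with time constant
#' `tau_th`, and the thermo-optic coupling `k_T` converts temperature offset
#' into resonance detuning. A negative `k_T` at a positive-detuning lock
#' point makes the thermal path regenerative for transmission-reducing
#' excursions: a dip cools the cavity, which pushes the resonance further
#' away — the photothermal cascade behind burst firing.
#'
#' @param tau_th Thermal relaxation time (s).
#' @param c_abs Heating coefficient (K per W of coupled power per s).
#' @param k_T Thermo-optic gain (Hz of detuning per K, signed).
#' @return Object of class `thermal_config`.
#' @export
thermal_config <- function(tau_th = 5e-4, c_abs = 2e4, k_T = -5.4e11) {
  if (!is.finite(tau_th) || tau_th <= 0)
    stop("tau_th must be positive", call. = FALSE)
  structure(list(tau_th = tau_th, c_abs = c_abs, k_T = k_T),
            class = "thermal_config")
}

#' Noise configuration
#'
#' Two noise sources: Ornstein-Uhlenbeck detuning noise (environmental /
#' acoustic drive of the cavity length, stationary standard deviation
#' `detuning_sigma`, correlation time `corr_time`) and white detector noise
#' added to the sampled transmission.
#'
#' @param detuning_sigma Stationary std of the OU detuning noise (Hz).
#' @param corr_time OU correlation time (s).
#' @param detector_sigma White detector noise, as a fraction of full
#'   transmission.
#' @return Object of class `noise_config`.
#' @export
noise_config <- function(detuning_sigma = 4e6, corr_time = 1e-3,
                         detector_sigma = 0.015) {
  if (any(c(detuning_sigma, corr_time, detector_sigma) < 0))
    stop("noise parameters must be >= 0", call. = FALSE)
  if (corr_time <= 0) stop("corr_time must be positive", call. = FALSE)
  structure(list(detuning_sigma = detuning_sigma, corr_time = corr_time,
                 detector_sigma = detector_sigma),
            class = "noise_config")
}

#' Map low-pass filter resistance to cutoff frequency
#'
#' The experimental servo inserts an RC low-pass (resistance 10-32 kOhm)
#' before the length actuator; given a nominal capacitance this maps the
#' resistance to the cutoff `f = 1/(2 pi R C)` used by [lock_config()].
#'
#' @param resistance Resistance (Ohm).
#' @param capacitance Nominal capacitance (F); default 10 nF.
#' @return Cutoff frequency (Hz).
#' @export
#' @examples
#' lowpass_cutoff_from_resistance(10e3)  # ~1.6 kHz
lowpass_cutoff_from_resistance <- function(resistance, capacitance = 10e-9) {
  if (any(resistance <= 0) || capacitance <= 0)
    stop("resistance and capacitance must be positive", call. = FALSE)
  1 / (2 * pi * resistance * capacitance)
}

#' Square-pulse injection schedule
#'
#' Program of piezo test pulses used for internal calibration: a list of
#' pulse amplitudes (expressed as cavity frequency shifts), a common width
#' and repetition rate, and the number of repeats per amplitude.
#'
#' @param amplitudes Pulse amplitudes (Hz, >= 0).
#' @param width Pulse width (s).
#' @param rate Repetition rate (Hz); `width * rate` must be < 1.
#' @param repeats_per_amplitude Pulses applied per amplitude.
#' @return Object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(amplitudes, width = 1e-3, rate = 2,
                           repeats_per_amplitude = 48) {
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (width * rate >= 1) stop("width * rate must be < 1", call. = FALSE)
  structure(list(amplitudes = amplitudes, width = width, rate = rate,
                 repeats_per_amplitude = as.integer(repeats_per_amplitude)),
            class = "pulse_schedule")
}

#' Single-amplitude pulse program for one trace
#'
#' Drive program injecting square detuning pulses of one amplitude at a fixed
#' rate, starting after the lock-settling window.
#'
#' @param amplitude Pulse amplitude (Hz).
#' @param width Pulse width (s).
#' @param rate Repetition rate (Hz).
#' @param t0 Time of the first pulse onset (s); defaults to 0.75 s, past the
#'   0.5-s settling window.
#' @return Object of class `pulse_program`.
#' @export
pulse_program <- function(amplitude, width = 1e-3, rate = 2, t0 = 0.75) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, width = width, rate = rate, t0 = t0),
            class = "pulse_program")
}

#' Molecular-transit drive program
#'
#' Drive program in which molecules of one analyte arrive by diffusion at a
#' spherical sensing region around the mode waist and their Brownian paths
#' are converted to an effective detuning drive
#' `delta_ext(t) = gain * dnu_max * I(r(t))` summed over molecules in
#' transit. `dnu_max` is the first-order perturbative mode-center shift
#' ([peak_shift()]); `gain` is the photothermal pre-amplification factor of
#' the sensing regime (see the methods vignette) — the fast thermal stage
#' that converts the raw polarizability shift into the effective detuning
#' excursion seen by the servo.
#'
#' @param env An [environment_conditions()] (concentration, temperature,
#'   viscosity).
#' @param an An [analyte()].
#' @param response_gain Dimensionless pre-amplification; `NULL` uses the
#'   value pinned in the settings.
#' @param sensing_radius_factor Sensing-sphere radius as a multiple of the
#'   mode waist; trajectories are discarded past twice this radius.
#' @return Object of class `transit_program`.
#' @export
transit_program <- function(env, an, response_gain = NULL,
                            sensing_radius_factor = 1.5) {
  stopifnot(inherits(env, "environment_conditions"), inherits(an, "analyte"))
  structure(list(env = env, analyte = an, response_gain = response_gain,
                 sensing_radius_factor = sensing_radius_factor),
            class = "transit_program")
}

#' Pinned burst-firing sensor preset
#'
#' Returns the packaged operating point of the burst-firing detection regime:
#' cavity geometry, servo, thermal and noise configuration, and the
#' molecular response gain, bundled as `sensor_settings`. The same knobs the
#' experiment tunes are exposed: raising `input_power`, lowering `f_lp` or
#' raising `e_set` all increase sensitivity (shift the pulse-detection
#' threshold to smaller amplitudes).
#'
#' @param input_power Injected optical power (W).
#' @param e_set Servo set point (see [lock_config()]).
#' @param f_lp Servo low-pass cutoff (Hz).
#' @param detuning_sigma OU detuning-noise std (Hz).
#' @param response_gain Molecular photothermal pre-amplification factor.
#' @param linewidth Cavity linewidth (Hz).
#' @param ... Further overrides passed to [cavity_geometry()].
#' @return Object of class `sensor_settings`: fields `geom`, `mode`, `lock`,
#'   `thermal`, `noise`, `response_gain`, `dt`, `sample_rate`,
#'   `settle_time`.
#' @export
#' @examples
#' s <- burst_regime()
#' tr <- simulate_trace(s, drive = pulse_program(45e6), duration = 2, seed = 1)
burst_regime <- function(input_power = 50e-6, e_set = 0.05, f_lp = 200,
                         detuning_sigma = 4e6, response_gain = 10000,
                         linewidth = 200e6, ...) {
  geom <- cavity_geometry(linewidth = linewidth, input_power = input_power, ...)
  sensor_settings(
    geom = geom,
    lock = lock_config(g_p = 0, g_i = 10000, e_set = e_set, f_lp = f_lp),
    thermal = thermal_config(tau_th = 5e-4, c_abs = 2e4, k_T = -5.4e11),
    noise = noise_config(detuning_sigma = detuning_sigma, corr_time = 1e-3,
                         detector_sigma = 0.015),
    response_gain = response_gain
  )
}

#' Bundle sensor settings
#'
#' @param geom A [cavity_geometry()].
#' @param lock A [lock_config()].
#' @param thermal A [thermal_config()].
#' @param noise A [noise_config()].
#' @param response_gain Molecular photothermal pre-amplification factor.
#' @param dt Integrator step (s).
#' @param sample_rate Output sampling rate (Hz).
#' @param settle_time Lock-settling window excluded from analysis (s).
#' @return Object of class `sensor_settings`.
#' @export
sensor_settings <- function(geom, lock, thermal, noise, response_gain = 10000,
                            dt = 1e-5, sample_rate = 2e4, settle_time = 0.5) {
  stopifnot(inherits(geom, "cavity_geometry"), inherits(lock, "lock_config"),
            inherits(thermal, "thermal_config"), inherits(noise, "noise_config"))
  if (dt > 0.1 / lock$f_lp)
    stop("dt too coarse for the servo low-pass: require dt <= 0.1/f_lp",
         call. = FALSE)
  if (dt > 0.1 * noise$corr_time)
    stop("dt too coarse for the noise correlation time", call. = FALSE)
  structure(list(geom = geom, mode = gaussian_mode(geom), lock = lock,
                 thermal = thermal, noise = noise,
                 response_gain = response_gain, dt = dt,
                 sample_rate = sample_rate, settle_time = settle_time),
            class = "sensor_settings")
}

# Brownian path from a boundary start until exit at the kill radius; returns
# n x 3 positions at dt resolution (capped at max_steps). Uses current RNG.
.transit_path <- function(D, dt, start, kill_radius, max_steps = 20000L) {
  chunk <- 512L
  pos <- start
  out <- matrix(NA_real_, nrow = max_steps, ncol = 3)
  n <- 0L
  sd_step <- sqrt(2 * D * dt)
  repeat {
    steps <- matrix(stats::rnorm(3L * chunk, sd = sd_step), ncol = 3)
    path <- sweep(apply(steps, 2, cumsum), 2, pos, `+`)
    r2 <- rowSums(path^2)
    exited <- which(r2 > kill_radius^2)
    take <- if (length(exited)) exited[1L] else chunk
    take <- min(take, max_steps - n)
    if (take > 0L) {
      out[n + seq_len(take), ] <- path[seq_len(take), , drop = FALSE]
      n <- n + take
    }
    if (length(exited) || n >= max_steps) break
    pos <- path[chunk, ]
  }
  out[seq_len(n), , drop = FALSE]
}

# Build the external-drive vector (Hz per integrator step) for a drive
# program. Returns list(delta_ext, onsets, n_molecules, arrival_rate).
.build_drive <- function(drive, settings, n_steps, dt) {
  delta_ext <- numeric(n_steps)
  onsets <- NULL
  n_mol <- 0L
  rate <- NA_real_
  if (is.null(drive)) {
    # blank (water) trace
  } else if (inherits(drive, "pulse_program")) {
    width_steps <- max(1L, round(drive$width / dt))
    period <- 1 / drive$rate
    t_end <- (n_steps - width_steps) * dt
    if (drive$t0 <= t_end)
      onsets <- seq(drive$t0, t_end, by = period)
    for (t_on in onsets) {
      i0 <- round(t_on / dt) + 1L
      idx <- i0:min(n_steps, i0 + width_steps - 1L)
      delta_ext[idx] <- delta_ext[idx] + drive$amplitude
    }
  } else if (inherits(drive, "transit_program")) {
    gain <- drive$response_gain
    if (is.null(gain)) gain <- settings$response_gain
    shift <- peak_shift(drive$analyte, settings$geom, settings$mode)$shift_hz
    R_s <- drive$sensing_radius_factor * settings$mode$waist
    arr <- transit_arrivals(drive$env, drive$analyte, R_s, n_steps * dt)
    rate <- arr$rate
    n_mol <- length(arr$times)
    D <- arr$diffusion_constant
    for (k in seq_len(n_mol)) {
      path <- .transit_path(D, dt, arr$starts[k, ], 2 * R_s)
      if (nrow(path) == 0L) next
      i0 <- round(arr$times[k] / dt) + 1L
      if (i0 > n_steps) next
      idx <- i0:min(n_steps, i0 + nrow(path) - 1L)
      contrib <- gain * shift * mode_intensity(path[seq_along(idx), ,
                                                    drop = FALSE],
                                               settings$mode)
      delta_ext[idx] <- delta_ext[idx] + contrib
    }
  } else {
    stop("unsupported drive program: ", paste(class(drive), collapse = "/"),
         call. = FALSE)
  }
  list(delta_ext = delta_ext, onsets = onsets, n_molecules = n_mol,
       arrival_rate = rate)
}

#' Simulate a locked-cavity transmission trace
#'
#' Integrates the coupled optical-thermal-servo dynamics of the locked FFPC
#' with explicit Euler-Maruyama stepping and returns the decimated,
#' normalized transmission time series. The drive can be `NULL` (blank water
#' trace: noise only), a [pulse_program()] (calibration pulses, recorded in
#' the pulse channel), or a [transit_program()] (Poisson molecular transits
#' converted to an effective detuning drive). Fully reproducible under a
#' fixed seed. The thermal operating point is captured at the end of the
#' settling window; the window is excluded from downstream analysis.
#'
#' @param settings A [sensor_settings()] bundle, e.g. [burst_regime()].
#' @param drive Drive program or `NULL`.
#' @param duration Trace duration (s).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Object of class `transmission_trace`: `sample_rate`,
#'   `transmission`, optional `pulse_channel` (Hz), `onsets`, `lock_break`
#'   flag, and `metadata` (settings snapshot, seed, molecule count).
#' @export
#' @examples
#' s <- burst_regime()
#' tr <- simulate_trace(s, duration = 2, seed = 7)  # blank trace
simulate_trace <- function(settings, drive = NULL, duration, seed) {
  stopifnot(inherits(settings, "sensor_settings"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory for simulation", call. = FALSE)
  set.seed(as.integer(seed))
  dt <- settings$dt
  decim <- max(1L, round(1 / (settings$sample_rate * dt)))
  n_steps <- as.integer(round(duration / dt))
  n_steps <- (n_steps %/% decim) * decim

  dr <- .build_drive(drive, settings, n_steps, dt)
  lk <- settings$lock; th <- settings$thermal; nz <- settings$noise
  res <- sim_core(dr$delta_ext, dt, decim, settings$geom$linewidth,
                  lk$g_p, lk$g_i, lk$e_set, lk$f_lp, lk$k_act,
                  th$tau_th, th$c_abs, th$k_T, settings$geom$input_power,
                  nz$detuning_sigma, nz$corr_time, nz$detector_sigma,
                  settings$settle_time,
                  lockbreak_mult = 5, lockbreak_dur = 0.05)
  if (res$diverged)
    stop(sprintf("simulation diverged at t = %.4f s", res$diverge_time),
         call. = FALSE)
  trans <- res$transmission
  pulse_channel <- NULL
  if (inherits(drive, "pulse_program")) {
    idx <- seq(1L, n_steps, by = decim)
    pulse_channel <- dr$delta_ext[idx]
  }
  structure(list(
    sample_rate = settings$sample_rate,
    transmission = trans,
    pulse_channel = pulse_channel,
    onsets = dr$onsets,
    lock_break = isTRUE(res$lock_break),
    settle_time = settings$settle_time,
    metadata = list(seed = as.integer(seed), duration = duration,
                    dt = dt, n_molecules = dr$n_molecules,
                    arrival_rate = dr$arrival_rate,
                    settings = unclass_settings(settings))
  ), class = "transmission_trace")
}

# flatten settings into plain lists for metadata / serialization
unclass_settings <- function(settings) {
  lapply(settings[c("geom", "lock", "thermal", "noise")], unclass) |>
    c(list(response_gain = settings$response_gain, dt = settings$dt,
           sample_rate = settings$sample_rate,
           settle_time = settings$settle_time))
}

#' @export
print.transmission_trace <- function(x, ...) {
  cat(sprintf("transmission trace: %.3g s at %g kHz (%d samples)%s\n",
              length(x$transmission) / x$sample_rate, x$sample_rate / 1e3,
              length(x$transmission),
              if (x$lock_break) " [LOCK BREAK]" else ""))
  if (!is.null(x$pulse_channel))
    cat(sprintf("  pulse channel present, %d onsets\n", length(x$onsets)))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A `transmission_trace`.
#' @return Numeric vector of sample times (s), starting at 1/sample_rate.
#' @export
trace_times <- function(trace) {
  seq_along(trace$transmission) / trace$sample_rate
}
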