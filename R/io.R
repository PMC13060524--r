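#' Write a transmission trace to a columnar file
#'
#' Plain-text columnar container: a JSON metadata block in '#'-prefixed
#' header lines followed by CSV columns `time_s, transmission[, pulse_hz]`.
#' Values round-trip to 9 significant digits; metadata (settings snapshot,
#' seed, settling window) round-trips losslessly.
#'
#' @param trace A `transmission_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "transmission_trace"))
  meta <- list(sample_rate = trace$sample_rate,
               settle_time = trace$settle_time,
               lock_break = trace$lock_break,
               onsets = trace$onsets,
               metadata = trace$metadata)
  hdr <- paste0("# ffpcsim-trace ",
                jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                 null = "null"))
  df <- data.frame(time_s = trace_times(trace),
                   transmission = trace$transmission)
  if (!is.null(trace$pulse_channel)) df$pulse_hz <- trace$pulse_channel
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  fmt <- vapply(df, function(col) formatC(col, digits = 9, format = "g"),
                character(nrow(df)))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(matrix(fmt, nrow = nrow(df)), 1, paste, collapse = ","),
             con)
  invisible(path)
}

#' Read a transmission trace
#'
#' Reads the container written by [write_trace()], or a bare CSV with
#' columns `time_s, transmission[, pulse_hz]` (in which case `sample_rate`
#' is inferred from the time column and there is no metadata). Calibration
#' scoring requires the pulse channel; traces read without one refuse
#' cleanly there.
#'
#' @param path File path.
#' @return A `transmission_trace`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  meta <- NULL
  if (startsWith(first, "# ffpcsim-trace ")) {
    meta <- jsonlite::fromJSON(sub("^# ffpcsim-trace ", "", first),
                               simplifyVector = TRUE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "transmission") %in% names(df)))
    stop("malformed trace file (need time_s, transmission columns): ", path,
         call. = FALSE)
  sr <- if (!is.null(meta)) meta$sample_rate
        else 1 / stats::median(diff(df$time_s))
  structure(list(
    sample_rate = sr,
    transmission = df$transmission,
    pulse_channel = if ("pulse_hz" %in% names(df)) df$pulse_hz else NULL,
    onsets = if (!is.null(meta)) meta$onsets else NULL,
    lock_break = if (!is.null(meta)) isTRUE(meta$lock_break) else FALSE,
    settle_time = if (!is.null(meta)) meta$settle_time else 0,
    metadata = if (!is.null(meta)) meta$metadata else list()
  ), class = "transmission_trace")
}

#' Write / read a sensor configuration
#'
#' YAML round-trip of a [sensor_settings()] bundle with sections `cavity`,
#' `lock`, `thermal`, `noise` plus the simulator fields (`response_gain`,
#' `dt`, `sample_rate`, `settle_time`).
#'
#' @param settings A [sensor_settings()].
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: the settings.
#' @export
write_config <- function(settings, path) {
  stopifnot(inherits(settings, "sensor_settings"))
  cfg <- list(cavity = unclass(settings$geom),
              lock = unclass(settings$lock),
              thermal = unclass(settings$thermal),
              noise = unclass(settings$noise),
              response_gain = settings$response_gain,
              dt = settings$dt, sample_rate = settings$sample_rate,
              settle_time = settings$settle_time)
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sensor_settings(
    geom = do.call(cavity_geometry, cfg$cavity),
    lock = do.call(lock_config, cfg$lock),
    thermal = do.call(thermal_config, cfg$thermal),
    noise = do.call(noise_config, cfg$noise),
    response_gain = cfg$response_gain, dt = cfg$dt,
    sample_rate = cfg$sample_rate, settle_time = cfg$settle_time
  )
}

#' Build a toy trace with a known event structure
#'
#' Deterministic-count synthetic trace used for testing and fixtures: a
#' noisy baseline with rectangular dips planted at given times; dips closer
#' than the clustering gap form one event. Returns the trace and the
#' ground-truth event count implied by the supplied gap rule.
#'
#' @param dip_times Dip onset times (s).
#' @param dip_width Dip width (s).
#' @param depth Dip floor (transmission value inside dips).
#' @param level Baseline level.
#' @param noise_sd Baseline noise.
#' @param duration Trace length (s).
#' @param sample_rate Sampling rate (Hz).
#' @param min_gap Clustering gap used to compute the ground truth (s).
#' @param seed Seed for the baseline noise.
#' @return List: `trace` (a `transmission_trace` with `settle_time = 0`),
#'   `n_events_truth`.
#' @export
#' @examples
#' toy <- toy_trace(c(1, 1.3, 3))
#' toy$n_events_truth  # first two dips merge: 2 events
toy_trace <- function(dip_times, dip_width = 0.02, depth = 0.1,
                      level = 0.9, noise_sd = 0.004, duration = NULL,
                      sample_rate = 1000, min_gap = 0.5, seed = 99) {
  set.seed(seed)
  if (is.null(duration)) duration <- max(dip_times) + 1
  n <- round(duration * sample_rate)
  x <- level + stats::rnorm(n, sd = noise_sd)
  for (t0 in dip_times) {
    i <- (round(t0 * sample_rate) + 1):round((t0 + dip_width) * sample_rate)
    i <- i[i >= 1 & i <= n]
    x[i] <- depth + stats::rnorm(length(i), sd = noise_sd)
  }
  # ground truth from the gap rule on the planted dip intervals
  dip_times <- sort(dip_times)
  gaps <- head(dip_times, -1) + dip_width
  n_truth <- if (length(dip_times)) 1 + sum(dip_times[-1] - gaps >= min_gap)
             else 0
  trace <- structure(list(sample_rate = sample_rate, transmission = x,
                          pulse_channel = NULL, onsets = NULL,
                          lock_break = FALSE, settle_time = 0,
                          metadata = list(seed = seed)),
                     class = "transmission_trace")
  list(trace = trace, n_events_truth = n_truth)
}

#' Generate deterministic test fixtures
#'
#' Writes a small set of plain-text assets with known answers: a toy trace
#' whose event count is encoded in its construction, a synthetic piezo scan
#' with a known Hz-per-volt conversion, and a calibration curve drawn from a
#' known sigmoid. Identical seeds give identical bytes.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths plus the ground truths.
#' @export
generate_fixtures <- function(seed = 1, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- toy_trace(c(1, 1.3, 3), seed = seed)
  trace_path <- file.path(dir, "toy_trace.csv")
  write_trace(toy$trace, trace_path)

  scan <- synthetic_piezo_scan(8e9, seed = seed + 1)
  scan_path <- file.path(dir, "piezo_scan.csv")
  utils::write.csv(data.frame(time_s = scan$times,
                              transmission = scan$transmission,
                              drive_voltage = scan$drive_voltage),
                   scan_path, row.names = FALSE)

  set.seed(seed + 2)
  a <- seq(5e6, 65e6, length.out = 13)
  a50 <- 30e6; s <- 5e6
  k <- stats::rbinom(length(a), 48, 1 / (1 + exp(-(a - a50) / s)))
  cal <- data.frame(amplitude_hz = a, n = 48, detected = k,
                    fraction = k / 48)
  cal_path <- file.path(dir, "calibration_curve.csv")
  utils::write.csv(cal, cal_path, row.names = FALSE)

  list(toy_trace = trace_path, piezo_scan = scan_path,
       calibration_curve = cal_path,
       truth = list(toy_events = toy$n_events_truth,
                    hz_per_volt = 8e9, a50 = a50, scale = s,
                    sideband_frequency = scan$sideband_frequency))
}
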