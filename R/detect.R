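#' Robust baseline estimate of a transmission trace
#'
#' Level and noise scale of the locked baseline, robust to the downward
#' spikes that detection events produce: the level is the median of the
#' samples above the 60th percentile, and sigma is the robust standard
#' deviation (1.4826 * MAD) of those same samples, rescaled by the Gaussian
#' truncation factor 0.533 so that for pure Gaussian baseline noise sigma
#' estimates the true noise standard deviation.
#'
#' @param trace A `transmission_trace` or numeric vector of transmission
#'   samples.
#' @return List with `level` and `sigma`.
#' @export
#' @examples
#' estimate_baseline(c(rep(0.8, 99), 0.1))
estimate_baseline <- function(trace) {
  x <- if (inherits(trace, "transmission_trace")) trace$transmission else trace
  if (length(x) < 2) stop("trace too short for baseline estimation",
                          call. = FALSE)
  upper <- x[x >= stats::quantile(x, 0.6, names = FALSE)]
  # 0.533: 1.4826*MAD of a standard normal truncated at its 60th percentile
  list(level = stats::median(upper),
       sigma = stats::mad(upper) / 0.533)
}

# samples of the analysis window (settling excluded) and its times
.analysis_window <- function(trace) {
  i0 <- if (inherits(trace, "transmission_trace"))
    floor(trace$settle_time * trace$sample_rate) + 1L else 1L
  i0
}

#' Detect transmission-drop events
#'
#' Thresholding plus burst clustering. Samples below
#' `level - drop_fraction * (level - floor)` (floor = trace minimum) mark
#' spikes; a noise guard keeps the threshold at least `noise_guard * sigma`
#' below the level so that blank traces yield essentially no spurious
#' spikes (burst drops are tens of sigma deep, so detection is insensitive
#' to the guard over a wide range). Runs of consecutive
#' sub-threshold samples are spikes; spikes merge into one detection event
#' unless they are separated by a contiguous dwell of at least `min_gap`
#' seconds at baseline — the 0.5-s independence rule. Baseline occupancy is
#' judged on a 10-ms moving average (above `level - 3 sigma`), so that
#' white detector noise cannot veto a genuine baseline dwell. The settling
#' window at the start of the trace is excluded.
#'
#' @param trace A `transmission_trace` (or numeric vector, assumed fully
#'   usable at `sample_rate`).
#' @param drop_fraction Fraction of the level-to-floor span a sample must
#'   drop to count as a spike; in (0, 1).
#' @param min_gap Minimum baseline dwell separating independent events (s).
#' @param noise_guard Minimum spike depth in units of the baseline sigma.
#' @param sample_rate Required when `trace` is a bare numeric vector.
#' @return data.frame of class `detection_events` with columns `start_time`,
#'   `end_time`, `minimum_transmission`, `spike_count`, and attribute
#'   `spike_minima` (list of per-spike minima per event) and `baseline`.
#' @export
#' @examples
#' x <- rep(0.8, 4000); x[1001:1010] <- 0.1; x[3001:3010] <- 0.12
#' detect_events(x, sample_rate = 1000)
detect_events <- function(trace, drop_fraction = 0.5, min_gap = 0.5,
                          noise_guard = 10, sample_rate = NULL) {
  if (inherits(trace, "transmission_trace")) {
    sr <- trace$sample_rate
    x <- trace$transmission
    i0 <- .analysis_window(trace)
  } else {
    if (is.null(sample_rate)) stop("sample_rate required for bare vectors",
                                   call. = FALSE)
    sr <- sample_rate
    x <- as.numeric(trace)
    i0 <- 1L
  }
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("drop_fraction must be in (0, 1)", call. = FALSE)
  empty <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      minimum_transmission = numeric(0),
                      spike_count = integer(0))
  if (length(x) - i0 + 1L < min_gap * sr) {
    warning("trace shorter than min_gap; no events reported")
    return(structure(empty, class = c("detection_events", "data.frame")))
  }
  xw <- x[i0:length(x)]
  bl <- estimate_baseline(xw)
  floor_level <- min(xw)
  thr <- bl$level - max(drop_fraction * (bl$level - floor_level),
                        noise_guard * bl$sigma)
  base_level <- bl$level - 3 * bl$sigma

  spike <- xw < thr
  if (!any(spike)) {
    out <- structure(empty, class = c("detection_events", "data.frame"))
    attr(out, "baseline") <- bl
    return(out)
  }
  r <- rle(spike)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sp_start <- starts[r$values]
  sp_end <- ends[r$values]
  n_sp <- length(sp_start)

  win <- max(1L, as.integer(round(0.01 * sr)))
  smooth <- if (win > 1L) {
    cs <- cumsum(c(0, xw))
    (cs[(win + 1L):(length(xw) + 1L)] - cs[1:(length(xw) - win + 1L)]) / win
  } else xw
  # align: smooth[i] covers xw[i .. i+win-1]; pad tail with last value
  at_base <- c(smooth, rep(smooth[length(smooth)], win - 1L)) >= base_level
  gap_steps <- as.integer(ceiling(min_gap * sr))
  # longest contiguous baseline dwell between consecutive spikes
  merge_prev <- logical(n_sp)
  if (n_sp > 1) {
    for (k in 2:n_sp) {
      seg <- at_base[(sp_end[k - 1] + 1L):(sp_start[k] - 1L)]
      longest <- if (length(seg)) max(0L, with(rle(seg), {
        runs <- lengths[values]
        if (length(runs)) max(runs) else 0L
      })) else 0L
      merge_prev[k] <- longest < gap_steps
    }
  }
  ev_id <- cumsum(!merge_prev)
  n_ev <- ev_id[n_sp]
  start_i <- vapply(seq_len(n_ev), function(e) sp_start[ev_id == e][1],
                    integer(1))
  end_i <- vapply(seq_len(n_ev), function(e) {
    idx <- which(ev_id == e)
    sp_end[idx[length(idx)]]
  }, integer(1))
  spike_minima <- lapply(seq_len(n_ev), function(e) {
    idx <- which(ev_id == e)
    vapply(idx, function(k) min(xw[sp_start[k]:sp_end[k]]), numeric(1))
  })
  out <- data.frame(
    start_time = (start_i + i0 - 2L) / sr,
    end_time = (end_i + i0 - 1L) / sr,
    minimum_transmission = vapply(spike_minima, min, numeric(1)),
    spike_count = as.integer(tabulate(ev_id, n_ev))
  )
  out <- structure(out, class = c("detection_events", "data.frame"))
  attr(out, "spike_minima") <- spike_minima
  attr(out, "baseline") <- bl
  out
}

#' Summarize detected events
#'
#' Event rate over the analysis window (settling excluded) and signal to
#' noise, `snr = (level - deepest event minimum) / sigma`. With no events
#' the SNR is `NA`; with a flat (sigma = 0) trace it is `Inf`.
#'
#' @param events A `detection_events` data.frame from [detect_events()].
#' @param trace The trace the events came from (for duration and baseline).
#' @return List of class `event_summary`: `n_events`, `duration`,
#'   `events_per_second`, `snr`.
#' @export
summarize_events <- function(events, trace) {
  if (inherits(trace, "transmission_trace")) {
    dur <- length(trace$transmission) / trace$sample_rate - trace$settle_time
    bl <- estimate_baseline(trace)
  } else {
    stop("summarize_events needs a transmission_trace", call. = FALSE)
  }
  bl_ev <- attr(events, "baseline")
  if (!is.null(bl_ev)) bl <- bl_ev  # settled-window baseline from detection
  n <- nrow(events)
  snr <- if (n == 0) NA_real_
         else if (bl$sigma == 0) Inf
         else (bl$level - min(events$minimum_transmission)) / bl$sigma
  structure(list(n_events = n, duration = dur,
                 events_per_second = n / dur, snr = snr),
            class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("%d events in %.2f s (%.3f /s), SNR %.1f\n",
              x$n_events, x$duration, x$events_per_second, x$snr))
  invisible(x)
}

#' Coefficient of variation of spike minima
#'
#' Saturation diagnostic of the burst regime: the per-spike minimum
#' transmission across all spikes in the supplied events. In the burst
#' regime, spikes saturate near a common floor, so the CV is small.
#'
#' @param events A `detection_events` data.frame (or a list of them, pooled).
#' @return List with `minima` (all per-spike minima) and `cv`
#'   (sd/mean of the minima).
#' @export
spike_depth_cv <- function(events) {
  evs <- if (inherits(events, "detection_events")) list(events) else events
  minima <- unlist(lapply(evs, function(e) unlist(attr(e, "spike_minima"))))
  if (length(minima) < 2) return(list(minima = minima, cv = NA_real_))
  list(minima = minima, cv = stats::sd(minima) / mean(minima))
}
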