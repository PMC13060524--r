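# Independent brute-force oracles used to cross-check the fast implementations.

# Plain-loop event segmentation: threshold, spike runs, 0.5-s baseline-dwell
# merging. Mirrors the detection CONTRACT, written as a direct scan so the
# two code paths share nothing but the definition.
oracle_events <- function(x, sr, drop_fraction = 0.5, min_gap = 0.5,
                          noise_guard = 10) {
  n <- length(x)
  upper <- x[x >= stats::quantile(x, 0.6, names = FALSE)]
  level <- stats::median(upper)
  sigma <- stats::mad(upper) / 0.533
  thr <- level - max(drop_fraction * (level - min(x)), noise_guard * sigma)
  base <- level - 3 * sigma
  win <- max(1L, as.integer(round(0.01 * sr)))

  # moving average of full windows, tail padded with the last full window
  n_full <- n - win + 1L
  sm <- numeric(n)
  for (i in seq_len(n_full)) sm[i] <- mean(x[i:(i + win - 1L)])
  if (win > 1L) sm[(n_full + 1L):n] <- sm[n_full]
  at_base <- sm >= base

  spike <- x < thr
  # spike runs by scanning
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (spike[i]) {
      j <- i
      while (j < n && spike[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(data.frame(start = integer(0), end = integer(0),
                                       spikes = integer(0)))
  gap_steps <- as.integer(ceiling(min_gap * sr))
  events <- list(cur = runs[[1L]], spikes = 1L)
  out <- NULL
  cur <- runs[[1L]]; spikes <- 1L
  if (length(runs) > 1L) for (k in 2:length(runs)) {
    lo <- runs[[k - 1L]][2L] + 1L
    hi <- runs[[k]][1L] - 1L
    longest <- 0L; run <- 0L
    if (hi >= lo) for (m in lo:hi) {
      if (at_base[m]) { run <- run + 1L; longest <- max(longest, run) }
      else run <- 0L
    }
    if (longest >= gap_steps) {
      out <- rbind(out, c(cur[1L], cur[2L], spikes))
      cur <- runs[[k]]; spikes <- 1L
    } else {
      cur[2L] <- runs[[k]][2L]
      spikes <- spikes + 1L
    }
  }
  out <- rbind(out, c(cur[1L], cur[2L], spikes))
  data.frame(start = out[, 1L], end = out[, 2L], spikes = out[, 3L])
}

# Random toy trace with planted rectangular dips (returns vector + truth info)
random_toy_trace <- function(sr = 200, duration = 30) {
  n <- round(sr * duration)
  x <- 0.9 + stats::rnorm(n, sd = 0.003)
  k <- sample(0:5, 1)
  if (k > 0) {
    onsets <- sort(stats::runif(k, 0.5, duration - 0.5))
    widths <- stats::runif(k, 0.01, 0.2)
    depths <- stats::runif(k, 0.05, 0.4)
    for (m in seq_len(k)) {
      i <- round(onsets[m] * sr):round((onsets[m] + widths[m]) * sr)
      i <- i[i >= 1 & i <= n]
      x[i] <- depths[m] + stats::rnorm(length(i), sd = 0.003)
    }
  }
  x
}

# Exhaustive two-sided permutation p-value by bitmask enumeration
oracle_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  obs <- abs(mean(b) - mean(a))
  idx <- utils::combn(n, na)
  stats <- apply(idx, 2, function(ii)
    abs(mean(pooled[-ii]) - mean(pooled[ii])))
  mean(stats >= obs - 1e-12 * (1 + obs))
}

# shared settings for simulator-based tests
test_settings <- function(...) burst_regime(...)
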