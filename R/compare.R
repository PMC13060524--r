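#' Exact permutation test on per-trace event counts
#'
#' Two-sided test of equal event rates between two conditions, using the
#' difference of mean per-trace counts as the statistic and permuting trace
#' labels (traces are the replicates, hence the exchangeable units). All
#' label assignments are enumerated when the two sides total at most
#' `enumerate_limit` traces; otherwise `n_resample` random permutations are
#' drawn (reproducibly). The observed assignment is always included, so
#' p >= 1/(number of permutations).
#'
#' @param counts_a,counts_b Integer event counts per trace (>= 2 traces per
#'   side).
#' @param enumerate_limit Full enumeration up to this total number of traces.
#' @param n_resample Number of random permutations beyond the limit.
#' @param perm_seed Seed for the resampled branch.
#' @return p-value in (0, 1\].
#' @export
#' @examples
#' rate_test(c(0, 0, 1), c(14, 11, 16))  # exact: 2/20 = 0.1
rate_test <- function(counts_a, counts_b, enumerate_limit = 10,
                      n_resample = 1e5, perm_seed = 421) {
  if (length(counts_a) < 2 || length(counts_b) < 2)
    stop("need at least 2 traces per condition", call. = FALSE)
  pooled <- c(counts_a, counts_b)
  n <- length(pooled)
  n_a <- length(counts_a)
  obs <- abs(mean(counts_b) - mean(counts_a))
  stat <- function(idx_a) abs(mean(pooled[-idx_a]) - mean(pooled[idx_a]))
  eps <- 1e-12 * (1 + obs)
  if (n <= enumerate_limit) {
    splits <- utils::combn(n, n_a)
    stats <- apply(splits, 2, stat)
    mean(stats >= obs - eps)
  } else {
    set.seed(perm_seed)
    hits <- 1L  # observed assignment counts
    for (i in seq_len(n_resample - 1L)) {
      if (stat(sample.int(n, n_a)) >= obs - eps) hits <- hits + 1L
    }
    hits / n_resample
  }
}

#' Significance category from a p-value
#'
#' Standard star annotation: `ns` for p > 0.05, `*` for p <= 0.05, `**` for
#' p <= 0.01, `***` for p <= 0.001, `****` for p <= 0.0001; the most
#' significant applicable bin wins and boundaries are inclusive.
#'
#' @param p p-value(s) in \[0, 1\]; vectorized.
#' @return Character vector of categories.
#' @export
#' @examples
#' star_rating(c(0.2, 0.05, 0.003, 2e-5))
star_rating <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must be in [0, 1]", call. = FALSE)
  vapply(p, function(pp) {
    if (pp <= 1e-4) "****"
    else if (pp <= 1e-3) "***"
    else if (pp <= 0.01) "**"
    else if (pp <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Run a two-species differentiation protocol
#'
#' Simulates the standard differentiation experiment at one pinned
#' sensitivity: blank water traces, then traces with analyte A, then analyte
#' B, then blank water again — all with identical sensor settings and trace
#' length (pinning the settings object across conditions is what rules out
#' sensitivity drift between conditions). Events are counted per trace and
#' the conditions compared with [rate_test()].
#'
#' @param settings A [sensor_settings()] (e.g. [burst_regime()]), shared by
#'   every condition.
#' @param analyte_a,analyte_b [analyte()] objects. `analyte_a = NULL` makes
#'   condition A a water blank (for null calibration).
#' @param concentration Analyte concentration (mol/L), same for both.
#' @param n_traces Analyte traces per condition.
#' @param n_water Water traces per blank block (>= 2 for testing).
#' @param trace_length Trace length (s); the experimental protocol uses 33 s.
#' @param seed Integer seed; per-trace seeds derive from it.
#' @param drop_fraction Passed to [detect_events()].
#' @return Object of class `comparison_result`: per-condition counts and
#'   rates, pairwise p-values and significance categories.
#' @export
run_protocol <- function(settings, analyte_a, analyte_b,
                         concentration = 10e-12, n_traces = 5, n_water = 3,
                         trace_length = 33, seed = 1, drop_fraction = 0.5) {
  stopifnot(inherits(settings, "sensor_settings"))
  env <- environment_conditions(concentration = concentration)
  drive_for <- function(an) if (is.null(an)) NULL else transit_program(env, an)
  conditions <- list(
    water_before = list(drive = NULL, n = n_water),
    a = list(drive = drive_for(analyte_a), n = n_traces),
    b = list(drive = drive_for(analyte_b), n = n_traces),
    water_after = list(drive = NULL, n = n_water)
  )
  counts <- list()
  off <- 0L
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    counts[[nm]] <- vapply(seq_len(cond$n), function(j) {
      tr <- simulate_trace(settings, cond$drive, duration = trace_length,
                           seed = seed + 7919L * (off + j))
      nrow(detect_events(tr, drop_fraction = drop_fraction))
    }, integer(1))
    off <- off + cond$n
  }
  dur <- trace_length - settings$settle_time
  rates <- vapply(counts, function(k) mean(k) / dur, numeric(1))
  water_all <- c(counts$water_before, counts$water_after)
  p <- c(
    a_vs_water = rate_test(water_all, counts$a),
    b_vs_water = rate_test(water_all, counts$b),
    a_vs_b = rate_test(counts$a, counts$b),
    water_before_vs_after = rate_test(counts$water_before,
                                      counts$water_after)
  )
  structure(list(
    labels = c("water-before",
               if (is.null(analyte_a)) "water (A)" else analyte_a$name,
               if (is.null(analyte_b)) "water (B)" else analyte_b$name,
               "water-after"),
    counts = counts,
    events_per_second = rates,
    trace_length = trace_length,
    p_values = p,
    categories = star_rating(p)
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("differentiation protocol:\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  %-14s counts [%s]  rate %.3f /s\n", x$labels[i],
                paste(x$counts[[i]], collapse = ", "),
                x$events_per_second[i]))
  for (i in seq_along(x$p_values))
    cat(sprintf("  %-22s p = %.4g  %s\n", names(x$p_values)[i],
                x$p_values[i], x$categories[i]))
  invisible(x)
}
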