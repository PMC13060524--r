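#' Analyte description
#'
#' Sensing-relevant parameters of a molecule: orientation-averaged excess
#' polarizability volume over the displaced water (alpha', in cubic
#' angstroms), hydrodynamic radius, and optionally the diffusion constant
#' (derived from the radius by [stokes_einstein_diffusion()] when absent).
#'
#' @param name Analyte label.
#' @param alpha_prime Excess polarizability volume (A^3, > 0 for detectable
#'   species).
#' @param hydrodynamic_radius Hydrodynamic radius R_h (m).
#' @param molecular_weight Molecular weight (Da), metadata only.
#' @param diffusion_constant Diffusion constant D (m^2/s); if `NULL`,
#'   derived from `hydrodynamic_radius` on demand.
#' @return Object of class `analyte`.
#' @export
#' @examples
#' trp <- analyte("tryptophan", alpha_prime = 25, hydrodynamic_radius = 0.38e-9)
analyte <- function(name, alpha_prime, hydrodynamic_radius,
                    molecular_weight = NA_real_, diffusion_constant = NULL) {
  if (!is.finite(alpha_prime) || alpha_prime <= 0)
    stop("alpha_prime must be positive (A^3)", call. = FALSE)
  if (!is.finite(hydrodynamic_radius) || hydrodynamic_radius <= 0)
    stop("hydrodynamic radius must be positive", call. = FALSE)
  if (!is.null(diffusion_constant) &&
      (!is.finite(diffusion_constant) || diffusion_constant <= 0))
    stop("diffusion constant must be positive when supplied", call. = FALSE)
  structure(list(name = name, alpha_prime = alpha_prime,
                 hydrodynamic_radius = hydrodynamic_radius,
                 molecular_weight = molecular_weight,
                 diffusion_constant = diffusion_constant),
            class = "analyte")
}

#' @export
print.analyte <- function(x, ...) {
  cat(sprintf("analyte '%s': alpha' = %.3g A^3, R_h = %.3g nm\n",
              x$name, x$alpha_prime, x$hydrodynamic_radius * 1e9))
  invisible(x)
}

#' Built-in analyte table
#'
#' Loads the packaged analyte parameter table. The excess-polarizability
#' values are order-of-magnitude placeholders spanning ~1-50 A^3 that respect
#' the expected ordering (glycine < alanine < threonine < histidine <
#' tryptophan < phospho-threonine < Myc-tag); they are configuration defaults,
#' not measured values, and should be replaced with computed alpha' values
#' when available. Glycine is listed at the IUPAC 75.07 Da.
#'
#' @param path Optional path to a user table with columns
#'   `name, molecular_weight_da, alpha_prime_A3, hydrodynamic_radius_nm`.
#' @return Named list of [analyte()] objects.
#' @export
#' @examples
#' tab <- default_analytes()
#' names(tab)
default_analytes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "analytes.csv", package = "ffpcsim")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "molecular_weight_da", "alpha_prime_A3",
            "hydrodynamic_radius_nm")
  if (!all(need %in% names(df)))
    stop("analyte table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    analyte(df$name[i], df$alpha_prime_A3[i],
            df$hydrodynamic_radius_nm[i] * 1e-9,
            molecular_weight = df$molecular_weight_da[i])
  })
  names(out) <- df$name
  out
}

#' Environmental conditions
#'
#' Temperature, solvent viscosity and analyte concentration for a simulated
#' experiment.
#'
#' @param temperature Absolute temperature (K).
#' @param viscosity Dynamic viscosity (Pa s); water at 20 C is about 1.0 mPa s.
#' @param concentration Analyte concentration (mol/L); experiments here run
#'   at picomolar levels, e.g. `5e-12`.
#' @return Object of class `environment_conditions`.
#' @export
environment_conditions <- function(temperature = 293, viscosity = 1.0e-3,
                                   concentration = 5e-12) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (viscosity <= 0) stop("viscosity must be positive", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  structure(list(temperature = temperature, viscosity = viscosity,
                 concentration = concentration),
            class = "environment_conditions")
}

#' Stokes-Einstein diffusion constant
#'
#' `D = k_B T / (6 pi eta R_h)` for a sphere of hydrodynamic radius R_h in a
#' solvent of viscosity eta.
#'
#' @param hydrodynamic_radius R_h (m).
#' @param env An [environment_conditions()].
#' @return Diffusion constant (m^2/s).
#' @export
#' @examples
#' stokes_einstein_diffusion(0.34e-9, environment_conditions())
stokes_einstein_diffusion <- function(hydrodynamic_radius,
                                      env = environment_conditions()) {
  if (!is.finite(hydrodynamic_radius) || hydrodynamic_radius <= 0)
    stop("hydrodynamic radius must be positive", call. = FALSE)
  ffpc_constants$k_B * env$temperature /
    (6 * pi * env$viscosity * hydrodynamic_radius)
}

# D for an analyte: explicit value wins, else Stokes-Einstein
analyte_diffusion <- function(an, env = environment_conditions()) {
  if (!is.null(an$diffusion_constant)) return(an$diffusion_constant)
  stokes_einstein_diffusion(an$hydrodynamic_radius, env)
}

#' Maximum single-molecule resonance shift
#'
#' First-order perturbative shift of the cavity resonance when a molecule of
#' excess polarizability volume alpha' sits at the mode center:
#' `|dnu_max| = 2 pi alpha' nu / (n^2 V)` with `nu = c/lambda` and alpha'
#' converted to m^3. Molecular presence raises the local refractive index and
#' red-shifts the resonance; the magnitude is what drives detection. The
#' ratio to the linewidth is exposed because it is the figure the mechanism
#' hinges on: for amino-acid-scale alpha' it is below 1e-5.
#'
#' @param an An [analyte()].
#' @param geom A [cavity_geometry()].
#' @param mode A [gaussian_mode()]; defaults to `gaussian_mode(geom)`.
#' @return List with `shift_hz` (magnitude of the peak shift, Hz) and
#'   `ratio` (shift / linewidth).
#' @export
#' @examples
#' peak_shift(analyte("x", 5, 0.3e-9), cavity_geometry())
peak_shift <- function(an, geom, mode = gaussian_mode(geom)) {
  stopifnot(inherits(an, "analyte"), inherits(geom, "cavity_geometry"))
  if (mode$mode_volume <= 0) stop("mode volume must be positive", call. = FALSE)
  nu <- ffpc_constants$c / geom$wavelength
  shift <- 2 * pi * (an$alpha_prime * .A3_to_m3) * nu /
    (geom$refractive_index^2 * mode$mode_volume)
  list(shift_hz = shift, ratio = shift / geom$linewidth)
}

#' Normalized mode intensity at a point
#'
#' Relative intensity of the fundamental Gaussian mode,
#' `I(rho, z) = (w0/w(z))^2 exp(-2 rho^2 / w(z)^2)` with
#' `w(z)^2 = w0^2 (1 + (z/zR)^2)`; unity at the mode center.
#'
#' @param position Numeric length-3 (x, y, z in m, z along the cavity axis)
#'   or an n x 3 matrix of positions.
#' @param mode A [gaussian_mode()].
#' @return Intensity in \[0, 1\] (vector for matrix input).
#' @export
#' @examples
#' mode_intensity(c(0, 0, 0), gaussian_mode(cavity_geometry()))
mode_intensity <- function(position, mode) {
  stopifnot(inherits(mode, "gaussian_mode"))
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  rho2 <- p[, 1]^2 + p[, 2]^2
  wz2 <- mode$waist^2 * (1 + (p[, 3] / mode$rayleigh_range)^2)
  out <- (mode$waist^2 / wz2) * exp(-2 * rho2 / wz2)
  if (is.matrix(position)) out else out[[1]]
}

#' Brownian trajectory
#'
#' Free 3-D Brownian motion on a uniform time grid: per-axis increments are
#' independent Gaussians with variance `2 D dt`, so the ensemble mean-squared
#' displacement is `6 D t`. Reproducible for a fixed seed.
#'
#' @param D Diffusion constant (m^2/s, >= 0).
#' @param dt Time step (s).
#' @param duration Total duration (s).
#' @param start Numeric length-3 starting position (m).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (callers embedding trajectories in a larger seeded simulation).
#' @return List of class `trajectory`: `times`, `positions` (n x 3 matrix),
#'   `seed`.
#' @export
#' @examples
#' tr <- brownian_trajectory(6e-10, 1e-5, 1e-3, c(0, 0, 0), seed = 1)
brownian_trajectory <- function(D, dt, duration, start = c(0, 0, 0),
                                seed = NULL) {
  if (D < 0 || dt <= 0 || duration <= 0)
    stop("require D >= 0, dt > 0, duration > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, as.integer(ceiling(duration / dt)) + 1L)
  steps <- matrix(stats::rnorm(3 * (n - 1), sd = sqrt(2 * D * dt)),
                  ncol = 3)
  pos <- rbind(start, sweep(apply(steps, 2, cumsum), 2, start, `+`))
  dimnames(pos) <- NULL
  structure(list(times = (seq_len(n) - 1) * dt, positions = pos,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "trajectory")
}

# uniform random point on a sphere of radius r (uses current RNG stream)
.runif_sphere <- function(r) {
  v <- stats::rnorm(3)
  r * v / sqrt(sum(v^2))
}

#' Molecular transit arrivals
#'
#' Homogeneous Poisson arrivals of molecules at the boundary of a spherical
#' sensing region around the mode waist. The arrival rate is the Smoluchowski
#' diffusive flux onto a sphere of radius R_s:
#' `lambda = 4 pi D R_s C N_A` with the concentration converted to molecules
#' per cubic metre, so the delivered count is linear in concentration. Each
#' arrival carries a uniformly random starting point on the sphere surface.
#'
#' @param env An [environment_conditions()] (supplies C, T, eta).
#' @param an An [analyte()].
#' @param sensing_radius Sensing-sphere radius R_s (m); the simulator default
#'   is `1.5 * w0`.
#' @param duration Observation time (s).
#' @param seed Optional integer seed.
#' @return List of class `transit_arrivals`: `times` (sorted arrival times,
#'   s), `starts` (n x 3 matrix of boundary points), `rate` (expected
#'   arrivals per second), `sensing_radius`.
#' @export
#' @examples
#' env <- environment_conditions(concentration = 5e-12)
#' trp <- analyte("trp", 25, 0.38e-9)
#' transit_arrivals(env, trp, 1.5e-6, duration = 1, seed = 1)$rate
transit_arrivals <- function(env, an, sensing_radius, duration, seed = NULL) {
  stopifnot(inherits(env, "environment_conditions"), inherits(an, "analyte"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (sensing_radius <= 0) stop("sensing radius must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  D <- analyte_diffusion(an, env)
  number_density <- env$concentration * 1e3 * ffpc_constants$N_A  # per m^3
  rate <- 4 * pi * D * sensing_radius * number_density
  n <- stats::rpois(1, rate * duration)
  times <- sort(stats::runif(n, 0, duration))
  starts <- if (n > 0) t(vapply(seq_len(n),
                                function(i) .runif_sphere(sensing_radius),
                                numeric(3)))
            else matrix(numeric(0), ncol = 3)
  structure(list(times = times, starts = starts, rate = rate,
                 sensing_radius = sensing_radius, diffusion_constant = D),
            class = "transit_arrivals")
}
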