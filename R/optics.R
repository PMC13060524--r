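#' Cavity geometry
#'
#' Physical description of a symmetric two-mirror fiber Fabry-Perot
#' microcavity (FFPC): mirror separation, mirror radius of curvature, the
#' refractive index of the medium filling the gap, pump wavelength, resonance
#' linewidth and input power.
#'
#' @param length Mirror separation L in metres. Must satisfy
#'   `0 < L < 2*roc` (stability of the symmetric resonator).
#' @param roc Radius of curvature of each mirror (m), symmetric cavity.
#' @param refractive_index Refractive index n of the intracavity medium
#'   (>= 1); water-filled cavities use 1.33.
#' @param wavelength Vacuum wavelength of the pump (m).
#' @param linewidth Resonance linewidth kappa, FWHM in Hz.
#' @param input_power Optical power injected into the cavity (W).
#'
#' @return Object of class `cavity_geometry`.
#' @export
#' @examples
#' geom <- cavity_geometry(length = 10e-6, roc = 33e-6)
#' cavity_figures(geom)
cavity_geometry <- function(length = 10e-6, roc = 33e-6,
                            refractive_index = 1.33,
                            wavelength = 640e-9,
                            linewidth = 250e6,
                            input_power = 50e-6) {
  if (!is.finite(length) || length <= 0)
    stop("cavity length must be positive", call. = FALSE)
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("wavelength must be positive", call. = FALSE)
  if (length >= 2 * roc)
    stop("unstable symmetric resonator: require L < 2*ROC", call. = FALSE)
  if (refractive_index < 1)
    stop("refractive index must be >= 1", call. = FALSE)
  if (!is.finite(linewidth) || linewidth <= 0)
    stop("linewidth must be positive", call. = FALSE)
  if (input_power < 0)
    stop("input power must be non-negative", call. = FALSE)
  structure(list(length = length, roc = roc,
                 refractive_index = refractive_index,
                 wavelength = wavelength, linewidth = linewidth,
                 input_power = input_power),
            class = "cavity_geometry")
}

#' @export
print.cavity_geometry <- function(x, ...) {
  cat("FFPC geometry:\n")
  cat(sprintf("  L = %.3g um, ROC = %.3g um, n = %.3f\n",
              x$length * 1e6, x$roc * 1e6, x$refractive_index))
  cat(sprintf("  lambda = %.1f nm, kappa = %.1f MHz, P_in = %.1f uW\n",
              x$wavelength * 1e9, x$linewidth / 1e6, x$input_power * 1e6))
  invisible(x)
}

#' Longitudinal mode number
#'
#' Resonance condition of a plane Fabry-Perot cavity: `m * lambda = 2 n L`,
#' so the (real-valued) longitudinal mode number is `m = 2 n L / lambda`.
#' The caller may round to the nearest integer and back-solve the length for
#' exact resonance.
#'
#' @param geom A [cavity_geometry()].
#' @return Real-valued mode number.
#' @export
#' @examples
#' mode_number(cavity_geometry(length = 10e-6))  # about 41.6
mode_number <- function(geom) {
  stopifnot(inherits(geom, "cavity_geometry"))
  2 * geom$refractive_index * geom$length / geom$wavelength
}

#' Cavity figures of merit
#'
#' Free spectral range, finesse, quality factor and photon lifetime of the
#' cavity: `fsr = c/(2 n L)`, `F = fsr/kappa`, `Q = (c/lambda)/kappa`,
#' `tau = Q/(2 pi nu)`. The identities `F * kappa = fsr` and (with the
#' real-valued mode number m) `Q = m * F` hold exactly.
#'
#' @param geom A [cavity_geometry()].
#' @return Object of class `cavity_figures` with fields `fsr`, `finesse`,
#'   `q_factor`, `mode_number`, `photon_lifetime`.
#' @export
#' @examples
#' cavity_figures(cavity_geometry(linewidth = 190e6))$finesse
cavity_figures <- function(geom) {
  stopifnot(inherits(geom, "cavity_geometry"))
  cc <- ffpc_constants$c
  fsr <- cc / (2 * geom$refractive_index * geom$length)
  nu <- cc / geom$wavelength
  q <- nu / geom$linewidth
  structure(list(
    fsr = fsr,
    finesse = fsr / geom$linewidth,
    q_factor = q,
    mode_number = mode_number(geom),
    photon_lifetime = q / (2 * pi * nu)
  ), class = "cavity_figures")
}

#' @export
print.cavity_figures <- function(x, ...) {
  cat(sprintf("FSR %.4g THz | finesse %.0f | Q %.3g | m %.2f | tau_ph %.3g ns\n",
              x$fsr / 1e12, x$finesse, x$q_factor, x$mode_number,
              x$photon_lifetime * 1e9))
  invisible(x)
}

#' Gaussian mode of a symmetric cavity
#'
#' Fundamental Gaussian mode of the symmetric two-mirror resonator. The waist
#' follows the standard closed form
#' `w0^2 = (L lambda / 2 pi) sqrt((2 ROC - L)/L)` with the vacuum wavelength
#' (this convention reproduces the ~19 um^3 mode volume of the typical
#' water-filled geometry; the in-medium convention gives ~15 um^3). The mode
#' volume uses the top-hat-equivalent cross section `V = (pi/4) w0^2 L`,
#' averaging out the standing-wave axial structure.
#'
#' @param geom A [cavity_geometry()].
#' @return Object of class `gaussian_mode` with fields `waist` (m),
#'   `mode_volume` (m^3), `rayleigh_range` (m).
#' @export
#' @examples
#' gaussian_mode(cavity_geometry())$mode_volume * 1e18  # um^3
gaussian_mode <- function(geom) {
  stopifnot(inherits(geom, "cavity_geometry"))
  L <- geom$length
  if (L >= 2 * geom$roc)
    stop("unstable geometry: L >= 2*ROC", call. = FALSE)
  lam <- geom$wavelength
  w0_sq <- (L * lam / (2 * pi)) * sqrt((2 * geom$roc - L) / L)
  w0 <- sqrt(w0_sq)
  structure(list(
    waist = w0,
    mode_volume = (pi / 4) * w0_sq * L,
    rayleigh_range = pi * w0_sq / lam
  ), class = "gaussian_mode")
}

#' @export
print.gaussian_mode <- function(x, ...) {
  cat(sprintf("Gaussian mode: w0 = %.3g um, V = %.3g um^3, zR = %.3g um\n",
              x$waist * 1e6, x$mode_volume * 1e18, x$rayleigh_range * 1e6))
  invisible(x)
}

#' Normalized cavity transmission lineshape
#'
#' Lorentzian transmission of the cavity versus pump-resonance detuning,
#' normalized to unit peak: `T = 1 / (1 + (2 delta / kappa)^2)`. At
#' `delta = kappa/2` the transmission is exactly 1/2 (FWHM definition).
#'
#' @param detuning Detuning delta of pump from cavity resonance (Hz);
#'   vectorized.
#' @param linewidth Linewidth kappa (FWHM, Hz).
#' @return Transmission in \[0, 1\].
#' @export
#' @examples
#' cavity_transmission(c(0, 125e6), 250e6)
cavity_transmission <- function(detuning, linewidth) {
  if (!is.finite(linewidth) || linewidth <= 0)
    stop("linewidth must be positive", call. = FALSE)
  x <- 2 * detuning / linewidth
  1 / (1 + x^2)
}

#' PDH error signal lineshape
#'
#' Dispersive Pound-Drever-Hall error signal in the high-modulation-frequency
#' limit, `e(delta) = x / (1 + x^2)^2` with `x = 2 delta / kappa`, normalized
#' to unit slope in x at resonance. Odd in delta, linear near the lock point,
#' decaying for |delta| >> kappa; the extremum sits at `delta = kappa/(2 sqrt 3)`.
#' The servo locks to `e = set point`; positive set points park the lock
#' slightly off the fringe top.
#'
#' @param detuning Detuning (Hz); vectorized.
#' @param linewidth Linewidth kappa (FWHM, Hz).
#' @return Dimensionless error-signal value.
#' @export
#' @examples
#' pdh_error(0, 250e6)            # zero at the lock point
#' pdh_error(125e6, 250e6)        # positive above resonance
pdh_error <- function(detuning, linewidth) {
  if (!is.finite(linewidth) || linewidth <= 0)
    stop("linewidth must be positive", call. = FALSE)
  x <- 2 * detuning / linewidth
  x / (1 + x^2)^2
}
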