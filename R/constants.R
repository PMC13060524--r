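#' Physical constants
#'
#' Centralized table of the physical constants the package uses, in SI units.
#'
#' @format Named list:
#' \describe{
#'   \item{c}{speed of light in vacuum (m/s)}
#'   \item{k_B}{Boltzmann constant (J/K)}
#'   \item{N_A}{Avogadro constant (1/mol)}
#'   \item{eps0}{vacuum permittivity (F/m)}
#' }
#' @export
#' @examples
#' ffpc_constants$c
ffpc_constants <- list(
  c    = 299792458,
  k_B  = 1.380649e-23,
  N_A  = 6.02214076e23,
  eps0 = 8.8541878128e-12
)

# unit helpers used throughout; angstrom^3 -> m^3 for polarizability volumes
.A3_to_m3 <- 1e-30
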