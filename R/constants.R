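#' Physical constants and unit conversions
#'
#' All internal energies are kcal/mol; coordinates are Angstrom. Restraint
#' force constants declared in kJ/mol/A^2 (the usual MD-engine convention)
#' are converted on input with 1 kcal = 4.184 kJ (thermochemical calorie).
#'
#' @format `fel_constants` is a named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant in kcal/mol/K, 0.0019872041}
#'   \item{kB_SI}{Boltzmann constant in J/K}
#'   \item{h_SI}{Planck constant in J s}
#'   \item{kJ_per_kcal}{4.184}
#'   \item{T_default}{physiological temperature, 310.15 K}
#' }
#' @export
fel_constants <- list(
  kB          = 0.0019872041,   # kcal mol^-1 K^-1
  kB_SI       = 1.380649e-23,   # J K^-1 (exact, SI 2019)
  h_SI        = 6.62607015e-34, # J s (exact, SI 2019)
  kJ_per_kcal = 4.184,
  T_default   = 310.15
)

#' Convert a force constant from kJ/mol/A^2 to kcal/mol/A^2
#'
#' @param k numeric, force constant(s) in kJ/mol/A^2.
#' @return numeric, same shape, in kcal/mol/A^2.
#' @examples
#' kj_to_kcal(200)  # ~47.80 kcal/mol/A^2, the standard umbrella restraint
#' @export
kj_to_kcal <- function(k) {
  stopifnot(is.numeric(k))
  k / fel_constants$kJ_per_kcal
}

#' @rdname kj_to_kcal
#' @export
kcal_to_kj <- function(k) {
  stopifnot(is.numeric(k))
  k * fel_constants$kJ_per_kcal
}

# thermal energy in kcal/mol at temperature T (K); internal helper
kT <- function(temperature) fel_constants$kB * temperature
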