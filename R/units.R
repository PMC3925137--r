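#' Physical constants and unit conversions
#'
#' All internal mechanics are carried in SI units; trajectory coordinates are
#' in angstrom and masses in dalton, converted at the boundaries through these
#' constants.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{Da}{One dalton in kg.}
#'   \item{A}{One angstrom in m.}
#'   \item{kcal_mol}{One kcal/mol in J (per molecule).}
#' }
#' @export
fm_constants <- list(
  kB       = 1.380649e-23,
  Da       = 1.66053906660e-27,
  A        = 1e-10,
  kcal_mol = 6.94769e-21
)

#' Thermal energy kB*T
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal energy in joule.
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  fm_constants$kB * temperature
}
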