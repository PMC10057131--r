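# Units used throughout the package: lengths in angstrom (A), energies in
# kcal/mol, temperatures in K, times in fs.

#' Boltzmann constant in kcal/(mol K)
#'
#' @return A single number, 0.0019872041 kcal/(mol K).
#' @export
#' @examples
#' boltzmann_constant() * 300  # RT at 300 K, ~0.596 kcal/mol
boltzmann_constant <- function() 0.0019872041

#' Thermal energy kB T
#'
#' @param temperature Temperature in K. Default 300 K, the thermostat
#'   temperature of the simulated aminoacylation system.
#' @return kB T in kcal/mol.
#' @export
thermal_energy <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  boltzmann_constant() * temperature
}

.default_temperature <- 300
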