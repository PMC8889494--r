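#' Physical constants and unit conventions
#'
#' The package works in a single internal unit system throughout:
#' lengths in Angstrom, energies in kcal/mol, charges in units of the
#' elementary charge e, number densities in 1/A^3 and temperatures in K.
#' Electrostatic energies are \code{COULOMB_KCAL * q1 * q2 / r}, matching
#' the convention of the Amber force-field ecosystem.
#'
#' @format \code{COULOMB_KCAL} is the Coulomb conversion constant in
#'   kcal A / (mol e^2); \code{BOLTZMANN_KCAL} is Boltzmann's constant in
#'   kcal / (mol K).
#' @name constants
NULL

#' @rdname constants
#' @export
COULOMB_KCAL <- 332.0522173

#' @rdname constants
#' @export
BOLTZMANN_KCAL <- 0.00198720425864083

#' Inverse temperature
#'
#' @param temperature temperature in K.
#' @return beta = 1/(kB T) in (kcal/mol)^-1.
#' @export
beta_of <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (BOLTZMANN_KCAL * temperature)
}
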