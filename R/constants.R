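#' Physical constants and units
#'
#' All energies are in kcal/mol, distances in angstrom (Å), times in ps,
#' temperatures in K and masses in amu. No unit conversion happens at API
#' boundaries; the single mechanical conversion factor used internally by the
#' Langevin integrator is exported as `KCAL_TO_AKMA`.
#'
#' @format
#' * `KB_KCAL`: Boltzmann constant, 0.0019872041 kcal/mol/K.
#' * `KBT_298`: kB T at the default temperature of 298.15 K,
#'   0.59248 kcal/mol (rounded to the conventional 5 significant digits when
#'   quoted in documentation; the exported value is the exact product).
#' * `KCAL_TO_AKMA`: 1 kcal/mol expressed in amu Å²/ps² (= 418.4), used to
#'   convert potential gradients into accelerations.
#'
#' @name constants
NULL

#' @rdname constants
#' @export
KB_KCAL <- 0.0019872041

#' @rdname constants
#' @export
DEFAULT_TEMPERATURE <- 298.15

#' @rdname constants
#' @export
KBT_298 <- KB_KCAL * DEFAULT_TEMPERATURE

#' @rdname constants
#' @export
KCAL_TO_AKMA <- 418.4

#' Thermal energy at a given temperature
#'
#' @param temperature Temperature in K.
#' @return kB T in kcal/mol.
#' @export
kBT <- function(temperature = DEFAULT_TEMPERATURE) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCAL * temperature
}
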