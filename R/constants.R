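#' Physical constants and unit conventions
#'
#' The package works in Angstrom (length), ns (time), kJ/mol (energy),
#' elementary charges (valence), mV (voltage), K (temperature) and pS
#' (conductance). All conversions go through this one table.
#'
#' @return Named list with elements \code{kB} (Boltzmann constant,
#'   kJ/mol/K), \code{e_C} (elementary charge, Coulomb), \code{e_mV}
#'   (energy of one elementary charge across 1 mV, kJ/mol) and
#'   \code{coulomb} (Coulomb prefactor in vacuum, kJ*A/mol/e^2).
#' @examples
#' ion_constants()$kB * 310  # thermal energy at 310 K, kJ/mol
#' @export
ion_constants <- function() {
  list(
    kB      = 0.0083144626,     # kJ/mol/K
    e_C     = 1.602176634e-19,  # C
    e_mV    = 0.0964853321233,  # kJ/mol per e*mV (Faraday / 1e6)
    coulomb = 1389.35457644     # kJ*A/mol/e^2, vacuum
  )
}

# internal shorthand
.kB <- 0.0083144626
.e_C <- 1.602176634e-19
.e_mV <- 0.0964853321233
.coulomb <- 1389.35457644
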