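# Physical constants and unit conversions used throughout the package.
# Internal unit system: length Angstrom, energy kcal/mol, charge e, time fs,
# mass amu, temperature K.

# Coulomb constant in kcal mol^-1 Angstrom e^-2
KCAL_COULOMB <- 332.0637

# 1 eV per particle expressed in kcal/mol (EEM chi/eta are tabulated in eV)
EV_TO_KCAL <- 23.0609

# 1 amu Angstrom^2 fs^-2 in kcal/mol (kinetic-energy conversion)
MASS_VEL2_TO_KCAL <- 2390.0574

# Boltzmann constant in kcal mol^-1 K^-1
KB_KCAL <- 0.0019872041

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Supported chemical elements
#'
#' The toolkit targets aqueous iron-sulfur chemistry and therefore supports
#' the four elements H, O, Fe and S.
#'
#' @format Character vector of element symbols.
#' @export
REAX_ELEMENTS <- c("H", "O", "Fe", "S")

# Reference atomic masses (amu); the ffield may override via its mass column.
REAX_MASSES <- c(H = 1.008, O = 15.999, Fe = 55.845, S = 32.06)
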