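## Physical constants used across the package.  Energies are kcal/mol,
## distances Angstrom, time ps (frame spacing) or ns (rates), unless noted.

## Coulomb conversion factor, kcal * Angstrom / (mol * e^2)
COULOMB_KCAL <- 332.0636

## Gas constant
R_KCAL <- 1.98720425e-3  # kcal / (mol K)
R_CAL  <- 1.98720425     # cal / (mol K)

## SI constants (CODATA), used by the entropy module
KB_SI     <- 1.380649e-23      # J / K
H_SI      <- 6.62607015e-34    # J s
NA_SI     <- 6.02214076e23     # 1 / mol
AMU_KG    <- 1.66053906660e-27 # kg
C_CM      <- 2.99792458e10     # cm / s
ATM_PA    <- 101325            # Pa
CAL_J     <- 4.184             # J / cal

## Conversion: eigenvalue of the mass-weighted Hessian in
## kcal mol^-1 A^-2 amu^-1  ->  angular frequency squared in s^-2
HESS_EIG_TO_OMEGA2 <- CAL_J * 1000 / (NA_SI * AMU_KG * 1e-20)

#' Package constants
#'
#' Returns the physical constants the package computes with, mainly so that
#' scripts and tests can reuse the exact values (Coulomb factor
#' 332.0636 kcal A mol^-1 e^-2, gas constant 1.98720425e-3 kcal mol^-1 K^-1,
#' and the SI set behind the entropy expressions).
#'
#' @return Named list of constants.
#' @export
endstate_constants <- function() {
  list(coulomb_kcal = COULOMB_KCAL, r_kcal = R_KCAL, r_cal = R_CAL,
       kb_si = KB_SI, h_si = H_SI, avogadro = NA_SI, amu_kg = AMU_KG,
       c_cm = C_CM, atm_pa = ATM_PA, cal_j = CAL_J)
}
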