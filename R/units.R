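# Internal unit system: kJ/mol, nm, ps, K. kcal/mol appears only at reporting.

#' Physical constants and unit conversions
#'
#' `kB_kj` is the molar Boltzmann (gas) constant in kJ/mol/K. `C0_nm3` is the
#' standard concentration 1/1660 A^-3 expressed in nm^-3, the 1 M reference
#' density entering standard-state binding free energies.
#'
#' @name units
#' @keywords internal
NULL

kB_kj <- 0.00831446261815324   # kJ/mol/K
C0_nm3 <- 1 / 1.660            # nm^-3  (= 1/1660 A^-3)
KJ_PER_KCAL <- 4.184

#' @param x energies in kJ/mol
#' @rdname units
#' @export
kj_to_kcal <- function(x) x / KJ_PER_KCAL

#' @param x_kcal energies in kcal/mol
#' @rdname units
#' @export
kcal_to_kj <- function(x_kcal) x_kcal * KJ_PER_KCAL

#' @param T_K temperature in kelvin
#' @return `kBT()`: thermal energy kB*T in kJ/mol.
#' @rdname units
#' @export
kBT <- function(T_K) kB_kj * T_K
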