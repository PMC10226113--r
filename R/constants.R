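# Physical constants and unit conversions.  All internal thermodynamic
# arithmetic is done in SI; conventional units (mN/m, A^2/molecule, mol/L,
# umol/m^2, kJ/mol) appear only at the interfaces, through these factors.

#' Physical constants used throughout the package
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R}{Molar gas constant, 8.314462618 J mol^-1 K^-1.}
#'   \item{N_A}{Avogadro constant, 6.02214076e23 mol^-1.}
#'   \item{mNm_A2_to_kJ_mol}{Work of compression unit: 1 (mN/m) x (A^2/molecule)
#'     expressed in kJ/mol (= 6.02214076e-3).}
#'   \item{A2_to_umol_m2}{Numerator converting an area per molecule S
#'     (A^2/molecule) into a surface density 1e26/(N_A * S) (umol/m^2).}
#' }
#' @export
fp_constants <- list(
  R = 8.314462618,
  N_A = 6.02214076e23,
  # 1 mN/m * A^2/molecule = 1e-3 N/m * 1e-20 m^2 = 1e-23 J/molecule
  mNm_A2_to_kJ_mol = 1e-23 * 6.02214076e23 / 1e3,
  A2_to_umol_m2 = 1e26 / 6.02214076e23
)

# Surface density Gamma_s [umol/m^2] from area per molecule S [A^2/molecule]
area_to_density <- function(S) fp_constants$A2_to_umol_m2 / S

# Area per molecule S [A^2/molecule] from surface density [umol/m^2]
density_to_area <- function(Gamma_s) fp_constants$A2_to_umol_m2 / Gamma_s
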