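#' Physical constants used throughout the package
#'
#' A single pinned location for the unit-conversion and Coulomb constants so
#' that every module (and every test) refers to the same values.
#'
#' * `hc_na_kcal_nm` — h·c·N_A expressed in kcal·nm·mol⁻¹ (28591.4, six
#'   significant figures, thermochemical calorie). Divides a wavelength in nm
#'   to give a photon energy per mole in kcal·mol⁻¹.
#' * `coulomb_kcal` — Coulomb constant k_e in kcal·Å·mol⁻¹·e⁻² (332.0636),
#'   the standard molecular-mechanics electrostatics prefactor.
#'
#' @format A named list with elements `hc_na_kcal_nm` and `coulomb_kcal`.
#' @export
#' @examples
#' chromotune_constants$hc_na_kcal_nm / 525 # photon energy at 525 nm
chromotune_constants <- list(
  hc_na_kcal_nm = 28591.4,
  coulomb_kcal  = 332.0636
)

# round half away from zero, so -1348.5 reports as -1349
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
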