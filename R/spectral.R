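#' Convert wavelength to wavenumber
#'
#' The energy scale native to vibrational and electronic spectroscopy:
#' a band at wavelength \eqn{\lambda} nm lies at \eqn{10^7/\lambda} cm\eqn{^{-1}}.
#'
#' @param lambda_nm Wavelength(s) in nm. Must be positive and finite.
#' @return Wavenumber(s) in cm\eqn{^{-1}}.
#' @export
#' @examples
#' nm_to_wavenumber(500) # 20000
nm_to_wavenumber <- function(lambda_nm) {
  check_positive_wavelength(lambda_nm)
  1e7 / lambda_nm
}

#' Convert wavenumber to wavelength
#'
#' @param wavenumber_cm Wavenumber(s) in cm\eqn{^{-1}}. Must be positive.
#' @return Wavelength(s) in nm.
#' @export
wavenumber_to_nm <- function(wavenumber_cm) {
  if (any(!is.finite(wavenumber_cm)) || any(wavenumber_cm <= 0)) {
    abort("`wavenumber_cm` must be positive and finite.",
          class = "chromotune_domain_error")
  }
  1e7 / wavenumber_cm
}

#' Convert wavelength to molar photon energy
#'
#' Uses the pinned constant `chromotune_constants$hc_na_kcal_nm`
#' (h·c·N_A = 28591.4 kcal·nm·mol⁻¹), the scale on which vertical excitation
#' energies of retinal chromophores are usually tabulated.
#'
#' @inheritParams nm_to_wavenumber
#' @return Energy in kcal·mol\eqn{^{-1}}.
#' @export
#' @examples
#' nm_to_kcalmol(525) # ~54.5 kcal/mol
nm_to_kcalmol <- function(lambda_nm) {
  check_positive_wavelength(lambda_nm)
  chromotune_constants$hc_na_kcal_nm / lambda_nm
}

check_positive_wavelength <- function(lambda_nm) {
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    abort("Wavelengths must be positive and finite.",
          class = "chromotune_domain_error")
  }
  invisible(lambda_nm)
}

#' Construct a table of absorption bands
#'
#' @param label Character vector of band labels (e.g. protein variants).
#' @param lambda_max Absorption maxima in nm, positive and finite.
#' @return A tibble with columns `label` and `lambda_max`.
#' @export
#' @examples
#' spectral_bands(c("KR2 WT", "P219T"), c(525, 542))
spectral_bands <- function(label, lambda_max) {
  check_positive_wavelength(lambda_max)
  stopifnot(length(label) == length(lambda_max))
  tibble(label = as.character(label), lambda_max = as.numeric(lambda_max))
}

#' Mutational spectral shift between two absorption bands
#'
#' Computes the wavelength and energy shift of a variant relative to a
#' reference. The wavenumber shift is
#' \eqn{10^7/\lambda_{variant} - 10^7/\lambda_{reference}}, so a red-shift
#' (longer wavelength) gives a negative wavenumber shift.
#'
#' @param reference,variant Absorption maxima in nm, or one-row tibbles as
#'   returned by [spectral_bands()].
#' @param reference_label,variant_label Labels used when plain numbers are
#'   supplied.
#' @return One-row tibble with `reference_label`, `variant_label`, `delta_nm`,
#'   `delta_wavenumber` (raw, cm\eqn{^{-1}}) and `delta_wavenumber_int`
#'   (rounded half away from zero, the convention under which -1348.5 reports
#'   as -1349).
#' @export
#' @examples
#' compute_shift(525, 542) # the P219T-like shift, about -597 cm^-1
compute_shift <- function(reference, variant,
                          reference_label = "reference",
                          variant_label = "variant") {
  ref <- as_band(reference, reference_label)
  var <- as_band(variant, variant_label)
  dnm <- var$lambda_max - ref$lambda_max
  dwn <- nm_to_wavenumber(var$lambda_max) - nm_to_wavenumber(ref$lambda_max)
  tibble(
    reference_label = ref$label,
    variant_label = var$label,
    delta_nm = dnm,
    delta_wavenumber = dwn,
    delta_wavenumber_int = round_half_away(dwn)
  )
}

as_band <- function(x, default_label) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, all(c("label", "lambda_max") %in% names(x)))
    list(label = x$label, lambda_max = x$lambda_max)
  } else {
    check_positive_wavelength(x)
    list(label = default_label, lambda_max = as.numeric(x))
  }
}

#' Shifts of every variant in a band table relative to one reference
#'
#' @param bands Tibble with columns `label`, `lambda_max` (nm); see
#'   [spectral_bands()] and [read_band_table()].
#' @param reference Label of the reference band (must appear in `bands`).
#' @return Tibble of shifts, one row per non-reference band, with the columns
#'   of [compute_shift()].
#' @export
shift_table <- function(bands, reference) {
  stopifnot(is.data.frame(bands), all(c("label", "lambda_max") %in% names(bands)))
  ref_row <- bands[bands$label == reference, ]
  if (nrow(ref_row) != 1) {
    abort(sprintf("Reference label '%s' must occur exactly once.", reference),
          class = "chromotune_consistency_error")
  }
  others <- bands[bands$label != reference, ]
  purrr::map_dfr(seq_len(nrow(others)), function(i) {
    compute_shift(ref_row, others[i, ])
  })
}

#' Additivity analysis of combined mutational shifts
#'
#' Tests whether the energy shift of a combined mutant equals the sum of its
#' single-mutant components, the signature of independently acting mutations
#' on the two ends of the chromophore.
#'
#' @param components Tibble of component shifts (rows from [compute_shift()]
#'   or [shift_table()]); at least two, all sharing one reference.
#' @param combined One-row tibble: the shift of the combined mutant, same
#'   reference.
#' @return One-row tibble with `n_components`, `predicted_sum` (sum of raw
#'   component wavenumber shifts, cm\eqn{^{-1}}), `predicted_sum_int` (sum of
#'   the integer-rounded components), `combined` (raw), `combined_int`, and
#'   `deviation` = combined - predicted_sum (raw cm\eqn{^{-1}}).
#' @export
#' @examples
#' b <- spectral_bands(c("WT", "P219T", "S254A", "double"),
#'                     c(525, 542, 545, 565))
#' s <- shift_table(b, "WT")
#' additivity(s[1:2, ], s[3, ])
additivity <- function(components, combined) {
  stopifnot(is.data.frame(components), is.data.frame(combined),
            nrow(combined) == 1)
  if (nrow(components) < 2) {
    abort("Need at least two component shifts.",
          class = "chromotune_consistency_error")
  }
  refs <- unique(c(components$reference_label, combined$reference_label))
  if (length(refs) != 1) {
    abort("All shifts must share the same reference.",
          class = "chromotune_consistency_error")
  }
  predicted <- sum(components$delta_wavenumber)
  predicted_int <- sum(components$delta_wavenumber_int)
  comb <- combined$delta_wavenumber
  comb_int <- combined$delta_wavenumber_int
  tibble(
    reference_label = refs,
    n_components = nrow(components),
    predicted_sum = predicted,
    predicted_sum_int = predicted_int,
    combined = comb,
    combined_int = comb_int,
    deviation = comb - predicted,
    deviation_int = comb_int - predicted_int
  )
}

#' Linear model linking the C=C stretch frequency to the absorption red-shift
#'
#' The retinal ethylenic stretch frequency \eqn{\nu_{C=C}} is linearly
#' anti-correlated with \eqn{\lambda_{max}}: the canonical calibration is a
#' 70 cm\eqn{^{-1}} downshift per 270 nm of red-shift, the default slope here.
#'
#' @param slope Downshift in cm\eqn{^{-1}} per nm of red-shift (> 0).
#' @param intercept Offset in cm\eqn{^{-1}}.
#' @return A list of class `cc_stretch_model`.
#' @export
cc_stretch_model <- function(slope = 70 / 270, intercept = 0) {
  if (!is.finite(slope) || slope <= 0) {
    abort("`slope` must be positive.", class = "chromotune_domain_error")
  }
  structure(list(slope = slope, intercept = intercept),
            class = "cc_stretch_model")
}

#' Predicted C=C stretch downshift for a given red-shift
#'
#' @param model A [cc_stretch_model()].
#' @param delta_nm Red-shift(s) of \eqn{\lambda_{max}} in nm (positive =
#'   red-shift).
#' @return Tibble with `delta_nm`, `downshift` (cm\eqn{^{-1}}, raw) and
#'   `downshift_int` (rounded half away from zero).
#' @export
#' @examples
#' predict_cc_downshift(cc_stretch_model(), c(17, 20, 270))
predict_cc_downshift <- function(model, delta_nm) {
  stopifnot(inherits(model, "cc_stretch_model"))
  raw <- model$slope * delta_nm + model$intercept
  tibble(delta_nm = delta_nm, downshift = raw,
         downshift_int = round_half_away(raw))
}

#' Read a band table from CSV
#'
#' Expects columns `label` and `lambda_max_nm` (or `lambda_max`).
#'
#' @param path CSV file path.
#' @return Tibble with columns `label`, `lambda_max` suitable for
#'   [shift_table()].
#' @export
read_band_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if ("lambda_max_nm" %in% names(x)) {
    x <- dplyr::rename(x, lambda_max = "lambda_max_nm")
  }
  spectral_bands(x$label, x$lambda_max)
}
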