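#' Tidy a global photocycle fit
#'
#' @param x A `photocycle_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted exponential: `term`, `estimate`
#'   (lifetime, s), `std.error`.
#' @export
tidy.photocycle_fit <- function(x, ...) {
  tibble(term = paste0("tau_", seq_len(nrow(x$lifetimes))),
         estimate = x$lifetimes$tau,
         std.error = x$lifetimes$se)
}

#' @rdname tidy.photocycle_fit
#' @return `glance()` returns a one-row model summary: `n_exponentials`,
#'   `residual_rms`, `turnover_time`, `converged`.
#' @export
glance.photocycle_fit <- function(x, ...) {
  tibble(n_exponentials = nrow(x$lifetimes),
         residual_rms = x$residual_rms,
         turnover_time = x$turnover_time,
         converged = x$converged)
}

#' Tidy a bleach-difference fit
#'
#' @param x A `bleach_fit`.
#' @param ... Unused.
#' @return One row per fitted parameter: `term`, `estimate`.
#' @export
tidy.bleach_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @rdname tidy.bleach_fit
#' @export
glance.bleach_fit <- function(x, ...) {
  tibble(fitted_lambda_max = x$fitted_lambda_max,
         fit_uncertainty = x$fit_uncertainty,
         window_lo = x$window[1], window_hi = x$window[2])
}

#' Tidy conjugation metrics into one long table
#'
#' @param x A `conjugation_metrics` object.
#' @param ... Unused.
#' @return Tibble with columns `quantity` (`bond_length`, `dihedral`,
#'   `distortion`, `bla`), `name`, `value`.
#' @export
tidy.conjugation_metrics <- function(x, ...) {
  bind_rows(
    tibble(quantity = "bond_length", name = x$bonds$bond,
           value = x$bonds$length),
    tibble(quantity = "dihedral", name = x$dihedrals$dihedral,
           value = x$dihedrals$angle),
    tibble(quantity = "distortion", name = x$dihedrals$dihedral,
           value = x$dihedrals$distortion),
    tibble(quantity = "bla", name = "BLA", value = x$bla)
  )
}
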