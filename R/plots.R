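#' Plot a transient-absorption matrix
#'
#' Heat map of \eqn{\Delta A(t, \lambda)} on a log time axis.
#'
#' @param object A `ta_data` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ta_data <- function(object, ...) {
  tidy.ta_data(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$wavelength,
                                 fill = .data$delta_A)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "time (s)", y = "wavelength (nm)",
                  fill = expression(Delta * A)) +
    ggplot2::theme_minimal()
}

#' Plot decay-associated spectra of a global photocycle fit
#'
#' @param object A `photocycle_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.photocycle_fit <- function(object, ...) {
  n <- nrow(object$lifetimes)
  tibble(
    component = rep(sprintf("tau = %.3g s", object$lifetimes$tau),
                    each = length(object$wavelengths)),
    wavelength = rep(object$wavelengths, times = n),
    amplitude = as.vector(t(object$das))
  ) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$wavelength, y = .data$amplitude,
                                 colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "wavelength (nm)", y = "DAS amplitude (AU)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bleach difference spectrum with its fitted band centre
#'
#' @param object A `bleach_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bleach_fit <- function(object, ...) {
  ggplot2::ggplot(object$difference,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$difference)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$fitted_lambda_max,
                        linetype = 2, colour = "red") +
    ggplot2::annotate("text", x = object$fitted_lambda_max, y = 0,
                      hjust = -0.1, vjust = -0.5, colour = "red",
                      label = sprintf("%.1f nm", object$fitted_lambda_max)) +
    ggplot2::labs(x = "wavelength (nm)", y = "after - before (AU)") +
    ggplot2::theme_minimal()
}

#' Bar chart of mutational wavenumber shifts
#'
#' @param shifts Tibble from [shift_table()] or rows of [compute_shift()].
#' @return A ggplot.
#' @export
plot_shift_table <- function(shifts) {
  ggplot2::ggplot(shifts,
                  ggplot2::aes(x = stats::reorder(.data$variant_label,
                                                  .data$delta_wavenumber),
                               y = .data$delta_wavenumber)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = expression(Delta * nu ~ (cm^-1))) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Bar chart of per-residue charge-off contributions
#'
#' @param contributions Tibble from [charge_off()] or
#'   [compare_charge_off()].
#' @return A ggplot.
#' @export
plot_charge_off <- function(contributions) {
  y <- if ("delta_contribution" %in% names(contributions)) {
    "delta_contribution"
  } else {
    "contribution"
  }
  p <- ggplot2::ggplot(contributions,
                       ggplot2::aes(x = factor(.data$residue_id),
                                    y = .data[[y]]))
  if ("classification" %in% names(contributions)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$classification))
  } else {
    p <- p + ggplot2::geom_col(fill = "steelblue")
  }
  p +
    ggplot2::labs(x = "residue", y = paste0(y, " (kcal/mol)")) +
    ggplot2::theme_minimal()
}
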