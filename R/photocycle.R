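# Gaussian absorption band evaluated on a wavelength grid; the band is
# Gaussian in the wavenumber domain, the physically natural shape for
# retinal-protein visible bands.
gaussian_band <- function(wavelength_nm, center_nm, width_wn, amplitude) {
  nu <- 1e7 / wavelength_nm
  nu0 <- 1e7 / center_nm
  amplitude * exp(-((nu - nu0)^2) / (2 * width_wn^2))
}

#' Sequential photocycle scheme
#'
#' An irreversible first-order chain of spectroscopic intermediates
#' (e.g. K -> K/L -> L/M -> O -> ground): each intermediate decays into the
#' next with lifetime `tau`, the last decay returning to the unphotolysed
#' ground state. Each intermediate and the ground state carry a Gaussian
#' (in wavenumber) absorption band.
#'
#' @param intermediates Tibble with columns `intermediate` (label), `tau`
#'   (lifetime, s, > 0), `center_nm`, `width_wn` (cm\eqn{^{-1}}), `amplitude`
#'   (AU).
#' @param ground List with `center_nm`, `width_wn`, `amplitude` for the
#'   ground-state band.
#' @return A list of class `photocycle_scheme`.
#' @export
photocycle_scheme <- function(intermediates, ground) {
  need <- c("intermediate", "tau", "center_nm", "width_wn", "amplitude")
  stopifnot(is.data.frame(intermediates), all(need %in% names(intermediates)),
            nrow(intermediates) >= 1)
  if (any(!is.finite(intermediates$tau) | intermediates$tau <= 0)) {
    abort("All lifetimes must be positive.", class = "chromotune_domain_error")
  }
  if (anyDuplicated(intermediates$intermediate)) {
    abort("Intermediate labels must be unique.",
          class = "chromotune_domain_error")
  }
  structure(list(intermediates = as_tibble(intermediates),
                 ground = ground),
            class = "photocycle_scheme")
}

#' KR2-like default photocycle scheme
#'
#' A four-intermediate K -> K/L -> L/M -> O chain with lifetimes
#' 30 us, 300 us, 1 ms and a configurable final ground-state-recovery
#' (turnover) lifetime, defaulting to the wild-type 4.8 ms. Band positions
#' follow the usual sodium-pump intermediate ordering (red-shifted K/O,
#' blue-shifted L/M); amplitudes are flash-photolysis-scale (peak
#' absorbance differences of a few times 0.01 AU).
#'
#' @param turnover Final (slowest) lifetime in seconds.
#' @param ground_center_nm Ground-state absorption maximum, nm.
#' @return A `photocycle_scheme`.
#' @export
kr2_scheme <- function(turnover = 4.8e-3, ground_center_nm = 525) {
  photocycle_scheme(
    intermediates = tibble(
      intermediate = c("K", "K/L", "L/M", "O"),
      tau = c(30e-6, 300e-6, 1e-3, turnover),
      center_nm = c(545, 535, 470, 600),
      width_wn = c(1600, 1600, 1700, 1500),
      amplitude = c(0.040, 0.040, 0.034, 0.046)
    ),
    ground = list(center_nm = ground_center_nm, width_wn = 1600,
                  amplitude = 0.040)
  )
}

#' Closed-form concentration profiles of a sequential photocycle
#'
#' Solves the irreversible first-order chain with unit initial population in
#' the first intermediate, using the classical sum-of-exponentials closed
#' form for distinct rates. Chains with (near-)degenerate rates (relative
#' rate gap below 1e-9) fall back to a matrix-exponential evaluation, where
#' the closed form is singular. The recovered-ground column completes the
#' mass balance: every row sums to 1.
#'
#' @param scheme A [photocycle_scheme()].
#' @param times Numeric vector of times (s), >= 0.
#' @return Tibble with column `time`, one column per intermediate, and
#'   `ground`.
#' @export
concentrations <- function(scheme, times) {
  stopifnot(inherits(scheme, "photocycle_scheme"))
  if (any(!is.finite(times) | times < 0)) {
    abort("Times must be finite and non-negative.",
          class = "chromotune_domain_error")
  }
  k <- 1 / scheme$intermediates$tau
  n <- length(k)
  degenerate <- n > 1 &&
    min(abs(outer(k, k, "-")[lower.tri(matrix(0, n, n))])) / max(k) < 1e-9
  conc <- if (degenerate) {
    conc_matrix_exp(k, times)
  } else {
    conc_bateman(k, times)
  }
  conc <- matrix(conc, nrow = length(times), ncol = n)
  out <- as_tibble(conc, .name_repair = "minimal")
  names(out) <- scheme$intermediates$intermediate
  out <- bind_cols(tibble(time = times), out)
  out$ground <- pmax(0, 1 - rowSums(conc))
  out
}

# Bateman cascade: c_i(t) = prod_{j<i} k_j * sum_{j<=i} exp(-k_j t) /
#                            prod_{l<=i, l!=j} (k_l - k_j)
conc_bateman <- function(k, times) {
  n <- length(k)
  sapply(seq_len(n), function(i) {
    pref <- if (i > 1) prod(k[seq_len(i - 1)]) else 1
    terms <- vapply(seq_len(i), function(j) {
      denom <- prod(k[setdiff(seq_len(i), j)] - k[j])
      if (i == 1) denom <- 1
      exp(-k[j] * times) / denom
    }, numeric(length(times)))
    pref * rowSums(matrix(terms, nrow = length(times)))
  })
}

conc_matrix_exp <- function(k, times) {
  n <- length(k)
  A <- matrix(0, n, n)
  diag(A) <- -k
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- k[1:(n - 1)]
  t(vapply(times, function(tt) {
    as.numeric(Matrix::expm(A * tt) %*% c(1, rep(0, n - 1)))
  }, numeric(n)))
}

#' Simulate a transient-absorption matrix
#'
#' Builds \eqn{\Delta A(t, \lambda) = \sum_i c_i(t)\,(\epsilon_i(\lambda) -
#' \epsilon_{ground}(\lambda))} from the photocycle forward model and adds
#' white Gaussian noise of standard deviation `noise_sigma / sqrt(n_averages)`,
#' emulating the averaging of repeated flash-photolysis traces.
#'
#' @param scheme A [photocycle_scheme()].
#' @param wavelengths Wavelength grid, nm.
#' @param times Time grid, s (log-spaced is the usual convention).
#' @param noise_sigma Single-shot noise standard deviation, AU.
#' @param n_averages Number of averaged traces (default 90).
#' @param seed Optional RNG seed for reproducibility.
#' @return A list of class `ta_data` with `wavelengths`, `times`, `delta_A`
#'   (time x wavelength matrix), `noise_sigma`, `n_averages`.
#' @export
simulate_ta <- function(scheme, wavelengths, times, noise_sigma = 0.002,
                        n_averages = 90, seed = NULL) {
  stopifnot(length(wavelengths) >= 1, length(times) >= 1)
  if (is.unsorted(times, strictly = TRUE)) {
    abort("Times must be strictly increasing.",
          class = "chromotune_domain_error")
  }
  conc <- concentrations(scheme, times)
  C <- as.matrix(conc[, scheme$intermediates$intermediate, drop = FALSE])
  g <- scheme$ground
  eps_g <- gaussian_band(wavelengths, g$center_nm, g$width_wn, g$amplitude)
  S <- t(apply(scheme$intermediates, 1, function(row) {
    gaussian_band(wavelengths, as.numeric(row[["center_nm"]]),
                  as.numeric(row[["width_wn"]]),
                  as.numeric(row[["amplitude"]])) - eps_g
  }))
  dA <- C %*% S
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    dA <- dA + matrix(rnorm(length(dA), sd = noise_sigma / sqrt(n_averages)),
                      nrow = nrow(dA))
  }
  structure(list(wavelengths = wavelengths, times = times, delta_A = dA,
                 noise_sigma = noise_sigma, n_averages = n_averages),
            class = "ta_data")
}

#' @export
print.ta_data <- function(x, ...) {
  cat(sprintf(
    "Transient absorption: %d times x %d wavelengths, dA range [%.3g, %.3g]\n",
    length(x$times), length(x$wavelengths), min(x$delta_A), max(x$delta_A)))
  invisible(x)
}

#' Tidy a transient-absorption matrix into long format
#'
#' @param x A `ta_data` object.
#' @param ... Unused.
#' @return Tibble with columns `time`, `wavelength`, `delta_A`.
#' @export
tidy.ta_data <- function(x, ...) {
  tidyr::expand_grid(time = x$times, wavelength = x$wavelengths) %>%
    mutate(delta_A = as.vector(t(x$delta_A)))
}

#' Rank-k SVD denoising of transient-absorption data
#'
#' Truncates the singular value decomposition of the \eqn{\Delta A} matrix at
#' rank `k`. Noiseless data from an m-intermediate sequential scheme has rank
#' m, so the discarded components are noise; the Frobenius norm of what is
#' removed equals exactly the root-sum-square of the discarded singular
#' values (Eckart-Young).
#'
#' @param data A `ta_data` object.
#' @param k Number of components kept (1 <= k <= min(dim)).
#' @return A `ta_data` object with the reconstructed matrix and two extra
#'   fields: `singular_values` (all of them) and `rank` (= k).
#' @export
svd_denoise <- function(data, k) {
  stopifnot(inherits(data, "ta_data"))
  kmax <- min(dim(data$delta_A))
  if (!is.numeric(k) || k < 1 || k > kmax) {
    abort(sprintf("`k` must lie in [1, %d].", kmax),
          class = "chromotune_domain_error")
  }
  s <- svd(data$delta_A)
  kk <- seq_len(k)
  rec <- s$u[, kk, drop = FALSE] %*%
    (s$d[kk] * t(s$v[, kk, drop = FALSE]))
  out <- data
  out$delta_A <- rec
  out$singular_values <- s$d
  out$rank <- k
  out
}

#' Global multi-exponential fit of transient-absorption data
#'
#' Fits \eqn{\Delta A(t, \lambda) = \sum_j a_j(\lambda) e^{-t/\tau_j}} with
#' lifetimes shared across all wavelengths, by variable projection: for any
#' trial set of lifetimes the per-wavelength amplitudes (the decay-associated
#' spectra) are obtained by linear least squares, and only the lifetimes are
#' iterated (Levenberg-Marquardt on log-lifetimes). The slowest fitted
#' lifetime is reported as the photocycle turnover time.
#'
#' @param data A `ta_data` object (optionally denoised with
#'   [svd_denoise()]).
#' @param n_exponentials Number of shared exponentials to fit.
#' @param initial_tau Optional vector of starting lifetimes (s); defaults to
#'   log-spaced values spanning the time grid.
#' @return A list of class `photocycle_fit` with `lifetimes` (tibble: `tau`,
#'   `se`, sorted ascending), `das` (n_exponentials x n_wavelength matrix of
#'   decay-associated spectra), `wavelengths`, `residual_rms`,
#'   `turnover_time`, `converged`, `message`.
#' @export
global_fit <- function(data, n_exponentials, initial_tau = NULL) {
  stopifnot(inherits(data, "ta_data"), n_exponentials >= 1)
  t <- data$times
  Y <- data$delta_A
  if (is.null(initial_tau)) {
    initial_tau <- exp(seq(log(max(min(t), 1e-12) * 3), log(max(t) / 3),
                           length.out = n_exponentials))
  }
  stopifnot(length(initial_tau) == n_exponentials, all(initial_tau > 0))

  design <- function(log_tau) exp(-outer(t, exp(-log_tau))) # exp(-t/tau)
  resid_fun <- function(log_tau) {
    Phi <- design(log_tau)
    A <- qr.coef(qr(Phi), Y)
    as.vector(Y - Phi %*% A)
  }
  fit <- minpack.lm::nls.lm(
    par = log(initial_tau), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$info %in% 1:4) {
    abort(paste0("Global fit did not converge: ", fit$message),
          class = "chromotune_fit_error",
          residual_trace = fit$rsstrace)
  }
  log_tau <- fit$par
  tau <- exp(log_tau)
  se_log <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_,
                                                                    length(tau)))
  se <- tau * se_log
  Phi <- design(log_tau)
  A <- qr.coef(qr(Phi), Y) # n_exp x n_wavelength: decay-associated spectra
  ord <- order(tau)
  res <- Y - Phi %*% A
  dup <- any(duplicated(round(log_tau[ord], 3)))
  if (dup) {
    warn("Fitted lifetimes contain near-duplicates; the model is likely over-parameterised.")
  }
  structure(list(
    lifetimes = tibble(tau = tau[ord], se = se[ord]),
    das = A[ord, , drop = FALSE],
    wavelengths = data$wavelengths,
    residual_rms = sqrt(mean(res^2)),
    turnover_time = max(tau),
    converged = TRUE,
    message = fit$message
  ), class = "photocycle_fit")
}

#' @export
print.photocycle_fit <- function(x, ...) {
  cat("Global photocycle fit:", nrow(x$lifetimes), "exponentials\n")
  cat("  lifetimes (s):",
      paste(sprintf("%.3g (+/- %.2g)", x$lifetimes$tau, x$lifetimes$se),
            collapse = ", "), "\n")
  cat(sprintf("  turnover %.3g s, residual RMS %.3g AU\n",
              x$turnover_time, x$residual_rms))
  invisible(x)
}

#' Ratio of photocycle turnover times
#'
#' @param a,b `photocycle_fit` objects; the ratio reported is
#'   `b$turnover_time / a$turnover_time` (variant over reference).
#' @return A single dimensionless number.
#' @export
turnover_ratio <- function(a, b) {
  stopifnot(inherits(a, "photocycle_fit"), inherits(b, "photocycle_fit"))
  if (!isTRUE(a$converged) || !isTRUE(b$converged)) {
    abort("Both fits must have converged.", class = "chromotune_fit_error")
  }
  if (a$turnover_time <= 0) {
    abort("Reference turnover time must be positive.",
          class = "chromotune_domain_error")
  }
  b$turnover_time / a$turnover_time
}

#' Write / read a transient-absorption matrix as CSV
#'
#' Layout: first column `time_s`, remaining columns named by wavelength in
#' nm.
#'
#' @param data A `ta_data` object.
#' @param path CSV file path.
#' @return `write_ta_csv` returns `path` invisibly; `read_ta_csv` returns a
#'   `ta_data` object.
#' @export
write_ta_csv <- function(data, path) {
  stopifnot(inherits(data, "ta_data"))
  df <- as.data.frame(data$delta_A)
  names(df) <- as.character(data$wavelengths)
  df <- cbind(time_s = data$times, df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' @rdname write_ta_csv
#' @export
read_ta_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  structure(list(
    wavelengths = as.numeric(names(x)[-1]),
    times = x$time_s,
    delta_A = unname(as.matrix(x[, -1])),
    noise_sigma = NA_real_, n_averages = NA_integer_
  ), class = "ta_data")
}
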