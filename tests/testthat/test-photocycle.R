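test_that("a single intermediate decays as a pure exponential", {
  sch <- photocycle_scheme(
    tibble::tibble(intermediate = "O", tau = 1, center_nm = 600,
                   width_wn = 1500, amplitude = 0.05),
    ground = list(center_nm = 525, width_wn = 1600, amplitude = 0.04)
  )
  t <- c(0, 0.5, 1, 2, 5)
  cc <- concentrations(sch, t)
  expect_equal(cc$O, exp(-t), tolerance = 1e-12)
  expect_equal(cc$O + cc$ground, rep(1, length(t)), tolerance = 1e-12)
})

test_that("mass is conserved at every time point for random chains", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    sch <- photocycle_scheme(
      tibble::tibble(intermediate = paste0("I", seq_len(n)),
                     tau = 10^runif(n, -5, -2), center_nm = 550,
                     width_wn = 1500, amplitude = 0.04),
      ground = list(center_nm = 525, width_wn = 1600, amplitude = 0.04)
    )
    cc <- concentrations(sch, 10^seq(-7, 0, length.out = 60))
    expect_equal(rowSums(as.matrix(cc[, -1])), rep(1, 60), tolerance = 1e-9)
    expect_true(all(as.matrix(cc[, -1]) >= -1e-12))
  }
})

test_that("closed form agrees with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  taus <- c(1e-3, 5e-3, 20e-3)
  sch <- photocycle_scheme(
    tibble::tibble(intermediate = c("A", "B", "C"), tau = taus,
                   center_nm = c(545, 500, 600), width_wn = 1500,
                   amplitude = 0.04),
    ground = list(center_nm = 525, width_wn = 1600, amplitude = 0.04)
  )
  times <- seq(0, 0.2, length.out = 101)
  k <- 1 / taus
  ode_fun <- function(t, y, parms) {
    list(c(-k[1] * y[1],
           k[1] * y[1] - k[2] * y[2],
           k[2] * y[2] - k[3] * y[3]))
  }
  num <- deSolve::ode(c(1, 0, 0), times, ode_fun, NULL,
                      rtol = 1e-10, atol = 1e-12)
  cc <- concentrations(sch, times)
  expect_equal(as.matrix(cc[, c("A", "B", "C")]),
               unname(num[, 2:4]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("degenerate (equal-rate) chains use the matrix-exponential path", {
  sch <- photocycle_scheme(
    tibble::tibble(intermediate = c("A", "B"), tau = c(1e-3, 1e-3),
                   center_nm = c(545, 600), width_wn = 1500,
                   amplitude = 0.04),
    ground = list(center_nm = 525, width_wn = 1600, amplitude = 0.04)
  )
  t <- c(0, 5e-4, 1e-3, 3e-3)
  cc <- concentrations(sch, t)
  k <- 1e3
  expect_equal(cc$A, exp(-k * t), tolerance = 1e-9)
  expect_equal(cc$B, k * t * exp(-k * t), tolerance = 1e-9) # t e^{-kt} law
  expect_error(
    photocycle_scheme(
      tibble::tibble(intermediate = "A", tau = -1, center_nm = 545,
                     width_wn = 1500, amplitude = 0.04),
      ground = list(center_nm = 525, width_wn = 1600, amplitude = 0.04)
    ),
    class = "chromotune_domain_error"
  )
})

test_that("simulated matrices are exact at zero noise and reproducible under seed", {
  wl <- seq(400, 650, length.out = 20)
  t <- 10^seq(-6, -1, length.out = 50)
  clean <- simulate_ta(kr2_scheme(), wl, t, noise_sigma = 0)
  a <- simulate_ta(kr2_scheme(), wl, t, seed = 5)
  b <- simulate_ta(kr2_scheme(), wl, t, seed = 5)
  expect_identical(a$delta_A, b$delta_A)
  expect_false(identical(a$delta_A, clean$delta_A))
  # the noise applied is sigma / sqrt(n_averages)
  big <- simulate_ta(kr2_scheme(), seq(400, 650, length.out = 60),
                     10^seq(-6, -1, length.out = 400),
                     noise_sigma = 0.002, n_averages = 90, seed = 9)
  big_clean <- simulate_ta(kr2_scheme(), seq(400, 650, length.out = 60),
                           10^seq(-6, -1, length.out = 400), noise_sigma = 0)
  expect_equal(sd(big$delta_A - big_clean$delta_A), 0.002 / sqrt(90),
               tolerance = 0.02)
})

test_that("SVD reconstruction obeys the rank and Eckart-Young identities", {
  wl <- seq(400, 650, length.out = 30)
  t <- 10^seq(-6, -1, length.out = 80)
  clean <- simulate_ta(kr2_scheme(), wl, t, noise_sigma = 0)
  den <- svd_denoise(clean, 4)
  sv <- den$singular_values
  # noiseless 4-intermediate data has rank 4
  expect_lt(sv[5] / sv[1], 1e-9)
  # full-rank reconstruction reproduces the input
  full <- svd_denoise(clean, min(dim(clean$delta_A)))
  expect_equal(full$delta_A, clean$delta_A, tolerance = 1e-12)
  # truncation error equals the Frobenius tail of discarded singular values
  noisy <- simulate_ta(kr2_scheme(), wl, t, noise_sigma = 0.002, seed = 2)
  for (k in c(1, 2, 4)) {
    d <- svd_denoise(noisy, k)
    tail_norm <- sqrt(sum(d$singular_values[-seq_len(k)]^2))
    expect_equal(norm(noisy$delta_A - d$delta_A, "F"), tail_norm,
                 tolerance = 1e-9)
  }
  expect_error(svd_denoise(clean, 0), class = "chromotune_domain_error")
  expect_error(svd_denoise(clean, 1000), class = "chromotune_domain_error")
})

test_that("global fit recovers a noiseless single-exponential lifetime exactly", {
  sch <- photocycle_scheme(
    tibble::tibble(intermediate = "O", tau = 4.8e-3, center_nm = 600,
                   width_wn = 1500, amplitude = 0.046),
    ground = list(center_nm = 525, width_wn = 1600, amplitude = 0.04)
  )
  ta <- simulate_ta(sch, seq(400, 650, length.out = 25),
                    10^seq(-5, -1, length.out = 80), noise_sigma = 0)
  fit <- global_fit(ta, 1)
  expect_equal(fit$lifetimes$tau, 4.8e-3, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-10)
  expect_equal(fit$turnover_time, fit$lifetimes$tau[1])
})

test_that("overfitting with an extra exponential is flagged or negligible", {
  sch <- photocycle_scheme(
    tibble::tibble(intermediate = c("A", "O"), tau = c(5e-4, 4.8e-3),
                   center_nm = c(545, 600), width_wn = 1500,
                   amplitude = c(0.04, 0.046)),
    ground = list(center_nm = 525, width_wn = 1600, amplitude = 0.04)
  )
  ta <- simulate_ta(sch, seq(400, 650, length.out = 25),
                    10^seq(-6, -1, length.out = 100),
                    noise_sigma = 0.002, seed = 31)
  fit <- suppressWarnings(global_fit(ta, 3))
  amp <- apply(abs(fit$das), 1, max)
  taus <- fit$lifetimes$tau
  gaps <- abs(diff(log(taus)))
  extra_negligible <- min(amp) < 0.05 * max(amp)
  duplicated_tau <- any(gaps < 0.2)
  expect_true(extra_negligible || duplicated_tau)
})

test_that("turnover ratios compare slowest lifetimes", {
  mk_fit <- function(turnover) {
    sch <- photocycle_scheme(
      tibble::tibble(intermediate = "O", tau = turnover, center_nm = 600,
                     width_wn = 1500, amplitude = 0.046),
      ground = list(center_nm = 525, width_wn = 1600, amplitude = 0.04)
    )
    ta <- simulate_ta(sch, seq(450, 650, length.out = 15),
                      10^seq(-5, 0, length.out = 60), noise_sigma = 0)
    global_fit(ta, 1)
  }
  wt <- mk_fit(4.8e-3)
  mut <- mk_fit(8.2e-3)
  expect_equal(turnover_ratio(wt, mut), 8.2 / 4.8, tolerance = 1e-4)
  expect_lt(turnover_ratio(wt, mut), 2)
  expect_equal(turnover_ratio(wt, wt), 1, tolerance = 1e-12)
  expect_equal(turnover_ratio(mk_fit(1e-3), mk_fit(3e-3)), 3,
               tolerance = 1e-4)
})

test_that("transient-absorption matrices round-trip through CSV", {
  ta <- simulate_ta(kr2_scheme(), seq(400, 650, length.out = 10),
                    10^seq(-6, -1, length.out = 20), noise_sigma = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ta_csv(ta, path)
  back <- read_ta_csv(path)
  expect_equal(back$delta_A, ta$delta_A, tolerance = 1e-12)
  expect_equal(back$wavelengths, ta$wavelengths)
  expect_equal(back$times, ta$times, tolerance = 1e-12)
})
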