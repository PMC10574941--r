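test_that("filter transfer functions satisfy H(0)=1, 0<=H<=1, monotone", {
  freqs <- seq(0, 0.5, length.out = 400)
  for (f in list(filter_spec(0.05), filter_spec(0.05, 0.02),
                 filter_spec(0.03, family = "gaussian_lowpass"))) {
    h <- filter_response(f, freqs)
    expect_identical(h[1], 1)
    expect_true(all(h >= 0 & h <= 1))
    expect_true(all(diff(h) <= 1e-12))
    expect_equal(filter_response(f, -freqs), h)  # even in f
  }
  expect_error(filter_spec(-1), "positive")
})

test_that("fft_filter is the identity for an all-pass filter and preserves
           constants for any filter", {
  fx <- pigment_fixture("chl_like", k = 10, seed = 5)
  s <- fx$test
  out <- fft_filter(s, identity_filter(s))
  expect_equal(out$intensity, s$intensity, tolerance = 1e-12)

  const <- spectrum(s$axis, rep(0.37, nrow(s)))
  filt <- fft_filter(const, filter_spec(0.001, 0.0005))
  expect_equal(filt$intensity, rep(0.37, nrow(s)), tolerance = 1e-12)
})

test_that("fft_filter is linear and obeys the Parseval variance identity on
           white noise", {
  n <- 16384
  ax <- seq_len(n)
  na <- synth_noise(n, 1e-4, seed = 21)$residual
  nb <- synth_noise(n, 2e-4, seed = 22)$residual
  f <- filter_spec(0.1, 0.05)
  fa <- fft_filter(spectrum(ax, na), f)$intensity
  fb <- fft_filter(spectrum(ax, nb), f)$intensity
  fab <- fft_filter(spectrum(ax, na + nb), f)$intensity
  expect_equal(fab, fa + fb, tolerance = 1e-12)

  h2 <- mean(filter_response(f, specderiv:::fft_freqs(n, 1))^2)
  expect_equal(var(fa) / var(na), h2, tolerance = 0.1)
})

test_that("spectral differentiation reproduces analytic derivatives of a
           smooth mixture for orders 1-8", {
  m <- oracle_mixture()
  s <- mixture_spectrum(m, oracle_axis(k = 8))
  for (n in 1:8) {
    d <- differentiate(s, n, method = "spectral")
    idx <- 26:230
    expect_lt(rel_rmse(d$value[idx], mixture_derivative(m, s$axis[idx], n)),
              1e-6)
  }
})

test_that("first derivative of a linear ramp is its slope (finite
           differences, interior)", {
  ax <- seq(0, 10, length.out = 64)
  d <- differentiate(spectrum(ax, 2 + 3 * ax), 1, method = "finite_difference")
  expect_equal(d$value[2:63], rep(3, 62), tolerance = 1e-10)
})

test_that("finite differences cross-check the spectral method at low order", {
  m <- oracle_mixture()
  s <- mixture_spectrum(m, oracle_axis(k = 10))
  d_fd <- differentiate(s, 2, method = "finite_difference")
  idx <- 103:922
  expect_lt(rel_rmse(d_fd$value[idx], mixture_derivative(m, s$axis[idx], 2)),
            5e-3)
})

test_that("orders above eight are refused with the precision rationale", {
  s <- mixture_spectrum(oracle_mixture(), oracle_axis())
  expect_error(differentiate(s, 9), "double precision")
  expect_error(differentiate(s, 0), "at least 1")
})

test_that("a single unsmoothed differentiation costs about two orders of
           magnitude in signal-to-noise", {
  fx <- pigment_fixture("chl_like", k = 12, noise_amplitude = 1e-4, seed = 8)
  snr0 <- max(fx$model$intensity) / sd(fx$noise$residual)
  d_noisy <- differentiate(fx$test, 1)$value
  d_clean <- differentiate(fx$model, 1)$value
  snr1 <- max(abs(d_clean)) / sd(d_noisy - d_clean)
  drop <- snr0 / snr1
  expect_gt(drop, 10)     # qualitative: differentiation is noise-amplifying
  expect_gt(snr1, 1)      # but one derivative is still usable
})

test_that("normalize_derivative scales to unit magnitude, idempotently,
           preserving signs", {
  s <- mixture_spectrum(oracle_mixture(), oracle_axis(k = 9))
  d <- differentiate(s, 3)
  nd <- normalize_derivative(d)
  expect_equal(max(abs(nd$value)), 1)
  expect_identical(sign(nd$value), sign(d$value))
  expect_equal(normalize_derivative(nd)$value, nd$value)
  zero <- specderiv:::new_derivative(1:8, rep(0, 8), 1)
  expect_error(normalize_derivative(zero), "all-zero")
})

test_that("derivative discrepancy is an RMSE over the trimmed central
           window", {
  s <- mixture_spectrum(oracle_mixture(), oracle_axis(k = 9))
  a <- normalize_derivative(differentiate(s, 8))
  expect_identical(derivative_discrepancy(a, a), 0)
  b <- specderiv:::new_derivative(a$axis, -a$value, 8L, normalized = TRUE)
  idx <- 52:461
  expect_equal(derivative_discrepancy(a, b),
               sqrt(mean((2 * a$value[idx])^2)), tolerance = 1e-12)
  short <- specderiv:::new_derivative(1:8, 1:8, 8L)
  expect_error(derivative_discrepancy(a, short), "shape error")
  wrong_order <- specderiv:::new_derivative(a$axis, a$value, 7L)
  expect_error(derivative_discrepancy(a, wrong_order), "same order")
})

test_that("sign_changes finds the crossings of a smooth derivative and
           ignores dead-band wiggle", {
  ax <- seq(-6, 6, length.out = 1024)
  m <- gaussian_mixture(1, 0, 2 * sqrt(2 * log(2)))  # sigma = 1
  d2 <- normalize_derivative(
    specderiv:::new_derivative(ax, mixture_derivative(m, ax, 2), 2L))
  sc <- sign_changes(d2, tol = 0.02, margin = 0.05)
  # second derivative of a Gaussian crosses zero at u = +/- 1
  expect_length(sc, 2)
  expect_equal(ax[sc], c(-1, 1), tolerance = 0.02)
})

test_that("the optimal-filter search hits a near-identity optimum on
           noiseless input", {
  fx <- pigment_fixture("chl_like", k = 12, seed = 1)
  sr <- find_optimal_filter(fx$model, fx$mixture, order = 8, seed = 2)
  expect_lt(sr$objective, 1e-4)
  # the recorded optimum objective is recomputable from its filter
  rec <- extract_derivative(fx$model, sr$best, 8)
  ref <- normalize_derivative(
    analytic_derivative(fx$mixture, fx$model$axis, 8))
  expect_equal(derivative_discrepancy(rec, ref), sr$objective,
               tolerance = 1e-10)
})

test_that("the search optimum is no worse than any traced candidate and a
           single-candidate grid is returned verbatim", {
  fx <- pigment_fixture("chl_like", k = 10, noise_amplitude = 1e-4, seed = 4)
  sr <- find_optimal_filter(fx$test, fx$mixture, order = 8, seed = 4)
  expect_true(all(sr$objective <= sr$trace$objective + 1e-15))

  one <- find_optimal_filter(fx$test, fx$mixture, order = 8,
                             space = list(cutoff = c(0.004, 0.004001)),
                             family = "gaussian_lowpass",
                             strategy = "grid", n_grid = 1)
  expect_equal(one$best$cutoff, 0.004, tolerance = 1e-3)
  expect_equal(nrow(one$trace), 1L)
  expect_error(
    find_optimal_filter(fx$test, fx$mixture, space = list(cutoff = c(2, 1))),
    "config error")
})

test_that("on noisy input the objective is high at both filtering extremes
           and the optimum is interior", {
  fx <- pigment_fixture("chl_like", k = 12, noise_amplitude = 1e-4, seed = 6)
  ref <- normalize_derivative(
    analytic_derivative(fx$mixture, fx$model$axis, 8))
  obj_at <- function(cutoff) {
    d <- differentiate(fx$test, 8, filter = filter_spec(cutoff, cutoff / 4))
    derivative_discrepancy(normalize_derivative(d), ref)
  }
  sr <- find_optimal_filter(fx$test, fx$mixture, order = 8, seed = 6)
  under <- obj_at(3e-4)   # over-smoothing: band structure destroyed
  over <- obj_at(0.2)     # under-smoothing: amplified noise dominates
  expect_gt(under, 5 * sr$objective)
  expect_gt(over, 5 * sr$objective)
  nyq <- 1 / (2 * (fx$test$axis[2] - fx$test$axis[1]))
  expect_gt(sr$best$cutoff, 3e-4)
  expect_lt(sr$best$cutoff, 0.5 * nyq)
})

test_that("extract_derivative applied with an absurdly low cutoff degrades
           the match monotonically at the endpoint", {
  fx <- pigment_fixture("chl_like", k = 10, noise_amplitude = 1e-4, seed = 9)
  sr <- find_optimal_filter(fx$test, fx$mixture, order = 8, seed = 9)
  ref <- normalize_derivative(
    analytic_derivative(fx$mixture, fx$test$axis, 8))
  broad <- extract_derivative(fx$test, filter_spec(2e-4, 1e-4), 8)
  expect_gt(derivative_discrepancy(broad, ref), sr$objective)
})
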