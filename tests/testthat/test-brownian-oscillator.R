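test_that("spectral density is odd, vanishes at zero, and matches the
           resonance closed form", {
  modes <- vibronic_modes(omega = c(1000, 350), gamma = c(100, 40),
                          huang_rhys = c(1, 0.3))
  expect_identical(spectral_density(modes, 0), 0)
  w <- seq(-3000, 3000, by = 7)
  expect_equal(spectral_density(modes, -w), -spectral_density(modes, w),
               tolerance = 1e-12)
  expect_true(all(spectral_density(modes, w[w > 0]) > 0))
  # single mode at resonance: C''(omega_j) = 2 S omega_j^2 / gamma_j
  one <- vibronic_modes(1000, 100, 1)
  expect_equal(spectral_density(one, 1000), 2 * 1 * 1000^2 / 100,
               tolerance = 1e-12)
})

test_that("reorganization energy equals the quadrature of C''(w)/w/pi", {
  expect_identical(reorganization_energy(vibronic_modes()), 0)
  expect_identical(reorganization_energy(vibronic_modes(100, 10, 1)), 100)
  modes <- vibronic_modes(omega = c(750, 1200), gamma = c(600, 90),
                          huang_rhys = c(0.5, 0.2))
  expect_equal(reorganization_energy(modes), lambda_quadrature(modes),
               tolerance = 1e-6)
})

test_that("lineshape function vanishes at t = 0 and for empty mode lists", {
  tg <- seq(0, 500, length.out = 64)
  g <- lineshape_g(vibronic_modes(750, 600, 0.5), 295, tg)
  expect_equal(g[1], 0 + 0i, tolerance = 1e-14)
  expect_true(all(Re(g) >= -1e-12))
  g0 <- lineshape_g(vibronic_modes(), 295, tg)
  expect_identical(g0, complex(real = numeric(64), imaginary = numeric(64)))
  expect_error(lineshape_g(vibronic_modes(750, 600, 0.5), -1, tg), "positive")
})

test_that("Im g grows linearly at long times with slope 2*pi*c*lambda", {
  modes <- vibronic_modes(750, 600, 0.5)
  tg <- seq(0, 2000, length.out = 512)
  g <- lineshape_g(modes, 295, tg)
  lam <- lambda_quadrature(modes)
  tail_i <- tg > 1000
  slope <- coef(lm(Im(g)[tail_i] ~ tg[tail_i]))[2]
  a <- 2 * pi * 2.99792458e-5          # cm^-1 -> rad/fs
  expect_equal(unname(slope), a * lam, tolerance = 0.01)
})

test_that("with no vibronic modes the spectrum is the closed-form Gaussian
           of the inhomogeneous FWHM on a 4096-point grid", {
  p <- mbo_params(vibronic_modes(), omega_eg = 15000, fwhm_inh = 300)
  s <- absorption_spectrum(p, sim_grid(k = 12))
  expect_equal(nrow(s), 4096)
  expect_lt(max(abs(s$intensity - gaussian_curve(s$axis, 15000, 300))), 1e-8)
})

test_that("the delta-function limit peaks at omega_eg within one grid step", {
  p <- mbo_params(vibronic_modes(), omega_eg = 15000, fwhm_inh = 1e-3)
  expect_warning(s <- absorption_spectrum(p, sim_grid(k = 10)), "truncation")
  grid <- sim_grid(k = 10)
  expect_lte(abs(s$axis[which.max(s$intensity)] - 15000), grid$dnu)
})

test_that("the frequency integral is invariant under inhomogeneous
           broadening (convolution conserves area)", {
  modes <- vibronic_modes(c(750, 1200), c(600, 120), c(0.5, 0.15))
  area <- vapply(c(50, 200, 600), function(fw) {
    s <- absorption_spectrum(mbo_params(modes, 15000, fw), sim_grid(k = 12),
                             normalize = FALSE)
    sum(s$intensity) * (s$axis[2] - s$axis[1])
  }, numeric(1))
  expect_equal(area[2] / area[1], 1, tolerance = 1e-6)
  expect_equal(area[3] / area[1], 1, tolerance = 1e-6)
})

test_that("doubling the time-domain extent leaves the peak-normalized
           spectrum unchanged (truncation convergence)", {
  p <- mbo_params(vibronic_modes(750, 600, 0.5), 15000, 250)
  s1 <- absorption_spectrum(p, sim_grid(k = 11))
  s2 <- absorption_spectrum(p, sim_grid(k = 12))   # same span, doubled t_max
  # the k+1 grid contains the k grid at every other point
  on_common <- approx(s2$axis, s2$intensity, xout = s1$axis)$y
  expect_lt(max(abs(on_common - s1$intensity), na.rm = TRUE), 1e-6)
})

test_that("parameter containers enforce their invariants", {
  expect_error(vibronic_modes(-5, 1, 1), "positive")
  expect_error(vibronic_modes(5, 0, 1), "positive")
  expect_error(vibronic_modes(5, 1, -0.1), "non-negative")
  expect_error(mbo_params(vibronic_modes(), omega_eg = -1), "positive")
  p <- mbo_params(vibronic_modes(), omega_eg = 15000, fwhm_inh = 300)
  expect_equal(p$temperature, 295)
  expect_equal(inhomogeneous_delta(p), 300 / (2 * sqrt(2 * log(2))))
})

test_that("MBO parameter files round-trip", {
  p <- mbo_params(vibronic_modes(c(750.123456789, 1200), c(600, 90),
                                 c(0.5, 0.25)),
                  omega_eg = 14803.21, fwhm_inh = 251.5, temperature = 288)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mbo_params(p, path)
  q <- read_mbo_params(path)
  expect_equal(q$modes$omega, p$modes$omega, tolerance = 1e-12)
  expect_equal(q$omega_eg, p$omega_eg, tolerance = 1e-12)
  expect_equal(q$temperature, 288)
})

test_that("differential evolution recovers one-mode model parameters from a
           self-generated target", {
  true_p <- mbo_params(vibronic_modes(750, 300, 0.6),
                       omega_eg = 14800, fwhm_inh = 250)
  target <- absorption_spectrum(true_p, sim_grid(k = 10))
  fit <- fit_mbo(target, n_modes = 1, grid = sim_grid(k = 10),
                 control = de_control(seed = 5, max_gen = 120, pop_size = 50))
  expect_lt(abs(fit$params$omega_eg - 14800), 10)
  expect_lt(fit$rmse, 1e-3)
  expect_equal(glance(fit)$seed, 5L)
})

test_that("zero-mode fit reduces to a Gaussian (omega_eg, FWHM) fit", {
  target <- absorption_spectrum(
    mbo_params(vibronic_modes(), omega_eg = 15000, fwhm_inh = 400),
    sim_grid(k = 9))
  fit <- fit_mbo(target, n_modes = 0, grid = sim_grid(k = 9),
                 control = de_control(seed = 3, max_gen = 60, pop_size = 30))
  expect_lt(abs(fit$params$omega_eg - 15000), 2)
  expect_lt(abs(fit$params$fwhm_inh - 400), 5)
})

test_that("per-mode bounds of the wrong arity are rejected", {
  target <- absorption_spectrum(
    mbo_params(vibronic_modes(), omega_eg = 15000, fwhm_inh = 400),
    sim_grid(k = 9))
  expect_error(
    fit_mbo(target, n_modes = 2,
            bounds = list(omega = list(c(100, 500))),
            control = de_control(max_gen = 1)),
    "config error")
})
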