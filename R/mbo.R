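#' Vibronic modes and multimode Brownian oscillator parameters
#'
#' Each vibronic mode couples a damped molecular vibration to the electronic
#' transition and is described by its frequency `omega` (cm^-1), relaxation
#' rate `gamma` (cm^-1) and dimensionless Huang-Rhys factor `huang_rhys`.
#' The full model adds the 0-0 electronic energy gap `omega_eg` (cm^-1),
#' the inhomogeneous (static-disorder) Gaussian FWHM `fwhm_inh` (cm^-1) and
#' the bath temperature (K).
#'
#' @param omega,gamma,huang_rhys Numeric vectors of equal length (recycled);
#'   `omega > 0`, `gamma > 0`, `huang_rhys >= 0`.
#' @return `vibronic_modes()`: a tibble with one row per mode.
#' @export
vibronic_modes <- function(omega = numeric(), gamma = numeric(),
                           huang_rhys = numeric()) {
  m <- tibble(omega = as.numeric(omega), gamma = as.numeric(gamma),
              huang_rhys = as.numeric(huang_rhys))
  if (nrow(m)) {
    if (any(m$omega <= 0)) abort("Mode frequencies must be positive.")
    if (any(m$gamma <= 0)) abort("Relaxation rates must be positive.")
    if (any(m$huang_rhys < 0)) abort("Huang-Rhys factors must be non-negative.")
  }
  m
}

#' @rdname vibronic_modes
#' @param modes A tibble of vibronic modes (possibly empty).
#' @param omega_eg Electronic 0-0 energy gap, cm^-1, positive.
#' @param fwhm_inh Inhomogeneous-broadening FWHM, cm^-1, non-negative.
#' @param temperature Bath temperature in kelvin; room temperature defaults
#'   to 295 K.
#' @return `mbo_params()`: an `mbo_params` list.
#' @export
mbo_params <- function(modes = vibronic_modes(), omega_eg, fwhm_inh = 0,
                       temperature = 295) {
  modes <- vibronic_modes(modes$omega, modes$gamma, modes$huang_rhys)
  if (omega_eg <= 0) abort("`omega_eg` must be positive.")
  if (fwhm_inh < 0) abort("`fwhm_inh` must be non-negative.")
  if (temperature <= 0) abort("`temperature` must be positive.")
  structure(list(modes = modes, omega_eg = as.numeric(omega_eg),
                 fwhm_inh = as.numeric(fwhm_inh),
                 temperature = as.numeric(temperature)),
            class = "mbo_params")
}

#' @export
print.mbo_params <- function(x, ...) {
  cat(sprintf(
    "Multimode Brownian oscillator model: %d mode(s), omega_eg = %g cm^-1,\n  inhomogeneous FWHM = %g cm^-1 (delta = %g), T = %g K\n",
    nrow(x$modes), x$omega_eg, x$fwhm_inh, inhomogeneous_delta(x), x$temperature))
  if (nrow(x$modes)) print(x$modes)
  invisible(x)
}

#' Derived inhomogeneous-broadening standard deviation (cm^-1)
#'
#' `delta = fwhm_inh / (2 sqrt(2 ln 2))`, the Gaussian sigma of the static
#' disorder distribution.
#'
#' @param p An `mbo_params` object.
#' @export
inhomogeneous_delta <- function(p) p$fwhm_inh * .fwhm_to_sigma

#' Spectral density of the vibronic modes
#'
#' Evaluates the multimode Brownian oscillator spectral density
#' \deqn{C''(\omega) = \sum_j \frac{2 S_j \omega_j^3 \omega \gamma_j}
#'   {(\omega_j^2-\omega^2)^2 + \omega^2\gamma_j^2},}
#' an odd function of frequency, in cm^-1 for cm^-1 input.
#'
#' @param modes A [vibronic_modes()] tibble.
#' @param omega Numeric frequencies (cm^-1); negative values allowed.
#' @return Numeric vector, same length as `omega`.
#' @examples
#' spectral_density(vibronic_modes(1000, 100, 1), 1000)  # 2*S*omega^2/gamma
#' @export
spectral_density <- function(modes, omega) {
  out <- numeric(length(omega))
  for (j in seq_len(nrow(modes))) {
    wj <- modes$omega[j]; gj <- modes$gamma[j]; sj <- modes$huang_rhys[j]
    out <- out + 2 * sj * wj^3 * omega * gj /
      ((wj^2 - omega^2)^2 + omega^2 * gj^2)
  }
  out
}

#' Reorganization energy of a mode set
#'
#' The diagnostic sum `lambda = sum_j S_j omega_j` (cm^-1), which also
#' equals `(1/pi) * integral of C''(w)/w over w > 0`.
#'
#' @inheritParams spectral_density
#' @return Scalar, cm^-1.
#' @export
reorganization_energy <- function(modes) {
  if (!nrow(modes)) return(0)
  sum(modes$huang_rhys * modes$omega)
}

#' Simulation grid for the lineshape Fourier transform
#'
#' The time and frequency records used by the half-range Fourier transform
#' contain `2^k` points. The time step is tied to the spectral span by
#' `dt = 1 / (span * c)` (c in cm/fs), so the returned frequency window has
#' width `span` centred on the electronic gap.
#'
#' @param k Grid exponent; `N = 2^k` points (default 12, i.e. 4096).
#' @param span Spectral window width in cm^-1 (default 20000).
#' @return A `sim_grid` list with `k`, `n`, `dt` (fs), `t_max` (fs),
#'   `dnu` (cm^-1) and `span`.
#' @export
sim_grid <- function(k = 12, span = 2e4) {
  if (k < 3 || k > 16) abort("`k` must be between 3 and 16.")
  if (span <= 0) abort("`span` must be positive.")
  n <- 2L^as.integer(k)
  dt <- 1 / (span * .c_cm_fs)
  structure(list(k = as.integer(k), n = n, dt = dt, t_max = n * dt,
                 dnu = span / n, span = span),
            class = "sim_grid")
}

# Quadrature of the lineshape function on a grid matched to the FFT:
# with nu_m = m*dnu, t_n = n*dt and 2*pi*c*dnu*dt = 2*pi/M the trig factors
# collapse to the DFT kernel, so both frequency integrals of g(t) are
# computed exactly on the grid by two length-M FFTs.
g_lineshape_fft <- function(modes, temperature, dt, n_t, m_fft = NULL) {
  m_fft <- m_fft %||% n_t
  if (m_fft < n_t) abort("FFT length must cover the time grid.")
  dnu <- 1 / (m_fft * dt * .c_cm_fs)
  t <- (seq_len(n_t) - 1) * dt
  if (!nrow(modes) || all(modes$huang_rhys == 0)) {
    return(complex(real = numeric(n_t), imaginary = numeric(n_t)))
  }
  nu <- (seq_len(m_fft) - 1) * dnu        # nu[1] = 0, handled analytically
  cw <- spectral_density(modes, nu)
  coth <- 1 / tanh(nu / (2 * .kB_cm * temperature))
  A <- B <- numeric(m_fft)
  A[-1] <- cw[-1] * coth[-1] / nu[-1]^2   # real-part integrand / (1 - cos)
  B[-1] <- cw[-1] / nu[-1]^2              # imag-part integrand / sin
  # omega -> 0 analytic limits (D-style regularisation of the 0/0 forms):
  # C''(w) ~ c0*w with c0 = sum 2 S g / w_j; coth ~ 2 kB T / w.
  c0 <- sum(2 * modes$huang_rhys * modes$gamma / modes$omega)
  # quadrature of (1/pi) int C''/nu dnu; the nu = 0 limit of C''/nu is c0
  lam_q <- dnu / pi * (0.5 * c0 + sum(cw[-1] / nu[-1]))
  ft <- fft(A, inverse = TRUE)[seq_len(n_t)]   # sum A_m exp(+2i pi m n / M)
  gt <- fft(B, inverse = TRUE)[seq_len(n_t)]
  re_g <- dnu / pi * (sum(A) - Re(ft)) +
    0.5 * dnu / pi * c0 * .kB_cm * temperature * (.two_pi_c * t)^2
  im_g <- -dnu / pi * Im(gt) + .two_pi_c * t * lam_q
  complex(real = re_g, imaginary = im_g)
}

#' Lineshape function g(t) of the Brownian oscillator bath
#'
#' Numerical quadrature of the temperature-dependent lineshape integral:
#' the real part integrates `(1 - cos wt)/w^2 * coth(hbar w / 2 kB T) * C''(w)`
#' and the imaginary part `-(sin wt - wt)/w^2 * C''(w)` over positive
#' frequencies (prefactor 1/pi after folding the even full-range integrand).
#' The `w -> 0` limits are substituted analytically. The frequency grid is
#' uniform with trapezoidal weights, matched to an FFT so `g` on long time
#' grids costs `O(M log M)`.
#'
#' @inheritParams spectral_density
#' @param temperature Kelvin, positive.
#' @param t_grid Uniform time grid starting at 0, in fs.
#' @param m_fft Quadrature/FFT length; defaults to the larger of the time
#'   grid length and 4096.
#' @return Complex vector `g(t)` on `t_grid`.
#' @export
lineshape_g <- function(modes, temperature, t_grid, m_fft = NULL) {
  if (temperature <= 0) abort("`temperature` must be positive.")
  if (length(t_grid) < 2 || abs(t_grid[1]) > 1e-12) {
    abort("`t_grid` must start at 0 and contain at least 2 points.")
  }
  dts <- diff(t_grid)
  if (diff(range(dts)) > 1e-9 * mean(dts)) abort("`t_grid` must be uniform.")
  m_fft <- m_fft %||% max(length(t_grid), 4096L)
  g_lineshape_fft(modes, temperature, dts[1], length(t_grid), m_fft)
}

#' Simulate the absorption spectrum of a pigment
#'
#' Half-range Fourier transform of the damped transition-dipole correlation
#' function:
#' \deqn{\sigma_{abs}(\omega) = \frac{1}{\pi}\,\mathrm{Re}\int_0^\infty
#'   dt\, e^{i(\omega-\Omega_{eg})t}\, e^{-g(t)}\, e^{-\Delta^2 t^2/2},}
#' evaluated by FFT on a `2^k` grid. With no vibronic modes this reduces in
#' closed form to a Gaussian of FWHM `fwhm_inh` centred at `omega_eg`.
#'
#' @param p An [mbo_params()] object.
#' @param grid A [sim_grid()]; its frequency window (centred on
#'   `p$omega_eg`) must cover the band.
#' @param normalize Normalize the output to unit peak (default `TRUE`).
#' @return A wavenumber [spectrum()] of `2^k` points.
#' @export
absorption_spectrum <- function(p, grid = sim_grid(), normalize = TRUE) {
  stopifnot(inherits(p, "mbo_params"), inherits(grid, "sim_grid"))
  n <- grid$n
  t <- (seq_len(n) - 1) * grid$dt
  # the quadrature grid for g is refined independently of the record length
  # so spectra computed at different k (time-domain extents) share the same
  # frequency discretisation of the spectral density
  g <- g_lineshape_fft(p$modes, p$temperature, grid$dt, n,
                       m_fft = max(n, 8192L))
  delta_ang <- inhomogeneous_delta(p) * .two_pi_c      # rad/fs
  envelope <- exp(-Re(g) - 0.5 * delta_ang^2 * t^2)
  tail_mag <- envelope[n]
  if (tail_mag > 1e-8) {
    warn(sprintf(
      "truncation: integrand envelope is %.2e at t_max = %g fs (> 1e-8); increase span or k.",
      tail_mag, grid$t_max))
  }
  f <- exp(-g - 0.5 * delta_ang^2 * t^2)
  f[1] <- 0.5 * f[1]                                   # trapezoidal endpoint
  sig <- grid$dt / pi * Re(fft(f, inverse = TRUE))
  idx <- seq_len(n) - 1L
  k_signed <- ifelse(idx < n / 2, idx, idx - n)
  nu <- p$omega_eg + k_signed * grid$dnu
  o <- order(nu)
  out <- spectrum(nu[o], sig[o], axis_unit = "wavenumber",
                  meta = list(model = "mbo", omega_eg = p$omega_eg,
                              fwhm_inh = p$fwhm_inh,
                              temperature = p$temperature,
                              n_modes = nrow(p$modes), k = grid$k,
                              span = grid$span))
  if (normalize) normalize_peak(out) else out
}

#' Fit multimode Brownian oscillator parameters to a target spectrum
#'
#' Seeded differential evolution over `(omega_eg, fwhm_inh)` plus
#' `(omega, gamma, huang_rhys)` per mode, minimizing the RMSE between the
#' peak-normalized simulated spectrum (interpolated onto the target axis)
#' and the target, followed by a bounded local polish.
#'
#' @param target A peak-normalized wavenumber spectrum on a uniform grid.
#' @param n_modes Number of vibronic modes to fit (0 gives a pure Gaussian).
#' @param bounds Named list of length-2 intervals: `omega_eg`, `fwhm_inh`,
#'   and (when `n_modes > 0`) `omega`, `gamma`, `huang_rhys`. Either one
#'   interval shared by all modes or a list of per-mode intervals.
#' @param temperature Bath temperature held fixed during the fit.
#' @param grid [sim_grid()] used for simulation during the fit.
#' @param control A [de_control()]; the seed governs all randomness.
#' @param polish Run the local polish after DE (default `TRUE`).
#' @return An `mbo_fit` object: `params` ([mbo_params()]), `rmse`,
#'   `history`, `evaluations`, `seed`.
#' @export
fit_mbo <- function(target, n_modes = 1, bounds = NULL, temperature = 295,
                    grid = sim_grid(k = 10), control = de_control(),
                    polish = TRUE) {
  target <- as_spectrum(target)
  if (axis_unit(target) != "wavenumber") abort("`target` must be in wavenumber units.")
  axis_step(target)
  win <- range(target$axis)
  bounds <- bounds %||% list()
  b_eg <- bounds$omega_eg %||% win
  b_fw <- bounds$fwhm_inh %||% c(10, diff(win))
  lower <- c(b_eg[1], b_fw[1]); upper <- c(b_eg[2], b_fw[2])
  as_per_mode <- function(b, default) {
    b <- b %||% default
    if (is.list(b)) {
      if (length(b) != n_modes) abort("Per-mode bounds must match `n_modes` (config error).")
      b
    } else rep(list(b), n_modes)
  }
  if (n_modes > 0) {
    bo <- as_per_mode(bounds$omega, c(50, 2500))
    bg <- as_per_mode(bounds$gamma, c(10, 2000))
    bs <- as_per_mode(bounds$huang_rhys, c(0, 2))
    for (j in seq_len(n_modes)) {
      lower <- c(lower, bo[[j]][1], bg[[j]][1], bs[[j]][1])
      upper <- c(upper, bo[[j]][2], bg[[j]][2], bs[[j]][2])
    }
  }
  tgt <- target$intensity / max(target$intensity)
  unpack <- function(par) {
    modes <- if (n_modes > 0) {
      i <- 2 + 3 * (seq_len(n_modes) - 1)
      vibronic_modes(pmax(par[i + 1], 1e-6), pmax(par[i + 2], 1e-6),
                     pmax(par[i + 3], 0))
    } else vibronic_modes()
    mbo_params(modes, omega_eg = par[1], fwhm_inh = max(par[2], 0),
               temperature = temperature)
  }
  objective <- function(par) {
    p <- tryCatch(unpack(par), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    sim <- suppressWarnings(absorption_spectrum(p, grid, normalize = TRUE))
    y <- approx(sim$axis, sim$intensity, xout = target$axis, rule = 2)$y
    sqrt(mean((y - tgt)^2))
  }
  res <- de_minimize(objective, lower, upper, control)
  if (polish) {
    pol <- polish_minimize(objective, res$par, lower, upper)
    res$par <- pol$par
    res$value <- pol$value
  }
  structure(list(params = unpack(res$par), rmse = res$value,
                 history = res$history, evaluations = res$evaluations,
                 seed = res$seed, n_modes = n_modes),
            class = "mbo_fit")
}

#' @export
print.mbo_fit <- function(x, ...) {
  cat(sprintf("MBO fit: %d mode(s), RMSE = %.3e (%d objective evaluations, seed %d)\n",
              x$n_modes, x$rmse, x$evaluations, x$seed))
  print(x$params)
  invisible(x)
}

#' Read/write MBO parameter files
#'
#' Structured key-value (YAML) documents listing the modes and scalar
#' parameters, serialized with 16 significant digits so files round-trip.
#'
#' @param p An `mbo_params` object.
#' @param path File path.
#' @return `write_mbo_params()` returns `path` invisibly;
#'   `read_mbo_params()` returns an `mbo_params` object.
#' @export
write_mbo_params <- function(p, path) {
  stopifnot(inherits(p, "mbo_params"))
  doc <- list(
    modes = if (nrow(p$modes)) purrr::transpose(as.list(p$modes)) else list(),
    omega_eg = p$omega_eg, fwhm_inh = p$fwhm_inh, temperature = p$temperature)
  writeLines(yaml::as.yaml(doc, precision = 16), path)
  invisible(path)
}

#' @rdname write_mbo_params
#' @export
read_mbo_params <- function(path) {
  doc <- yaml::read_yaml(path)
  modes <- if (length(doc$modes)) {
    vibronic_modes(
      omega = map_dbl(doc$modes, "omega"),
      gamma = map_dbl(doc$modes, "gamma"),
      huang_rhys = map_dbl(doc$modes, "huang_rhys"))
  } else vibronic_modes()
  mbo_params(modes, omega_eg = doc$omega_eg, fwhm_inh = doc$fwhm_inh,
             temperature = doc$temperature %||% 295)
}
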