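#' Synthetic pigment-like fixtures
#'
#' Ready-made Gaussian mixtures and test spectra emulating the four studied
#' pigment classes: chlorophyll- and bacteriochlorophyll-like Qy bands
#' (3 Gaussians in the 12,000-17,000 cm^-1 window) and carotenoid-like
#' S0->S2 bands with a vibronic progression (5 Gaussians in
#' 18,000-26,000 cm^-1). The mixtures are *synthetic stand-ins* — plausible
#' band positions, widths and amplitudes for each pigment class, not fitted
#' values for any real sample — with the dominant band normalized to
#' 1.0 optical units and a white-noise track of amplitude 1e-4 o.u.
#' overlaid, matching the signal-to-noise of a modern spectrophotometer.
#'
#' @param name One of `"chl_like"`, `"bchl_like"`, `"spheroidene_like"`,
#'   `"spheroidenone_like"`.
#' @return `pigment_mixture()`: a [gaussian_mixture()];
#'   `pigment_window()`: the length-2 wavenumber window (cm^-1).
#' @export
pigment_mixture <- function(name = c("chl_like", "bchl_like",
                                     "spheroidene_like", "spheroidenone_like")) {
  name <- match.arg(name)
  # Band positions keep every component >~ 5-7 sigma inside the class
  # window: an FFT treats the record as periodic, and an eighth derivative
  # amplifies any edge discontinuity, so the synthetic bands must decay to
  # numerical zero before the window edges (the same edge-effect concern
  # that motivates centring the measured peak).
  switch(name,
    # Qy 0-0 band, a vibronic satellite and a high-energy shoulder
    chl_like = gaussian_mixture(
      amplitude = c(1.0, 0.25, 0.10),
      center = c(14550, 15150, 15750),
      fwhm = c(380, 600, 380)),
    bchl_like = gaussian_mixture(
      amplitude = c(1.0, 0.25, 0.08),
      center = c(13300, 13950, 14600),
      fwhm = c(450, 650, 450)),
    # S0->S2 vibronic progression, ~1200 cm^-1 spacing
    spheroidene_like = gaussian_mixture(
      amplitude = c(0.75, 1.0, 0.80, 0.38, 0.14),
      center = c(19600, 20800, 22000, 23200, 24300),
      fwhm = c(800, 900, 1000, 1050, 900)),
    spheroidenone_like = gaussian_mixture(
      amplitude = c(0.80, 1.0, 0.70, 0.32, 0.12),
      center = c(19500, 20750, 22000, 23250, 24400),
      fwhm = c(900, 1000, 1100, 1150, 950)))
}

#' @rdname pigment_mixture
#' @export
pigment_window <- function(name = c("chl_like", "bchl_like",
                                    "spheroidene_like", "spheroidenone_like")) {
  name <- match.arg(name)
  if (name %in% c("chl_like", "bchl_like")) c(12000, 17000) else c(18000, 26000)
}

#' Build a pigment-like test fixture
#'
#' Samples the class mixture on a `2^k` wavenumber grid over the class
#' window, normalizes the peak to 1.0 o.u., and overlays seeded white noise
#' of the given amplitude. The noiseless model samples, the mixture and the
#' noise track are returned alongside the test spectrum so recovery can be
#' scored against exact ground truth.
#'
#' @inheritParams pigment_mixture
#' @param k Grid exponent (default 12, i.e. 4096 samples).
#' @param noise_amplitude Noise standard deviation, o.u. (default 1e-4).
#' @param seed Integer seed for the noise.
#' @return A list: `mixture`, `model` (noiseless spectrum), `test` (noisy
#'   spectrum), `noise` (the track), `window`, `name`.
#' @export
pigment_fixture <- function(name = c("chl_like", "bchl_like",
                                     "spheroidene_like", "spheroidenone_like"),
                            k = 12, noise_amplitude = 1e-4, seed = 1L) {
  name <- match.arg(name)
  mix <- pigment_mixture(name)
  win <- pigment_window(name)
  n <- 2L^as.integer(k)
  axis <- seq(win[1], win[2], length.out = n)
  raw <- mixture_value(mix, axis)
  scale <- max(raw)
  mix <- gaussian_mixture(mix$amplitude / scale, mix$center, mix$fwhm)
  model <- mixture_spectrum(mix, axis)
  noise <- synth_noise(n, amplitude = noise_amplitude, seed = seed,
                       axis = axis)
  list(mixture = mix, model = model,
       test = make_test_spectrum(model, noise),
       noise = noise, window = win, name = name)
}
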