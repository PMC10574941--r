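#' Straighten a measured instrument noise track
#'
#' An empty-cuvette noise record usually rides on a slowly varying baseline
#' (instrument sensitivity changes with wavelength). Straightening subtracts
#' a centred moving average so only the fast residual remains; the
#' characteristic amplitude is a robust standard deviation (1.4826 * MAD)
#' of that residual.
#'
#' @param raw A spectrum holding the raw noise record (at least
#'   `3 * smoother_window` points).
#' @param smoother_window Moving-average window in samples (odd preferred),
#'   default 51; must be at least 3.
#' @return A `noise_track` tibble with columns `axis`, `residual` and
#'   attributes `amplitude_scale` and `axis_unit`.
#' @export
straighten_noise <- function(raw, smoother_window = 51) {
  raw <- as_spectrum(raw)
  if (smoother_window < 3) abort("`smoother_window` must be at least 3 (config error).")
  if (nrow(raw) < 3 * smoother_window) {
    abort("Noise record must have at least 3 * smoother_window points.")
  }
  smooth <- moving_average(raw$intensity, smoother_window)
  residual <- raw$intensity - smooth
  new_noise_track(raw$axis, residual, axis_unit = axis_unit(raw),
                  meta = list(smoother_window = as.integer(smoother_window)))
}

# centred moving average with shrinking (partial) windows at the edges, so
# a constant record straightens to exactly zero everywhere
moving_average <- function(y, w) {
  n <- length(y)
  half <- w %/% 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

new_noise_track <- function(axis, residual, axis_unit = "wavenumber",
                            meta = list()) {
  scale <- 1.4826 * median(abs(residual - median(residual)))
  if (scale <= 0) scale <- max(sd(residual), .Machine$double.eps)
  out <- new_tibble(list(axis = as.numeric(axis),
                         residual = as.numeric(residual)),
                    nrow = length(axis), class = "noise_track")
  attr(out, "amplitude_scale") <- scale
  attr(out, "axis_unit") <- axis_unit
  attr(out, "meta") <- meta
  out
}

#' @export
amplitude_scale <- function(nt) attr(nt, "amplitude_scale")

#' Synthesize a reproducible instrument-like noise track
#'
#' Seeded Gaussian white noise with standard deviation `amplitude`
#' (optical units; about 1e-4 for a modern spectrophotometer when the peak
#' is normalized to 1), optionally shaped by a pointwise multiplicative
#' envelope to emulate wavelength-dependent detector sensitivity.
#'
#' @param n Number of samples (>= 8).
#' @param amplitude Noise standard deviation, optical units, positive.
#' @param seed Integer seed; the same seed reproduces the track exactly.
#' @param envelope Optional length-`n` multiplicative envelope.
#' @param axis Optional axis positions (defaults to sample index).
#' @param axis_unit Axis unit tag.
#' @return A `noise_track` tibble.
#' @export
synth_noise <- function(n, amplitude = 1e-4, seed = 1L, envelope = NULL,
                        axis = NULL, axis_unit = "wavenumber") {
  if (n < 8) abort("`n` must be at least 8.")
  if (amplitude <= 0) abort("`amplitude` must be positive.")
  if (!is.null(envelope) && length(envelope) != n) {
    abort("`envelope` length must equal `n` (shape error).")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  res <- rnorm(n, sd = amplitude)
  if (!is.null(envelope)) res <- res * envelope
  new_noise_track(axis %||% seq_len(n), res, axis_unit = axis_unit,
                  meta = list(seed = as.integer(seed), amplitude = amplitude,
                              enveloped = !is.null(envelope)))
}

#' Overlay a noise track on a model spectrum
#'
#' Adds the straightened residual to the model intensities, producing a
#' "test spectrum" with known analytic ground truth but experimental-grade
#' noise. Exactly additive, hence invertible given the noise record.
#'
#' @param model A spectrum (the analytic model samples).
#' @param noise A `noise_track` on the identical grid.
#' @return A spectrum; metadata records the noise provenance.
#' @export
make_test_spectrum <- function(model, noise) {
  model <- as_spectrum(model)
  if (nrow(model) != nrow(noise) ||
      max(abs(model$axis - noise$axis)) > 1e-9 * diff(range(model$axis))) {
    abort("Model and noise must share the same grid (shape error).")
  }
  with_spectrum_attrs(
    tibble(axis = model$axis, intensity = model$intensity + noise$residual),
    model,
    noise = list(amplitude_scale = amplitude_scale(noise),
                 provenance = attr(noise, "meta")))
}
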