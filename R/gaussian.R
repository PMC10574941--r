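#' Sum-of-Gaussians spectral models
#'
#' A Gaussian mixture is a tibble with one component per row: `amplitude`
#' (peak height, optical units), `center` (axis units) and `fwhm` (axis
#' units). A component's value at its centre is exactly its amplitude. The
#' mixture is the analytic "model spectrum" of the workflow: its derivative
#' of any order is exact, which is what makes it usable as ground truth for
#' tuning the noise filter.
#'
#' @param amplitude,center,fwhm Numeric vectors (recycled to a common
#'   length); `amplitude > 0`, `fwhm > 0`.
#' @return A `gaussian_mixture` tibble, sorted by ascending centre (the
#'   canonical order that breaks permutation symmetry).
#' @examples
#' m <- gaussian_mixture(c(1, 0.3), c(14900, 15600), c(350, 700))
#' mixture_value(m, 14900)
#' @export
gaussian_mixture <- function(amplitude, center, fwhm) {
  m <- tibble(amplitude = as.numeric(amplitude),
              center = as.numeric(center),
              fwhm = as.numeric(fwhm))
  if (nrow(m) < 1) abort("A mixture needs at least one component.")
  if (any(m$amplitude <= 0)) abort("Amplitudes must be positive.")
  if (any(m$fwhm <= 0)) abort("Widths must be positive.")
  m <- arrange(m, .data$center)
  class(m) <- c("gaussian_mixture", class(tibble()))
  m
}

mixture_sigma <- function(m) m$fwhm * .fwhm_to_sigma

#' Evaluate a Gaussian mixture
#'
#' `sum_c A_c exp(-(x - mu_c)^2 / (2 sigma_c^2))` with
#' `sigma = fwhm / (2 sqrt(2 ln 2))`.
#'
#' @param m A [gaussian_mixture()].
#' @param axis Numeric sample positions.
#' @return Numeric vector of model intensities.
#' @export
mixture_value <- function(m, axis) {
  mixture_derivative(m, axis, order = 0)
}

#' Exact analytic derivative of a Gaussian mixture
#'
#' Uses the probabilists' Hermite identity
#' `d^n/du^n e^{-u^2/2} = (-1)^n He_n(u) e^{-u^2/2}` with `u = (x - mu)/sigma`
#' and the chain-rule factor `sigma^{-n}`, summed over components. Exact to
#' rounding for any order, which is the point of decomposing a noisy
#' spectrum into Gaussians before differentiating.
#'
#' @inheritParams mixture_value
#' @param order Derivative order `n >= 0` (n = 0 evaluates the mixture).
#' @return Numeric vector of the nth derivative on `axis`.
#' @export
mixture_derivative <- function(m, axis, order) {
  if (order < 0) abort("Derivative order must be non-negative.")
  if (order > 12) abort("Orders above 12 are not supported.")
  stopifnot(inherits(m, "gaussian_mixture") || is.data.frame(m))
  n <- as.integer(order)
  out <- numeric(length(axis))
  sig <- m$fwhm * .fwhm_to_sigma
  for (j in seq_len(nrow(m))) {
    u <- (axis - m$center[j]) / sig[j]
    out <- out + m$amplitude[j] * (-1)^n * hermite_prob(n, u) *
      exp(-u^2 / 2) / sig[j]^n
  }
  out
}

# probabilists' Hermite polynomial He_n by the three-term recurrence
hermite_prob <- function(n, u) {
  if (n == 0L) return(rep(1, length(u)))
  h0 <- rep(1, length(u))
  h1 <- u
  if (n == 1L) return(h1)
  for (k in 1L:(n - 1L)) {
    h2 <- u * h1 - k * h0
    h0 <- h1
    h1 <- h2
  }
  h1
}

#' Model spectrum of a mixture on a given axis
#'
#' @inheritParams mixture_value
#' @param axis_unit Axis unit of the result.
#' @return A [spectrum()].
#' @export
mixture_spectrum <- function(m, axis, axis_unit = "wavenumber") {
  spectrum(axis, mixture_value(m, axis), axis_unit = axis_unit,
           meta = list(model = "gaussian_mixture", n_components = nrow(m)))
}

#' Decompose a spectrum into Gaussian components
#'
#' Approximates the target by `n_components` Gaussians. By default a seeded
#' differential-evolution search over (amplitude, centre, fwhm) boxes is
#' followed by a bounded local polish; with `init` supplied and
#' `strategy = "init_only"` the initial components are polished (or, with
#' `polish = FALSE`, returned as-is) without any global search — useful when
#' a manual decomposition is already acceptable.
#'
#' @param target A peak-normalized spectrum on a uniform grid.
#' @param n_components Number of Gaussians (3 suits chlorophyll-type Qy
#'   bands, 5 carotenoid S0->S2 bands).
#' @param init Optional [gaussian_mixture()] starting point.
#' @param strategy `"de"` (global search, default) or `"init_only"`.
#' @param bounds Optional named list of length-2 intervals `amplitude`,
#'   `center`, `fwhm` shared by all components; defaults to centres within
#'   the data window, fwhm between 2 grid steps and the window width, and
#'   amplitudes in (0, 2 * max intensity].
#' @param control A [de_control()].
#' @param polish Run the bounded local polish (default `TRUE`).
#' @return A `gaussian_fit` object: `mixture`, `rmse`, `history`,
#'   `evaluations`, `seed`.
#' @export
fit_gaussians <- function(target, n_components = 3, init = NULL,
                          strategy = c("de", "init_only"), bounds = NULL,
                          control = de_control(), polish = TRUE) {
  target <- as_spectrum(target)
  strategy <- match.arg(strategy)
  h <- axis_step(target)
  if (!is.null(init)) n_components <- nrow(init)
  if (n_components < 1) abort("`n_components` must be at least 1.")
  if (n_components > nrow(target) / 4) {
    abort("overparameterized: n_components exceeds length(target)/4.")
  }
  win <- range(target$axis)
  ymax <- max(target$intensity)
  bounds <- bounds %||% list()
  ba <- bounds$amplitude %||% c(ymax * 1e-4, 2 * ymax)
  bc <- bounds$center %||% win
  bw <- bounds$fwhm %||% c(2 * h, diff(win))
  lower <- rep(c(ba[1], bc[1], bw[1]), n_components)
  upper <- rep(c(ba[2], bc[2], bw[2]), n_components)
  unpack <- function(par) {
    i <- 3 * (seq_len(n_components) - 1)
    gaussian_mixture(pmax(par[i + 1], ba[1]), par[i + 2], pmax(par[i + 3], bw[1] / 2))
  }
  y <- target$intensity
  objective <- function(par) {
    i <- 3 * (seq_len(n_components) - 1)
    sig <- par[i + 3] * .fwhm_to_sigma
    pred <- 0
    for (j in seq_len(n_components)) {
      pred <- pred + par[3 * j - 2] *
        exp(-(target$axis - par[3 * j - 1])^2 / (2 * sig[j]^2))
    }
    sqrt(mean((pred - y)^2))
  }
  pack <- function(m) as.vector(rbind(m$amplitude, m$center, m$fwhm))
  history <- tibble(generation = integer(), best_objective = numeric())
  evals <- 0L
  if (strategy == "init_only") {
    if (is.null(init)) abort("`strategy = \"init_only\"` requires `init`.")
    par <- pmin(pmax(pack(init), lower), upper)
    value <- objective(par)
  } else {
    res <- de_minimize(objective, lower, upper, control)
    if (!is.null(init)) {
      par0 <- pmin(pmax(pack(init), lower), upper)
      if (objective(par0) < res$value) {
        res$par <- par0
        res$value <- objective(par0)
      }
    }
    par <- res$par
    value <- res$value
    history <- res$history
    evals <- res$evaluations
  }
  if (polish) {
    pol <- polish_minimize(objective, par, lower, upper, maxit = 1000)
    par <- pol$par
    value <- pol$value
  }
  structure(list(mixture = unpack(par), rmse = value, history = history,
                 evaluations = evals, seed = control$seed,
                 n_components = n_components),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian decomposition: %d component(s), RMSE = %.3e (seed %d)\n",
              x$n_components, x$rmse, x$seed))
  print(tibble::as_tibble(x$mixture))
  invisible(x)
}

#' Read/write Gaussian mixture files
#'
#' Structured key-value (YAML) documents listing components as
#' `{amplitude, center, fwhm}`, 16-significant-digit serialization.
#'
#' @param m A [gaussian_mixture()].
#' @param path File path.
#' @export
write_mixture <- function(m, path) {
  doc <- list(components = purrr::transpose(
    list(amplitude = m$amplitude, center = m$center, fwhm = m$fwhm)))
  writeLines(yaml::as.yaml(doc, precision = 16), path)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  doc <- yaml::read_yaml(path)
  gaussian_mixture(
    amplitude = map_dbl(doc$components, "amplitude"),
    center = map_dbl(doc$components, "center"),
    fwhm = map_dbl(doc$components, "fwhm"))
}
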