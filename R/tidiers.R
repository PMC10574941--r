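#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns one row per estimated component (Gaussian component,
#' vibronic mode, or traced filter candidate); `glance()` returns a one-row
#' summary of the fit.
#'
#' @param x A `gaussian_fit`, `mbo_fit` or `filter_search` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  mutate(as_tibble(x$mixture), component = dplyr::row_number(),
         .before = 1)
}

#' @rdname tidiers
#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(n_components = x$n_components, rmse = x$rmse,
         evaluations = x$evaluations, seed = x$seed)
}

#' @rdname tidiers
#' @method tidy mbo_fit
#' @export
tidy.mbo_fit <- function(x, ...) {
  modes <- as_tibble(x$params$modes)
  if (nrow(modes)) mutate(modes, mode = dplyr::row_number(), .before = 1)
  else modes
}

#' @rdname tidiers
#' @method glance mbo_fit
#' @export
glance.mbo_fit <- function(x, ...) {
  tibble(n_modes = x$n_modes, omega_eg = x$params$omega_eg,
         fwhm_inh = x$params$fwhm_inh, temperature = x$params$temperature,
         rmse = x$rmse, evaluations = x$evaluations, seed = x$seed)
}

#' @rdname tidiers
#' @method tidy filter_search
#' @export
tidy.filter_search <- function(x, ...) x$trace

#' @rdname tidiers
#' @method glance filter_search
#' @export
glance.filter_search <- function(x, ...) {
  tibble(family = x$best$family, cutoff = x$best$cutoff,
         rolloff = x$best$rolloff, objective = x$objective,
         order = x$order, candidates = nrow(x$trace), seed = x$seed)
}
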