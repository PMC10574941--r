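#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: spectra as intensity curves, derivative records as signed curves
#' around zero, Gaussian fits as data plus components plus envelope, and
#' filter searches as the objective landscape over cutoff.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

axis_lab <- function(unit) {
  if (identical(unit, "nm")) "wavelength (nm)" else expression(wavenumber~(cm^-1))
}

#' @rdname autoplot-methods
#' @method autoplot spectrum
#' @export
autoplot.spectrum <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$axis, y = .data$intensity)) +
    geom_line(linewidth = 0.3) +
    labs(x = axis_lab(axis_unit(object)), y = "intensity (o.u.)") +
    theme_minimal()
}

#' @rdname autoplot-methods
#' @method autoplot spectral_derivative
#' @export
autoplot.spectral_derivative <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$axis, y = .data$value)) +
    geom_hline(yintercept = 0, colour = "grey70", linewidth = 0.2) +
    geom_line(linewidth = 0.3) +
    labs(x = axis_lab(attr(object, "axis_unit")),
         y = sprintf("d^%d intensity%s", attr(object, "order"),
                     if (isTRUE(attr(object, "normalized"))) " (normalized)" else "")) +
    theme_minimal()
}

#' @rdname autoplot-methods
#' @param spectrum_data Optional spectrum to underlay the fitted envelope.
#' @method autoplot gaussian_fit
#' @export
autoplot.gaussian_fit <- function(object, spectrum_data = NULL, ...) {
  m <- object$mixture
  rng <- range(m$center) + c(-3, 3) * max(m$fwhm)
  if (!is.null(spectrum_data)) rng <- range(spectrum_data$axis)
  axis <- seq(rng[1], rng[2], length.out = 1024)
  comp <- purrr::map(seq_len(nrow(m)), function(i) {
    one <- gaussian_mixture(m$amplitude[i], m$center[i], m$fwhm[i])
    tibble(axis = axis, intensity = mixture_value(one, axis),
           component = factor(i))
  })
  comp <- bind_rows(comp)
  p <- ggplot(comp, aes(x = .data$axis, y = .data$intensity))
  if (!is.null(spectrum_data)) {
    p <- p + geom_line(data = as_tibble(spectrum_data),
                       aes(x = .data$axis, y = .data$intensity),
                       colour = "grey40", linewidth = 0.3)
  }
  p +
    geom_line(aes(colour = .data$component), linewidth = 0.3) +
    geom_line(data = tibble(axis = axis, intensity = mixture_value(m, axis)),
              linetype = "dashed", linewidth = 0.4) +
    labs(x = axis_lab("wavenumber"), y = "intensity (o.u.)",
         colour = "component") +
    theme_minimal()
}

#' @rdname autoplot-methods
#' @method autoplot filter_search
#' @export
autoplot.filter_search <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$cutoff, y = .data$objective)) +
    geom_point(size = 0.7, alpha = 0.6) +
    geom_vline(xintercept = object$best$cutoff, colour = "red",
               linewidth = 0.3) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "cutoff (cycles per axis unit)",
         y = "normalized-derivative RMSE") +
    theme_minimal()
}

#' Overlay two derivative records for comparison
#'
#' The workflow's verdict plot: recovered (filtered, differentiated noisy
#' spectrum) versus reference (analytic model derivative).
#'
#' @param recovered,reference `spectral_derivative` records on one grid.
#' @return A ggplot object.
#' @export
plot_derivative_comparison <- function(recovered, reference) {
  df <- bind_rows(
    mutate(as_tibble(recovered), curve = "recovered"),
    mutate(as_tibble(reference), curve = "reference"))
  ggplot(df, aes(x = .data$axis, y = .data$value, colour = .data$curve)) +
    geom_hline(yintercept = 0, colour = "grey70", linewidth = 0.2) +
    geom_line(linewidth = 0.3) +
    scale_colour_manual(values = c(recovered = "#1b9e77", reference = "black")) +
    labs(x = axis_lab(attr(reference, "axis_unit")),
         y = "normalized derivative", colour = NULL) +
    theme_minimal()
}
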