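#' Sampled optical spectra as tibbles
#'
#' A spectrum is a tibble with columns `axis` (sample positions, strictly
#' increasing, in nm or wavenumber cm^-1) and `intensity` (optical units).
#' The axis unit and free-form provenance tags travel as attributes
#' (`axis_unit`, `meta`) so spectra survive piping through the package's
#' verbs unchanged.
#'
#' @param axis Numeric vector of sample positions, strictly monotonic.
#' @param intensity Numeric vector of optical-unit values, same length.
#' @param axis_unit `"nm"` or `"wavenumber"`.
#' @param meta Named list of provenance tags.
#' @return A `spectrum` tibble.
#' @examples
#' s <- spectrum(seq(600, 800, by = 1), dnorm(seq(600, 800, 1), 700, 12))
#' axis_unit(s)
#' @export
spectrum <- function(axis, intensity, axis_unit = c("nm", "wavenumber"),
                     meta = list()) {
  axis_unit <- match.arg(axis_unit)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity)) {
    abort("`axis` and `intensity` must have the same length.")
  }
  if (is.unsorted(axis, strictly = FALSE)) {
    o <- order(axis)
    axis <- axis[o]
    intensity <- intensity[o]
  }
  out <- new_tibble(list(axis = axis, intensity = intensity),
                    nrow = length(axis),
                    class = "spectrum")
  attr(out, "axis_unit") <- axis_unit
  attr(out, "meta") <- meta
  validate_spectrum(out)
}

#' Coerce a data frame to a spectrum
#'
#' Accepts any data frame whose first two numeric columns (or columns named
#' `axis`/`intensity`) hold the sample positions and intensities.
#'
#' @param x A data frame or spectrum.
#' @inheritParams spectrum
#' @return A `spectrum` tibble.
#' @export
as_spectrum <- function(x, axis_unit = NULL, meta = NULL) {
  if (inherits(x, "spectrum") && is.null(axis_unit) && is.null(meta)) {
    return(validate_spectrum(x))
  }
  stopifnot(is.data.frame(x))
  cols <- if (all(c("axis", "intensity") %in% names(x))) {
    list(x[["axis"]], x[["intensity"]])
  } else {
    num <- which(vapply(x, is.numeric, logical(1)))
    if (length(num) < 2) abort("Need two numeric columns to form a spectrum.")
    list(x[[num[1]]], x[[num[2]]])
  }
  spectrum(cols[[1]], cols[[2]],
           axis_unit = axis_unit %||% attr(x, "axis_unit") %||% "nm",
           meta = meta %||% attr(x, "meta") %||% list())
}

validate_spectrum <- function(s) {
  if (nrow(s) < 8) abort("A spectrum needs at least 8 samples.")
  ax <- s$axis
  if (anyNA(ax) || any(!is.finite(ax))) abort("Axis values must be finite.")
  if (any(diff(ax) <= 0)) abort("Axis must be strictly increasing.")
  if (any(!is.finite(s$intensity))) abort("Intensities must all be finite.")
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
axis_unit <- function(s) attr(s, "axis_unit") %||% "nm"

spectrum_meta <- function(s) attr(s, "meta") %||% list()

with_spectrum_attrs <- function(df, template, ...) {
  extra <- list(...)
  meta <- modifyList(spectrum_meta(template), extra)
  spectrum(df$axis, df$intensity, axis_unit = axis_unit(template), meta = meta)
}

axis_step <- function(s) {
  d <- diff(s$axis)
  if (diff(range(d)) > 1e-8 * mean(d)) {
    abort("Spectrum is not on a uniform grid; regrid() it first.")
  }
  mean(d)
}

#' Read a two-column spectrum file
#'
#' Plain-text, two numeric columns (axis, intensity); lines starting with
#' `#` are comments; the delimiter may be tab, comma or whitespace and is
#' auto-detected unless given. A single non-numeric first row is treated as
#' a header. A `# unit: <nm|wavenumber>` comment sets the axis unit.
#'
#' @param path File path.
#' @param dialect `"auto"`, `"tab"`, `"comma"` or `"whitespace"`.
#' @param axis_unit Override the axis unit; default honours the file's
#'   `# unit:` comment, falling back to `"nm"`.
#' @return A `spectrum` tibble sorted by ascending axis.
#' @export
read_spectrum <- function(path, dialect = c("auto", "tab", "comma", "whitespace"),
                          axis_unit = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  unit <- axis_unit
  if (is.null(unit)) {
    m <- grep("^#\\s*unit:", lines, value = TRUE)
    unit <- if (length(m)) trimws(sub("^#\\s*unit:\\s*", "", m[1])) else "nm"
  }
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  lines <- lines[keep]
  if (!length(lines)) abort(sprintf("No data rows in '%s'.", path))
  sep <- switch(dialect,
    tab = "\t", comma = ",", whitespace = "ws",
    auto = if (grepl("\t", lines[1])) "\t"
           else if (grepl(",", lines[1])) "," else "ws")
  split1 <- function(l) {
    if (sep == "ws") strsplit(trimws(l), "\\s+")[[1]] else strsplit(l, sep, fixed = TRUE)[[1]]
  }
  fields <- lapply(lines, split1)
  start <- 1L
  first <- suppressWarnings(as.numeric(fields[[1]]))
  if (anyNA(first)) start <- 2L  # header row
  if (length(fields) < start) abort(sprintf("No data rows in '%s'.", path))
  rows <- fields[start:length(fields)]
  ncol <- vapply(rows, length, integer(1))
  if (any(ncol < 2)) {
    bad <- keep[start - 1 + which(ncol < 2)[1]]
    abort(sprintf("Line %d of '%s' has fewer than 2 columns.", bad, path))
  }
  parse_col <- function(j) {
    v <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), j)))
    if (anyNA(v)) {
      bad <- keep[start - 1 + which(is.na(v))[1]]
      abort(sprintf("Non-numeric value on line %d of '%s'.", bad, path))
    }
    v
  }
  ax <- parse_col(1L)
  it <- parse_col(2L)
  if (length(ax) < 8) abort(sprintf("'%s' has %d points; at least 8 required.", path, length(ax)))
  spectrum(ax, it, axis_unit = match.arg(unit, c("nm", "wavenumber")),
           meta = list(source = path))
}

#' Write a spectrum to a two-column text file
#'
#' Values are written with 16 significant digits and the axis unit is
#' recorded in a `# unit:` comment so [read_spectrum()] round-trips.
#'
#' @param s A spectrum.
#' @param path Output path.
#' @param sep Column delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = "\t") {
  s <- as_spectrum(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", axis_unit(s)), con)
  writeLines(paste0("axis", sep, "intensity"), con)
  writeLines(sprintf("%.16g%s%.16g", s$axis, sep, s$intensity), con)
  invisible(path)
}

#' Convert a wavelength axis to wavenumber
#'
#' Applies the point transform `axis -> 1e7 / axis` (nm to cm^-1) and
#' re-sorts ascending. Intensities are carried over unchanged: absorbance is
#' treated as a point function of the abscissa, with no Jacobian rescaling;
#' the convention is recorded in the metadata.
#'
#' @param s A spectrum with `axis_unit == "nm"` and positive axis values.
#' @return A wavenumber spectrum.
#' @export
to_wavenumber <- function(s) {
  s <- as_spectrum(s)
  if (axis_unit(s) == "wavenumber") return(s)
  if (any(s$axis <= 0)) abort("Wavelengths must be strictly positive.")
  spectrum(rev(1e7 / s$axis), rev(s$intensity), axis_unit = "wavenumber",
           meta = modifyList(spectrum_meta(s), list(axis_transform = "1e7/lambda, no Jacobian")))
}

#' Convert a wavenumber axis to wavelength
#'
#' Inverse of [to_wavenumber()]; the transform is an involution.
#'
#' @param s A spectrum with `axis_unit == "wavenumber"`.
#' @return A nm spectrum.
#' @export
to_wavelength <- function(s) {
  s <- as_spectrum(s)
  if (axis_unit(s) == "nm") return(s)
  if (any(s$axis <= 0)) abort("Wavenumbers must be strictly positive.")
  spectrum(rev(1e7 / s$axis), rev(s$intensity), axis_unit = "nm",
           meta = modifyList(spectrum_meta(s), list(axis_transform = "1e7/nu, no Jacobian")))
}

#' Resample a spectrum onto a power-of-two uniform grid
#'
#' Interpolates onto `2^k` uniformly spaced points spanning `window`.
#' Fast-Fourier processing downstream (filtering, spectral differentiation)
#' requires such grids. Interpolation is piecewise cubic by default, with a
#' linear fallback.
#'
#' @param s A spectrum.
#' @param k Grid exponent, `3 <= k <= 16`; output length is `2^k`.
#' @param window Length-2 numeric, target axis interval; defaults to the
#'   full data range.
#' @param method `"cubic"` (default) or `"linear"`.
#' @return A spectrum on the uniform grid.
#' @export
regrid <- function(s, k = 12, window = NULL, method = c("cubic", "linear")) {
  s <- as_spectrum(s)
  method <- match.arg(method)
  if (k < 3 || k > 16) abort("`k` must be between 3 and 16.")
  rng <- range(s$axis)
  window <- window %||% rng
  if (length(window) != 2 || window[1] >= window[2]) abort("`window` must be an increasing interval.")
  tol <- 1e-9 * diff(rng)
  if (window[1] < rng[1] - tol || window[2] > rng[2] + tol) {
    abort(sprintf("window [%g, %g] lies outside the data range [%g, %g].",
                  window[1], window[2], rng[1], rng[2]))
  }
  n <- 2L^as.integer(k)
  grid <- seq(window[1], window[2], length.out = n)
  y <- if (method == "cubic") {
    splinefun(s$axis, s$intensity, method = "fmm")(grid)
  } else {
    approx(s$axis, s$intensity, xout = grid, rule = 2)$y
  }
  with_spectrum_attrs(tibble(axis = grid, intensity = y), s,
                      regrid = list(k = as.integer(k), method = method))
}

#' Shift the global intensity maximum to the record's centre
#'
#' Differentiation by FFT treats the record as periodic; placing the main
#' peak at the middle sample keeps its structure away from the wrap-around
#' seam. The vacated margin is filled according to `pad_mode`, and the
#' applied shift is stored in the metadata (`center_shift`) so it can be
#' undone.
#'
#' @param s A spectrum on a uniform grid.
#' @param pad_mode `"edge"` (repeat the edge value, default), `"reflect"`,
#'   or `"zero"`.
#' @return The centred spectrum.
#' @export
center_peak <- function(s, pad_mode = c("edge", "reflect", "zero")) {
  s <- as_spectrum(s)
  pad_mode <- match.arg(pad_mode)
  axis_step(s)
  y <- s$intensity
  n <- length(y)
  if (diff(range(y)) == 0) abort("no distinct maximum: spectrum is flat.")
  peaks <- which(y == max(y))
  if (length(peaks) > 1) {
    warn(sprintf("%d equal maxima; using the lowest-axis one.", length(peaks)))
  }
  i_max <- peaks[1]
  target <- n %/% 2 + 1L
  shift <- target - i_max
  if (shift == 0) return(s)
  out <- numeric(n)
  src <- seq_len(n) - shift          # source index for each output position
  inside <- src >= 1 & src <= n
  out[inside] <- y[src[inside]]
  pad <- function(idx) {
    switch(pad_mode,
      edge = y[pmin(pmax(idx, 1L), n)],
      zero = rep(0, length(idx)),
      reflect = {
        r <- idx
        r[r < 1] <- 2 - r[r < 1]
        r[r > n] <- 2 * n - r[r > n]
        y[pmin(pmax(r, 1L), n)]
      })
  }
  if (any(!inside)) out[!inside] <- pad(src[!inside])
  with_spectrum_attrs(tibble(axis = s$axis, intensity = out), s,
                      center_shift = shift, center_pad = pad_mode)
}

#' Undo the shift applied by [center_peak()]
#'
#' @param s A spectrum carrying a `center_shift` metadata entry.
#' @return The un-shifted spectrum (padded margins are not recoverable).
#' @export
uncenter_peak <- function(s) {
  s <- as_spectrum(s)
  shift <- spectrum_meta(s)$center_shift
  if (is.null(shift) || shift == 0) return(s)
  y <- s$intensity
  n <- length(y)
  out <- numeric(n)
  src <- seq_len(n) + shift
  inside <- src >= 1 & src <= n
  out[inside] <- y[src[inside]]
  out[!inside] <- y[pmin(pmax(src[!inside], 1L), n)]
  with_spectrum_attrs(tibble(axis = s$axis, intensity = out), s, center_shift = 0L)
}

#' Normalize a spectrum to unit peak intensity
#'
#' Divides intensities by their maximum, the convention under which a
#' typical instrument noise track has amplitude about 1e-4 optical units.
#'
#' @param s A spectrum with a positive maximum.
#' @return The normalized spectrum (max intensity exactly 1).
#' @export
normalize_peak <- function(s) {
  s <- as_spectrum(s)
  m <- max(s$intensity)
  if (m <= 0) abort("Maximum intensity must be positive to normalize.")
  with_spectrum_attrs(tibble(axis = s$axis, intensity = s$intensity / m), s,
                      peak_scale = m)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("# A spectrum: %d samples, axis %g..%g %s\n",
              nrow(x), min(x$axis), max(x$axis),
              if (axis_unit(x) == "nm") "nm" else "cm^-1"))
  NextMethod()
}
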