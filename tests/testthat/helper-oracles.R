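# Independent numerical oracles used across the suite. These never call the
# code paths they check: derivatives come from finite differences, spectral
# integrals from stats::integrate.

# Fornberg's recursion for finite-difference weights of derivative m on
# arbitrary nodes x about the point z (Mathematics of Computation 51, 1988).
fornberg_weights <- function(z, x, m) {
  n <- length(x)
  w <- matrix(0, n, m + 1)
  c1 <- 1
  c4 <- x[1] - z
  w[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i - 1, m)
    c2 <- 1
    c5 <- c4
    c4 <- x[i] - z
    for (j in 1:(i - 1)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        for (k in mn:1) {
          w[i, k + 1] <- c1 * (k * w[i - 1, k] - c5 * w[i - 1, k + 1]) / c2
        }
        w[i, 1] <- -c1 * c5 * w[i - 1, 1] / c2
      }
      for (k in mn:1) w[j, k + 1] <- (c4 * w[j, k + 1] - k * w[j, k]) / c3
      w[j, 1] <- c4 * w[j, 1] / c3
    }
    c1 <- c2
  }
  w[, m + 1]
}

fd_stencil <- function(fn, x, n, h, npts) {
  half <- (npts - 1) / 2
  offs <- (-half:half) * h
  w <- fornberg_weights(0, offs, n)
  vals <- vapply(offs, function(o) fn(x + o), numeric(length(x)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(x))
  as.numeric(vals %*% w)
}

# nth central finite-difference derivative on a high-accuracy symmetric
# stencil, Richardson-extrapolated once (steps h and h/1.5). The step must
# stay well above the n-fold cancellation floor of eps-rounded function
# values: for n = 8 callers pass h ~ sigma/4.5 of the narrowest feature.
richardson_derivative <- function(fn, x, n, h) {
  npts <- n + 9 + (n %% 2)               # accuracy order ~ 10
  p <- npts - n
  if (p %% 2 == 1) p <- p + 1            # symmetric stencils gain a power
  d1 <- fd_stencil(fn, x, n, h, npts)
  d2 <- fd_stencil(fn, x, n, h / 1.5, npts)
  (1.5^p * d2 - d1) / (1.5^p - 1)
}

# reorganization energy by adaptive quadrature of the spectral density
lambda_quadrature <- function(modes) {
  stats::integrate(function(w) spectral_density(modes, w) / w / pi,
                   lower = 0, upper = Inf, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

# closed-form unit-peak Gaussian of given FWHM
gaussian_curve <- function(x, center, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(x - center)^2 / (2 * s^2))
}

# a well-conditioned three-band mixture for derivative-oracle checks: all
# components many sigma inside the window so the periodic extension is
# smooth to machine zero
oracle_mixture <- function() {
  gaussian_mixture(amplitude = c(1, 0.25, 0.1),
                   center = c(14550, 15150, 15750),
                   fwhm = c(380, 600, 380))
}

oracle_axis <- function(k = 8, window = c(10500, 18500)) {
  seq(window[1], window[2], length.out = 2L^k)
}

rel_rmse <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))

# identity transfer over the whole representable band: cutoff far above the
# Nyquist frequency, zero rolloff
identity_filter <- function(s) {
  nyq <- 1 / (2 * (s$axis[2] - s$axis[1]))
  filter_spec(10 * nyq, 0, family = "raised_cosine")
}
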