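Package: specderiv
Title: Undistorted High-Order Derivatives of Noisy Pigment Absorption Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering undistorted high-order (up to eighth)
    derivatives of noisy optical absorption spectra of photosynthetic
    pigments. Simulates reference lineshapes with a semiclassical multimode
    Brownian oscillator model, approximates measured spectra by sums of
    Gaussians whose derivatives of any order are exact, synthesizes test
    spectra by overlaying straightened instrument noise on the analytic
    model, and searches for the FFT low-pass filter whose application lets
    spectral differentiation of the noisy record reproduce the model's
    analytic eighth derivative. Includes a seeded differential-evolution
    optimizer shared by the lineshape fit, the Gaussian decomposition, and
    the filter search, plus a scriptable pipeline driven by a YAML
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
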