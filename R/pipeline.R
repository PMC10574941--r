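#' Pipeline configuration
#'
#' One YAML document drives the whole workflow. Recognised keys (all
#' optional unless a stage needs them): `input` (spectrum file), `noise`
#' (measured noise file; omitted means synthesize), `window` (length-2 axis
#' interval), `k` (grid exponent, 8..14), `n_gaussians`, `order`
#' (derivative order, 1..8), `noise_amplitude`, `smoother_window`,
#' `filter_family`, `filter_space` (`cutoff`/`rolloff` intervals), `seed`,
#' `fixture` (fixture class name for synthetic runs), `mbo` (parameter file
#' for simulation), `out_dir`.
#'
#' @param path YAML file path, or `NULL` to use `...` directly.
#' @param ... Key-value overrides applied after the file is read.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- modifyList(cfg, list(...))
  defaults <- list(k = 12, n_gaussians = 3, order = 8, noise_amplitude = 1e-4,
                   smoother_window = 51, filter_family = "raised_cosine",
                   seed = 1L, fixture = "chl_like", out_dir = ".")
  cfg <- modifyList(defaults, cfg)
  if (cfg$order < 1 || cfg$order > 8) {
    abort("`order` must lie in 1..8 (the eighth derivative is the double-precision ceiling).")
  }
  if (cfg$k < 8 || cfg$k > 14) abort("`k` must lie in 8..14.")
  structure(cfg, class = "pipeline_config")
}

cfg_path <- function(cfg, name) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  file.path(cfg$out_dir, name)
}

load_input_spectrum <- function(cfg) {
  if (!is.null(cfg[["input"]])) {
    s <- read_spectrum(cfg[["input"]])
    if (axis_unit(s) == "nm") s <- to_wavenumber(s)
    s <- regrid(s, k = cfg$k, window = cfg[["window"]])
    normalize_peak(s)
  } else {
    pigment_fixture(cfg$fixture, k = cfg$k,
                    noise_amplitude = cfg$noise_amplitude,
                    seed = cfg$seed)$test
  }
}

#' Run pipeline stages
#'
#' Thin orchestration of the package verbs, writing each stage's outputs
#' under `out_dir` and returning them invisibly. `run_all()` chains
#' simulate, decompose, maketest, tunefilter and derive, and ends with a
#' comparison report of the recovered versus reference derivatives.
#'
#' @param cfg A [pipeline_config()].
#' @return Stage outputs, invisibly (see each stage's files).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(cfg) {
  p <- if (!is.null(cfg[["mbo"]])) read_mbo_params(cfg[["mbo"]]) else {
    if (is.null(cfg[["mbo_params"]])) abort("simulate needs `mbo` (file) or `mbo_params` (config error).")
    mp <- cfg[["mbo_params"]]
    mbo_params(
      vibronic_modes(map_dbl(mp$modes, "omega"), map_dbl(mp$modes, "gamma"),
                     map_dbl(mp$modes, "huang_rhys")),
      omega_eg = mp$omega_eg, fwhm_inh = mp$fwhm_inh,
      temperature = mp$temperature %||% 295)
  }
  s <- absorption_spectrum(p, sim_grid(k = cfg$k))
  write_spectrum(s, cfg_path(cfg, "simulated_spectrum.tsv"))
  write_mbo_params(p, cfg_path(cfg, "simulated_params.yaml"))
  invisible(list(params = p, spectrum = s))
}

#' @rdname pipeline
#' @export
run_decompose <- function(cfg) {
  target <- load_input_spectrum(cfg)
  fit <- fit_gaussians(target, n_components = cfg$n_gaussians,
                       control = de_control(seed = cfg$seed,
                                            max_gen = cfg[["max_gen"]] %||% 200))
  write_mixture(fit$mixture, cfg_path(cfg, "mixture.yaml"))
  writeLines(yaml::as.yaml(list(rmse = fit$rmse, seed = fit$seed,
                                evaluations = fit$evaluations),
                           precision = 16),
             cfg_path(cfg, "decompose_report.yaml"))
  invisible(fit)
}

#' @rdname pipeline
#' @param mixture A [gaussian_mixture()]; defaults to the stage file.
#' @export
run_maketest <- function(cfg, mixture = NULL) {
  mixture <- mixture %||% read_mixture(cfg_path(cfg, "mixture.yaml"))
  win <- cfg[["window"]] %||% (range(mixture$center) + c(-4, 4) * max(mixture$fwhm))
  axis <- seq(win[1], win[2], length.out = 2L^cfg$k)
  model <- normalize_peak(mixture_spectrum(mixture, axis))
  noise <- if (!is.null(cfg[["noise"]])) {
    straighten_noise(read_spectrum(cfg[["noise"]]), cfg$smoother_window)
  } else {
    synth_noise(length(axis), amplitude = cfg$noise_amplitude,
                seed = cfg$seed, axis = axis)
  }
  if (nrow(noise) != length(axis)) {
    res <- approx(noise$axis, noise$residual, xout = axis, rule = 2)$y
    noise <- new_noise_track(axis, res, axis_unit = "wavenumber")
  }
  test <- make_test_spectrum(model, noise)
  write_spectrum(test, cfg_path(cfg, "test_spectrum.tsv"))
  invisible(list(model = model, test = test, noise = noise))
}

#' @rdname pipeline
#' @param test Test spectrum; defaults to the stage file.
#' @export
run_tunefilter <- function(cfg, test = NULL, mixture = NULL) {
  mixture <- mixture %||% read_mixture(cfg_path(cfg, "mixture.yaml"))
  test <- test %||% read_spectrum(cfg_path(cfg, "test_spectrum.tsv"))
  search <- find_optimal_filter(test, mixture, order = cfg$order,
                                space = cfg[["filter_space"]],
                                family = cfg$filter_family,
                                seed = cfg$seed)
  writeLines(yaml::as.yaml(list(
    family = search$best$family, cutoff = search$best$cutoff,
    rolloff = search$best$rolloff, objective = search$objective,
    order = search$order, seed = search$seed), precision = 16),
    cfg_path(cfg, "optimal_filter.yaml"))
  utils::write.csv(search$trace, cfg_path(cfg, "filter_trace.csv"),
                   row.names = FALSE)
  invisible(search)
}

#' @rdname pipeline
#' @param spectrum Input spectrum; defaults to the configured input (or the
#'   seeded fixture when no input file is configured).
#' @param filter A [filter_spec()]; defaults to the stage file.
#' @export
run_derive <- function(cfg, spectrum = NULL, filter = NULL) {
  if (is.null(filter)) {
    f <- yaml::read_yaml(cfg_path(cfg, "optimal_filter.yaml"))
    filter <- filter_spec(f$cutoff, f$rolloff, family = f$family)
  }
  spectrum <- spectrum %||% load_input_spectrum(cfg)
  d <- extract_derivative(spectrum, filter, order = cfg$order)
  out <- cfg_path(cfg, sprintf("derivative_order%d.tsv", cfg$order))
  con <- file(out, "w")
  writeLines(sprintf("# unit: %s", attr(d, "axis_unit")), con)
  writeLines("axis\tvalue", con)
  writeLines(sprintf("%.16g\t%.16g", d$axis, d$value), con)
  close(con)
  invisible(d)
}

#' @rdname pipeline
#' @export
run_fixtures <- function(cfg) {
  names <- c("chl_like", "bchl_like", "spheroidene_like", "spheroidenone_like")
  out <- lapply(names, function(nm) {
    fx <- pigment_fixture(nm, k = cfg$k, noise_amplitude = cfg$noise_amplitude,
                          seed = cfg$seed)
    write_spectrum(fx$test, cfg_path(cfg, sprintf("fixture_%s.tsv", nm)))
    write_mixture(fx$mixture, cfg_path(cfg, sprintf("fixture_%s_mixture.yaml", nm)))
    fx
  })
  invisible(setNames(out, names))
}

#' @rdname pipeline
#' @export
run_all <- function(cfg) {
  fx <- pigment_fixture(cfg$fixture, k = cfg$k,
                        noise_amplitude = cfg$noise_amplitude, seed = cfg$seed)
  decomposed <- if (isTRUE(cfg[["refit"]])) {
    fit_gaussians(fx$test, n_components = cfg$n_gaussians,
                  control = de_control(seed = cfg$seed,
                                       max_gen = cfg[["max_gen"]] %||% 200))$mixture
  } else fx$mixture
  write_mixture(decomposed, cfg_path(cfg, "mixture.yaml"))
  write_spectrum(fx$test, cfg_path(cfg, "test_spectrum.tsv"))
  search <- run_tunefilter(cfg, test = fx$test, mixture = decomposed)
  recovered <- extract_derivative(fx$test, search$best, order = cfg$order)
  reference <- normalize_derivative(
    analytic_derivative(fx$mixture, fx$test$axis, cfg$order))
  report <- list(
    fixture = cfg$fixture, order = cfg$order, seed = cfg$seed,
    filter = list(family = search$best$family, cutoff = search$best$cutoff,
                  rolloff = search$best$rolloff),
    objective = search$objective,
    rmse_vs_reference = derivative_discrepancy(recovered, reference),
    sign_changes_recovered = length(sign_changes(recovered, tol = 0.05)),
    sign_changes_reference = length(sign_changes(reference, tol = 0.05)),
    sign_agreement = sign_agreement(recovered, reference))
  writeLines(yaml::as.yaml(report, precision = 16),
             cfg_path(cfg, "pipeline_report.yaml"))
  invisible(list(fixture = fx, search = search, recovered = recovered,
                 reference = reference, report = report))
}
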