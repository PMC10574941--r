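#' Differential-evolution optimizer settings
#'
#' The DE/rand/1/bin strategy with boundary reflection is the shared global
#' optimizer behind the lineshape fit, the Gaussian decomposition and the
#' filter search. All stochastic choices derive from `seed`, so identical
#' settings and objective give bit-identical runs.
#'
#' @param pop_size Population size; default `15 * d` (capped at 150), set
#'   when the problem dimension is known.
#' @param max_gen Maximum number of generations.
#' @param F Mutation factor in (0, 2].
#' @param CR Crossover probability in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param tol Stop when the best objective improves by less than `tol`
#'   over `patience` consecutive generations.
#' @param patience Generations of stagnation tolerated before stopping.
#' @return A `de_control` list.
#' @export
de_control <- function(pop_size = NULL, max_gen = 200, F = 0.7, CR = 0.9,
                       seed = 1L, tol = 1e-10, patience = 40L) {
  if (!is.null(pop_size) && pop_size < 4) abort("`pop_size` must be at least 4.")
  if (max_gen < 0) abort("`max_gen` must be non-negative.")
  if (F <= 0 || F > 2) abort("`F` must lie in (0, 2].")
  if (CR < 0 || CR > 1) abort("`CR` must lie in [0, 1].")
  structure(list(pop_size = pop_size, max_gen = as.integer(max_gen),
                 F = F, CR = CR, seed = as.integer(seed), tol = tol,
                 patience = as.integer(patience)),
            class = "de_control")
}

#' Minimize a bounded objective by differential evolution
#'
#' DE/rand/1/bin: for each target vector a mutant `a + F*(b - c)` is built
#' from three distinct population members, binomially crossed with the
#' target, reflected back into the bounds, and kept if it does not worsen
#' the objective. Non-finite objective values are replaced by a large
#' penalty (1e6 times the worst finite value seen) so the search continues.
#'
#' @param fn Objective, a function of a numeric parameter vector.
#' @param lower,upper Numeric bounds, `lower < upper` elementwise.
#' @param control A [de_control()] list.
#' @return A list with `par` (best parameters), `value` (best objective),
#'   `history` (tibble: generation, best objective), `evaluations`, and
#'   `seed`.
#' @examples
#' de_minimize(function(x) sum(x^2), rep(-5, 3), rep(5, 3),
#'             de_control(max_gen = 60, seed = 7))$value
#' @export
de_minimize <- function(fn, lower, upper, control = de_control()) {
  d <- length(lower)
  if (d == 0 || length(upper) != d) abort("Bounds must be non-empty and of equal length.")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    abort("Bounds must be finite with lower < upper.")
  }
  np <- control$pop_size %||% min(15L * d, 150L)
  np <- max(np, 4L)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(control$seed)

  worst_finite <- 1
  evals <- 0L
  eval_fn <- function(x) {
    v <- fn(x)
    evals <<- evals + 1L
    if (!is.finite(v)) v <- 1e6 * abs(worst_finite) else {
      worst_finite <<- max(worst_finite, abs(v))
    }
    v
  }
  reflect <- function(x) {
    for (i in seq_len(20)) {
      lo <- x < lower
      hi <- x > upper
      if (!any(lo) && !any(hi)) break
      x[lo] <- 2 * lower[lo] - x[lo]
      x[hi] <- 2 * upper[hi] - x[hi]
    }
    pmin(pmax(x, lower), upper)
  }

  pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
  fit <- apply(pop, 1, eval_fn)
  hist_gen <- integer(0)
  hist_best <- numeric(0)
  stagnation <- 0L
  best_prev <- min(fit)

  gen <- 0L
  while (gen < control$max_gen) {
    gen <- gen + 1L
    for (i in seq_len(np)) {
      idx <- sample(seq_len(np)[-i], 3L)
      mutant <- pop[idx[1], ] + control$F * (pop[idx[2], ] - pop[idx[3], ])
      jrand <- sample.int(d, 1L)
      cross <- runif(d) < control$CR
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- reflect(trial)
      v <- eval_fn(trial)
      if (v <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- v
      }
    }
    best <- min(fit)
    hist_gen <- c(hist_gen, gen)
    hist_best <- c(hist_best, best)
    if (best_prev - best < control$tol) {
      stagnation <- stagnation + 1L
      if (stagnation >= control$patience) break
    } else {
      stagnation <- 0L
    }
    best_prev <- best
  }
  ib <- which.min(fit)
  list(par = pop[ib, ], value = fit[ib],
       history = tibble(generation = hist_gen, best_objective = hist_best),
       evaluations = evals, seed = control$seed)
}

# Bounded local polish used after DE: quasi-Newton with numerically
# differenced gradients (stats::nlminb), started from the DE optimum.
# Parameters are rescaled to O(1) first — mixed scales (band centres ~1e4,
# amplitudes ~1) otherwise defeat the finite-difference gradient steps.
polish_minimize <- function(fn, par, lower, upper, maxit = 400) {
  scale <- pmax(abs(upper - lower), 1e-8)
  safe <- function(z) {
    v <- fn(lower + z * scale)
    if (!is.finite(v)) 1e12 else v
  }
  z0 <- (par - lower) / scale
  res <- tryCatch(
    nlminb(z0, safe, lower = rep(0, length(par)), upper = rep(1, length(par)),
           control = list(iter.max = maxit, eval.max = 4 * maxit)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$objective) || res$objective > fn(par)) {
    list(par = par, value = fn(par))
  } else {
    p <- pmin(pmax(lower + res$par * scale, lower), upper)
    list(par = p, value = res$objective)
  }
}
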