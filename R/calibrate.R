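#' Default search space for calibration
#'
#' Every kinetic constant of the model searched on a log scale within
#' `[1/span, span]` times its current value. The literature-sourced Michaelis
#' constant of R1 (PLA2, from an enzyme database rather than from fitting)
#' is excluded by default.
#'
#' @param model An [eico_model()].
#' @param span Multiplicative half-width of the box (default 100).
#' @param exclude Parameter names to pin (default `"R1.k_m"`).
#' @return data.frame with columns `parameter`, `start`, `lower`, `upper`.
#' @export
default_parameter_space <- function(model, span = 100, exclude = "R1.k_m") {
  start <- get_constants(model)
  start <- start[setdiff(names(start), exclude)]
  data.frame(parameter = names(start), start = unname(start),
             lower = unname(start) / span, upper = unname(start) * span,
             stringsAsFactors = FALSE)
}

#' Calibration target specification
#'
#' Bundles everything the objective function needs: the metabolite set M over
#' which residuals are computed, the experimental steady-state concentrations
#' of those metabolites under the control (`ec`) and DDC (`ed`) conditions,
#' the two conditions themselves, and the parameter search space.
#'
#' @param model Base [eico_model()] whose non-searched constants are kept.
#' @param control,ddc The two [eico_condition()] objects (same strain).
#' @param experimental_control,experimental_ddc Named concentration vectors
#'   (nM) covering at least the metabolites in `metabolites`.
#' @param metabolites The metabolite set M (default [eico_metabolite_set()]).
#' @param parameter_space Search box, [default_parameter_space()] schema.
#' @param ss_tol Steady-state tolerance used inside the objective.
#' @return Object of class `eico_objective_spec`.
#' @export
objective_spec <- function(model, control, ddc,
                           experimental_control, experimental_ddc,
                           metabolites = eico_metabolite_set(),
                           parameter_space = default_parameter_space(model),
                           ss_tol = 1e-6) {
  stopifnot(inherits(model, "eico_model"),
            inherits(control, "eico_condition"),
            inherits(ddc, "eico_condition"))
  bad <- setdiff(metabolites, EICO_STATE)
  if (length(bad)) stop("unknown metabolite(s) in M: ", paste(bad, collapse = ", "))
  for (nm in c("experimental_control", "experimental_ddc")) {
    v <- get(nm)
    missing_m <- setdiff(metabolites, names(v))
    if (length(missing_m))
      stop(nm, " is missing: ", paste(missing_m, collapse = ", "))
    if (any(v[metabolites] < 0)) stop(nm, " has negative concentrations")
  }
  if (any(parameter_space$lower <= 0) ||
      any(parameter_space$lower >= parameter_space$upper))
    stop("parameter bounds must satisfy 0 < lower < upper")
  structure(list(model = model, control = control, ddc = ddc,
                 ec = experimental_control[metabolites],
                 ed = experimental_ddc[metabolites],
                 metabolites = metabolites,
                 parameter_space = parameter_space, ss_tol = ss_tol,
                 base_constants = get_constants(model),
                 cache = new.env(parent = emptyenv())),
            class = "eico_objective_spec")
}

#' Calibration objective function
#'
#' Sum of squared residuals between experimental and simulated steady-state
#' concentrations over the metabolite set M, under both the control and the
#' DDC condition:
#' \deqn{f(p) = \sum_{x \in M} (ec_x - sc_x(p))^2 + (ed_x - sd_x(p))^2.}
#' A candidate whose steady state fails to converge receives a large finite
#' penalty instead of an error so that population-based optimizers can
#' continue.
#'
#' @param par Named numeric vector of kinetic constants (subset of
#'   `spec$parameter_space$parameter`); missing entries keep the model value.
#' @param spec An [objective_spec()].
#' @return Non-negative scalar.
#' @export
eico_objective <- function(par, spec) {
  stopifnot(inherits(spec, "eico_objective_spec"))
  if (length(par)) {
    bad <- setdiff(names(par), names(spec$base_constants))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(par)) || any(par <= 0))
      stop("kinetic constants must be strictly positive")
  }
  compiled <- get0("compiled", envir = spec$cache, inherits = FALSE)
  if (is.null(compiled)) {
    compiled <- list(
      control = compile_condition(spec$model, spec$control$ratios,
                                  spec$control$pc_um * 1000),
      ddc = compile_condition(spec$model, spec$ddc$ratios,
                              spec$ddc$pc_um * 1000))
    assign("compiled", compiled, envir = spec$cache)
  }
  full <- spec$base_constants
  full[names(par)] <- par
  midx <- match(spec$metabolites, EICO_STATE)
  zeros <- rep(0, length(EICO_STATE))
  f <- 0
  for (side in c("control", "ddc")) {
    fns <- compiled[[side]]$with_constants(full)
    warm <- get0(paste0("warm_", side), envir = spec$cache, inherits = FALSE)
    sol <- steady_solve(fns$rhs, spec$ss_tol, init = zeros, t_max = 1e7,
                        warm = warm)
    if (!sol$converged) return(1e12)
    assign(paste0("warm_", side), sol$y, envir = spec$cache)
    target <- if (side == "control") spec$ec else spec$ed
    f <- f + sum((target - sol$y[midx])^2)
  }
  unname(f)
}

#' Fit kinetic parameters with a genetic algorithm
#'
#' Minimizes [eico_objective()] with an elitist genetic algorithm patterned
#' on the optimizers of kinetic-modelling suites: tournament selection
#' (k = 2), uniform crossover, per-gene log-normal mutation, elitism of one,
#' genes encoded on the log scale of the search box. The current model
#' constants are seeded into the initial population (the usual convention of
#' such suites); the remaining individuals are drawn log-uniformly from the
#' box. Deterministic for a given seed.
#'
#' @param spec An [objective_spec()].
#' @param population_size Individuals per generation (>= 2, default 50).
#' @param generations Number of generations (>= 1, default 500).
#' @param seed Integer RNG seed.
#' @param crossover_rate Probability of recombining a pair (default 0.7).
#' @param mutation_rate Per-gene mutation probability (default 0.1).
#' @param mutation_sigma Log-space standard deviation of a mutation step;
#'   either a scalar or `c(start, end)` for a geometric annealing schedule
#'   across generations (the default anneals from 0.2 to 0.02: steps
#'   comparable to the expected parameter misspecification first, fine
#'   polishing late).
#' @param verbose Print progress every 50 generations.
#' @return Object of class `eico_fit`: `best_parameters`, `best_objective`,
#'   `generation_trace` (best objective per generation, non-increasing),
#'   `seed`, `spec`, `model` (with the best parameters applied).
#' @seealso [predict.eico_fit()], [plot.eico_fit()]
#' @export
eico_fit <- function(spec, population_size = 50L, generations = 500L,
                     seed = 1L, crossover_rate = 0.7, mutation_rate = 0.1,
                     mutation_sigma = c(0.2, 0.02), verbose = FALSE) {
  stopifnot(inherits(spec, "eico_objective_spec"))
  if (population_size < 2L) stop("population_size must be >= 2")
  if (generations < 1L) stop("generations must be >= 1")
  ps <- spec$parameter_space
  npar <- nrow(ps)
  lo <- log(ps$lower); hi <- log(ps$upper)
  start <- pmin(pmax(log(ps$start), lo), hi)
  if (length(mutation_sigma) == 1L) mutation_sigma <- rep(mutation_sigma, 2L)
  sigma_at <- function(gen) {
    if (generations == 1L) return(mutation_sigma[1])
    mutation_sigma[1] *
      (mutation_sigma[2] / mutation_sigma[1])^((gen - 1) / (generations - 1))
  }
  # each fit starts from a cold steady-state cache for reproducibility
  rm(list = intersect(c("warm_control", "warm_ddc"), ls(spec$cache)),
     envir = spec$cache)

  decode <- function(g) setNames(exp(g), ps$parameter)
  evaluate <- function(g) eico_objective(decode(g), spec)

  fit <- with_preserved_seed(seed, {
    # Initial population: the current constants plus log-normal scatter
    # around them at the coarse mutation scale (clipped to the box), i.e.
    # the optimizer treats the shipped parameterization as the centre of
    # its prior, as is natural when refitting a curated model.
    pop <- matrix(start, population_size, npar, byrow = TRUE) +
      matrix(stats::rnorm(npar * population_size, 0, mutation_sigma[1]),
             population_size, npar)
    pop <- pmin(pmax(pop, matrix(lo, population_size, npar, byrow = TRUE)),
                matrix(hi, population_size, npar, byrow = TRUE))
    pop[1, ] <- start
    fitness <- apply(pop, 1, evaluate)
    trace <- numeric(generations)
    n_eval <- population_size
    for (gen in seq_len(generations)) {
      best_i <- which.min(fitness)
      newpop <- matrix(NA_real_, population_size, npar)
      newfit <- rep(NA_real_, population_size)
      newpop[1, ] <- pop[best_i, ]        # elitism of 1
      newfit[1] <- fitness[best_i]
      for (i in 2:population_size) {
        p1 <- tournament(fitness)
        p2 <- tournament(fitness)
        child <- pop[p1, ]
        if (runif(1) < crossover_rate) {
          take2 <- runif(npar) < 0.5
          child[take2] <- pop[p2, take2]
        }
        mut <- runif(npar) < mutation_rate
        if (any(mut))
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sigma_at(gen))
        child <- pmin(pmax(child, lo), hi)
        newpop[i, ] <- child
        newfit[i] <- evaluate(child)
        n_eval <- n_eval + 1L
      }
      pop <- newpop; fitness <- newfit
      trace[gen] <- min(fitness)
      if (verbose && gen %% 50L == 0L)
        eico_log("INFO", sprintf("generation %d: best f = %.6g", gen, trace[gen]))
    }
    if (all(fitness >= 1e12))
      stop("fit failure: no candidate reached a convergent steady state")
    best_i <- which.min(fitness)
    list(genome = pop[best_i, ], objective = fitness[best_i],
         trace = trace, n_eval = n_eval)
  })

  best_par <- decode(fit$genome)
  structure(list(best_parameters = best_par,
                 best_objective = fit$objective,
                 generation_trace = fit$trace,
                 n_evaluations = fit$n_eval,
                 seed = as.integer(seed), spec = spec,
                 model = set_constants(spec$model, best_par)),
            class = "eico_fit")
}

tournament <- function(fitness, k = 2L) {
  cand <- sample.int(length(fitness), k)
  cand[which.min(fitness[cand])]
}

#' @export
print.eico_fit <- function(x, ...) {
  cat("<eico_fit> genetic-algorithm calibration\n")
  cat(sprintf("  strain %s, %d parameters, %d generations, seed %d\n",
              x$spec$control$strain, length(x$best_parameters),
              length(x$generation_trace), x$seed))
  cat(sprintf("  best objective f = %.6g (over M = {%s})\n",
              x$best_objective, paste(x$spec$metabolites, collapse = ", ")))
  invisible(x)
}

#' @export
coef.eico_fit <- function(object, ...) object$best_parameters

#' @export
summary.eico_fit <- function(object, ...) {
  ps <- object$spec$parameter_space
  tab <- data.frame(parameter = ps$parameter, start = ps$start,
                    lower = ps$lower, upper = ps$upper,
                    fitted = unname(object$best_parameters[ps$parameter]))
  res <- residuals(object)
  out <- list(fit = object, parameters = tab, residuals = res)
  class(out) <- "summary.eico_fit"
  out
}

#' @export
print.summary.eico_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameters:\n")
  print(x$parameters, digits = 4, row.names = FALSE)
  cat("\nResiduals (experimental - simulated, nM):\n")
  print(x$residuals, digits = 4)
  invisible(x)
}

#' Steady-state predictions of a fitted model
#'
#' @param object An [eico_fit()] result.
#' @param condition `"control"`, `"ddc"`, `"both"`, or an [eico_condition()].
#' @param ... Ignored.
#' @return Named concentration vector (nM), or a two-row matrix for
#'   `"both"`.
#' @export
predict.eico_fit <- function(object, condition = "both", ...) {
  one <- function(cond) {
    ss <- steady_state(object$model, cond, tol = object$spec$ss_tol)
    if (!ss$converged) stop("fitted model failed to converge")
    ss$concentrations
  }
  if (inherits(condition, "eico_condition")) return(one(condition))
  condition <- match.arg(condition, c("both", "control", "ddc"))
  if (condition == "control") return(one(object$spec$control))
  if (condition == "ddc") return(one(object$spec$ddc))
  rbind(control = one(object$spec$control), ddc = one(object$spec$ddc))
}

#' @export
fitted.eico_fit <- function(object, ...) {
  p <- predict(object, "both")
  p[, object$spec$metabolites, drop = FALSE]
}

#' @export
residuals.eico_fit <- function(object, ...) {
  sim <- fitted(object)
  rbind(control = object$spec$ec - sim["control", ],
        ddc = object$spec$ed - sim["ddc", ])
}

#' Objective trajectory of a fit
#'
#' @param x An [eico_fit()] result.
#' @param ... Passed to [plot()].
#' @export
plot.eico_fit <- function(x, ...) {
  plot(seq_along(x$generation_trace), x$generation_trace, type = "s",
       log = "y", xlab = "generation", ylab = "best objective f",
       main = "GA calibration trace", ...)
  invisible(x)
}

#' Simulate noisy measurement tables from a fitted model
#'
#' Draws replicate metabolite measurements log-normally around the fitted
#' steady states of the training conditions (multiplicative noise of a given
#' coefficient of variation) and summarizes them as median and median
#' absolute deviation, mirroring the convention of the mass-spectrometry
#' tables the model is calibrated against.
#'
#' @param object An [eico_fit()] result.
#' @param nsim Number of measurement tables to draw.
#' @param seed RNG seed.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param replicates Replicates per strain/condition.
#' @param ... Ignored.
#' @return A list of `nsim` measurement data.frames (see
#'   [simulate_measurements()]).
#' @export
simulate.eico_fit <- function(object, nsim = 1, seed = 1L, noise_cv = 0.2,
                              replicates = 3L, ...) {
  p <- predict(object, "both")
  conds <- list(object$spec$control, object$spec$ddc)
  names(conds) <- c("control", "ddc")
  with_preserved_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      do.call(rbind, lapply(names(conds), function(tr) {
        draw_measurements(conds[[tr]]$strain, tr, p[tr, ],
                          noise_cv, replicates)
      }))
    })
  })
}
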