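#' Integrate the model ODE system
#'
#' Adaptive stiff integration (LSODA) of the seven-species ODE system under a
#' fixed condition.
#'
#' @param model An [eico_model()].
#' @param condition An [eico_condition()] (or a strain id together with
#'   `treatment`).
#' @param t_end End of the integration horizon in seconds.
#' @param times Optional explicit output times (overrides `t_end`).
#' @param init Initial concentrations in nM (default: all non-fixed species
#'   at 0, relying on the verified start-state independence of the system).
#' @param treatment Used when `condition` is a strain id.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return Matrix with a `time` column and one column per non-fixed
#'   metabolite (nM).
#' @export
integrate_model <- function(model, condition, t_end = 1e5, times = NULL,
                            init = NULL, treatment = "control",
                            rtol = 1e-8, atol = 1e-8) {
  condition <- get_condition(condition, treatment)
  if (t_end <= 0) stop("t_end must be > 0")
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  if (is.null(times)) times <- c(0, t_end)
  y0 <- init_state(init)
  f <- compile_rhs(model, condition$ratios, condition$pc_um * 1000)
  ode_fun <- function(t, y, parms) list(f(y)$dy)
  out <- deSolve::lsoda(y0, times, ode_fun, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("stiff-solver failure at t = ", max(out[, 1]))
  colnames(out) <- c("time", EICO_STATE)
  out
}

init_state <- function(init) {
  if (is.null(init)) return(setNames(rep(0, length(EICO_STATE)), EICO_STATE))
  if (!is.null(names(init))) init <- init[EICO_STATE]
  if (length(init) != length(EICO_STATE) || any(init < 0) ||
      any(!is.finite(init)))
    stop("init must be ", length(EICO_STATE), " finite non-negative values")
  setNames(as.numeric(init), EICO_STATE)
}

#' Solve for the steady state of a condition
#'
#' Integrates the system towards quasi-equilibrium over geometrically growing
#' horizons and polishes the result with a damped Newton iteration on the
#' right-hand side; the result is accepted once the residual
#' \eqn{\max_x |d[x]/dt|} falls below `tol`.
#'
#' @inheritParams integrate_model
#' @param tol Steady-state tolerance in nM/s.
#' @param t_max Maximum simulated horizon in seconds before giving up.
#' @return An object of class `eico_steady`: `concentrations` (named, nM),
#'   `residual_norm` (nM/s), `converged`, `t_reached`, `condition`.
#' @examples
#' m <- eico_model()
#' ss <- steady_state(m, eico_conditions()[["B6.control"]])
#' ss$converged
#' @export
steady_state <- function(model, condition, tol = 1e-6, init = NULL,
                         t_max = 1e8, treatment = "control") {
  condition <- get_condition(condition, treatment)
  if (tol <= 0) stop("tol must be > 0")
  cc <- compile_condition(model, condition$ratios, condition$pc_um * 1000)
  fns <- cc$with_constants(get_constants(model))
  sol <- steady_solve(fns$rhs, tol, init = init_state(init), t_max = t_max)
  new_steady(setNames(sol$y, EICO_STATE), sol$residual, sol$converged,
             sol$t_reached, condition)
}

# Shared steady-state driver on a compiled RHS. Optionally tries a damped
# Newton iteration from `warm` first (used by the calibration objective,
# where consecutive candidates have nearby steady states), then falls back
# to integrate-then-polish over geometrically growing horizons.
steady_solve <- function(rhs, tol, init, t_max = 1e8, warm = NULL) {
  if (!is.null(warm)) {
    y <- newton_polish(rhs, pmax(warm, 0), tol)
    if (!is.null(y))
      return(list(y = y, residual = max(abs(rhs(y))), converged = TRUE,
                  t_reached = 0))
  }
  y <- init
  t_reached <- 0
  converged <- FALSE
  if (max(abs(rhs(y))) <= tol)
    return(list(y = y, residual = max(abs(rhs(y))), converged = TRUE,
                t_reached = 0))
  horizon <- 1e3
  ode_fun <- function(t, yy, parms) list(rhs(yy))
  while (t_reached < t_max) {
    out <- deSolve::lsoda(y, c(0, horizon), ode_fun, parms = NULL,
                          rtol = 1e-8, atol = 1e-8)
    if (attr(out, "istate")[1] < 0) break
    y <- pmax(out[nrow(out), -1], 0)
    t_reached <- t_reached + horizon
    horizon <- horizon * 10
    polished <- newton_polish(rhs, y, tol)
    if (!is.null(polished)) {
      y <- polished
      converged <- TRUE
      break
    }
    if (max(abs(rhs(y))) <= tol) {
      converged <- TRUE
      break
    }
  }
  res <- max(abs(rhs(y)))
  list(y = y, residual = res, converged = converged && res <= tol,
       t_reached = t_reached)
}

# Damped Newton iteration on the RHS; returns the polished non-negative state
# or NULL if it fails to reach tol.
newton_polish <- function(rhs, y, tol, max_iter = 30L) {
  n <- length(y)
  fy <- rhs(y)
  for (iter in seq_len(max_iter)) {
    if (max(abs(fy)) <= tol * 0.1) return(pmax(y, 0))
    J <- matrix(0, n, n)
    h <- pmax(abs(y), 1e-8) * 1e-6
    for (j in seq_len(n)) {
      yp <- y; yp[j] <- y[j] + h[j]
      ym <- y; ym[j] <- max(y[j] - h[j], 0)
      J[, j] <- (rhs(yp) - rhs(ym)) / (yp[j] - ym[j])
    }
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    improved <- FALSE
    for (k in 1:12) {
      cand <- y + lambda * step
      if (all(cand >= 0)) {
        fc <- rhs(cand)
        if (all(is.finite(fc)) && max(abs(fc)) < max(abs(fy))) {
          y <- cand; fy <- fc; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) return(NULL)
  }
  if (max(abs(fy)) <= tol * 0.1) pmax(y, 0) else NULL
}

new_steady <- function(conc, residual, converged, t_reached, condition) {
  structure(list(concentrations = setNames(as.numeric(conc), EICO_STATE),
                 residual_norm = residual, converged = converged,
                 t_reached = t_reached, condition = condition),
            class = "eico_steady")
}

#' @export
print.eico_steady <- function(x, ...) {
  cat(sprintf("<eico_steady> %s / %s  converged = %s  (max |d/dt| = %.3g nM/s, t = %.3g s)\n",
              x$condition$strain, x$condition$treatment, x$converged,
              x$residual_norm, x$t_reached))
  print(signif(x$concentrations, 4))
  invisible(x)
}

#' Steady state of a strain/treatment condition
#'
#' Applies the condition's activity ratios and PC clamp to the model and
#' solves for the steady state; the input model is left unmodified.
#'
#' @inheritParams steady_state
#' @param strain A strain id (`"AJ"`, `"B6"`, `"PWD"`) or an
#'   [eico_condition()].
#' @param treatment `"control"` or `"ddc"` (ignored when `strain` is a
#'   condition object).
#' @return An `eico_steady` object.
#' @export
simulate_condition <- function(model, strain, treatment = "control",
                               tol = 1e-6, ...) {
  condition <- get_condition(strain, treatment)
  steady_state(model, condition, tol = tol, ...)
}

#' DDC-versus-control fold changes
#'
#' Per-metabolite concentration ratios between two converged steady states,
#' classified against a symmetric fold-change band: `up` when
#' ratio >= `threshold`, `down` when ratio <= 1/`threshold`, otherwise
#' `unchanged`.
#'
#' @param control,ddc Converged `eico_steady` objects.
#' @param threshold Classification threshold (default 1.5, the study's
#'   effect-size convention).
#' @return A data.frame of class `eico_foldchange` with columns `metabolite`,
#'   `control_nM`, `ddc_nM`, `ratio`, `classification`. Metabolites with a
#'   zero control concentration get `NA` ratio and classification.
#' @export
fold_changes <- function(control, ddc, threshold = 1.5) {
  stopifnot(inherits(control, "eico_steady"), inherits(ddc, "eico_steady"))
  if (!control$converged || !ddc$converged)
    stop("fold_changes requires converged steady states (control: ",
         control$converged, ", ddc: ", ddc$converged, ")")
  if (threshold <= 1) stop("threshold must be > 1")
  cc <- control$concentrations
  dd <- ddc$concentrations
  ratio <- ifelse(cc > 0, dd / cc, NA_real_)
  cls <- ifelse(is.na(ratio), NA_character_,
         ifelse(ratio >= threshold, "up",
         ifelse(ratio <= 1 / threshold, "down", "unchanged")))
  structure(data.frame(metabolite = EICO_STATE, control_nM = unname(cc),
                       ddc_nM = unname(dd), ratio = unname(ratio),
                       classification = unname(cls),
                       stringsAsFactors = FALSE),
            class = c("eico_foldchange", "data.frame"),
            threshold = threshold)
}

#' Simulate a strain end to end
#'
#' Convenience wrapper: control and DDC steady states plus the fold-change
#' table for one strain.
#'
#' @inheritParams simulate_condition
#' @param threshold Fold-change classification threshold.
#' @param conditions Optional condition list ([eico_conditions()] schema).
#' @return List with `control`, `ddc` (`eico_steady`) and `fold_changes`.
#' @export
simulate_strain <- function(model, strain, threshold = 1.5, tol = 1e-6,
                            conditions = NULL) {
  if (is.null(conditions)) conditions <- eico_conditions()
  ctrl <- steady_state(model, get_condition(strain, "control", conditions),
                       tol = tol)
  ddc <- steady_state(model, get_condition(strain, "ddc", conditions),
                      tol = tol)
  list(control = ctrl, ddc = ddc,
       fold_changes = fold_changes(ctrl, ddc, threshold = threshold))
}
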