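#' Revert a subset of enzyme activities to control levels
#'
#' Takes the DDC condition and replaces the activity ratios of the chosen
#' enzymes by their control values (1.0), then solves for the steady state.
#' Only the six activities perturbed by DDC treatment may be reverted
#' (ALOX5AP, GPX, PKCD, PTGS1, PERK, PSTAT3); the measured PC concentration
#' is not an enzyme and stays at its DDC value.
#'
#' @param model An [eico_model()].
#' @param ddc,control The DDC and control [eico_condition()]s of one strain.
#' @param subset Character vector of enzyme ids to revert (may be empty).
#' @param tol Steady-state tolerance (nM/s).
#' @return An `eico_steady` under the partially reverted condition.
#' @export
revert_enzymes <- function(model, ddc, control, subset = character(),
                           tol = 1e-6) {
  stopifnot(inherits(ddc, "eico_condition"), inherits(control, "eico_condition"))
  bad <- setdiff(subset, EICO_SCREEN_ENZYMES)
  if (length(bad))
    stop("the reversion screen is defined only on {",
         paste(EICO_SCREEN_ENZYMES, collapse = ", "), "}; got: ",
         paste(bad, collapse = ", "))
  ratios <- ddc$ratios
  ratios[subset] <- control$ratios[subset]
  cond <- eico_condition(ddc$strain, "ddc", ratios = ratios,
                         pc_um = ddc$pc_um)
  steady_state(model, cond, tol = tol)
}

all_enzyme_subsets <- function(enzymes = EICO_SCREEN_ENZYMES) {
  n <- length(enzymes)
  out <- list()
  for (mask in seq_len(2^n - 1))
    out[[mask]] <- enzymes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  out
}

#' Enzyme-reversion screen
#'
#' For each enzyme subset, reverts those activities to control levels in the
#' DDC condition and asks which metabolites return to the reference state
#' (the fully normal condition, all enzyme activities at control values). A
#' metabolite is `restored` when its steady-state concentration lies within
#' `reference_tolerance` (relative) of the reference concentration;
#' `overall_restored` requires every reported metabolite to be restored.
#'
#' @inheritParams revert_enzymes
#' @param subsets List of enzyme-id vectors; default: all 63 non-empty
#'   subsets of the six perturbed activities.
#' @param reference_tolerance Relative deviation counted as restored
#'   (default 0.1).
#' @param metabolites Reported metabolites (default: all non-fixed species).
#' @return Object of class `eico_reversion`: data.frame with one row per
#'   subset x metabolite (`subset`, `metabolite`, `concentration_nM`,
#'   `reference_nM`, `rel_deviation`, `restored`), with an `overall`
#'   data.frame attribute (`subset`, `converged`, `overall_restored`).
#' @export
reversion_screen <- function(model, ddc, control,
                             subsets = all_enzyme_subsets(),
                             reference_tolerance = 0.1,
                             metabolites = EICO_STATE,
                             tol = 1e-6) {
  if (!length(subsets)) stop("subsets must be a non-empty list")
  reference <- steady_state(model, control, tol = tol)
  if (!reference$converged) stop("reference state did not converge")
  ref <- reference$concentrations[metabolites]
  rows <- list(); overall <- list()
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    key <- if (length(sub)) paste(sort(sub), collapse = "+") else "(none)"
    ss <- tryCatch(revert_enzymes(model, ddc, control, sub, tol = tol),
                   error = function(e) NULL)
    if (is.null(ss) || !ss$converged) {
      overall[[i]] <- data.frame(subset = key, converged = FALSE,
                                 overall_restored = NA)
      next
    }
    conc <- ss$concentrations[metabolites]
    dev <- ifelse(ref > 0, abs(conc - ref) / ref, as.numeric(conc != ref))
    restored <- dev <= reference_tolerance
    rows[[i]] <- data.frame(subset = key, metabolite = metabolites,
                            concentration_nM = unname(conc),
                            reference_nM = unname(ref),
                            rel_deviation = unname(dev),
                            restored = unname(restored),
                            stringsAsFactors = FALSE)
    overall[[i]] <- data.frame(subset = key, converged = TRUE,
                               overall_restored = all(restored))
  }
  res <- do.call(rbind, rows)
  structure(res, class = c("eico_reversion", "data.frame"),
            overall = do.call(rbind, overall),
            reference = reference$concentrations,
            reference_tolerance = reference_tolerance)
}

#' Which subsets restore the DDC state?
#'
#' @param x An [reversion_screen()] result.
#' @return data.frame with `subset`, `converged`, `overall_restored`.
#' @export
restored_subsets <- function(x) {
  stopifnot(inherits(x, "eico_reversion"))
  attr(x, "overall")
}

#' In-silico drug-inhibition screen
#'
#' Divides the activity ratio of each enzyme in turn by each inhibition
#' factor (3-, 6-, 9-fold knockdowns by default), recomputes the steady state
#' of the DDC condition, and classifies every metabolite against the
#' unperturbed DDC steady state using the symmetric fold-change band of
#' [fold_changes()].
#'
#' @inheritParams revert_enzymes
#' @param enzymes Enzymes to knock down (default: the six DDC-perturbed
#'   activities).
#' @param factors Inhibition factors (> 1; default `c(3, 6, 9)`).
#' @param threshold Classification threshold (default 1.5).
#' @return Object of class `eico_drugscreen`: long data.frame (`enzyme`,
#'   `factor`, `metabolite`, `baseline_nM`, `inhibited_nM`, `ratio`,
#'   `classification`).
#' @export
drug_screen <- function(model, ddc, enzymes = EICO_SCREEN_ENZYMES,
                        factors = c(3, 6, 9), threshold = 1.5, tol = 1e-6) {
  stopifnot(inherits(ddc, "eico_condition"))
  if (any(factors < 1)) stop("inhibition factors must be >= 1")
  bad <- setdiff(enzymes, EICO_ENZYMES)
  if (length(bad)) stop("unknown enzyme(s): ", paste(bad, collapse = ", "))
  baseline <- steady_state(model, ddc, tol = tol)
  if (!baseline$converged) stop("unperturbed DDC state did not converge")
  base <- baseline$concentrations
  rows <- list()
  for (e in enzymes) {
    for (k in factors) {
      ratios <- ddc$ratios
      ratios[e] <- ratios[e] / k
      cond <- eico_condition(ddc$strain, "ddc", ratios = ratios,
                             pc_um = ddc$pc_um)
      ss <- steady_state(model, cond, tol = tol)
      if (!ss$converged)
        stop("knockdown ", e, "/", k, " did not converge")
      ratio <- ifelse(base > 0, ss$concentrations / base, NA_real_)
      cls <- ifelse(is.na(ratio), NA_character_,
             ifelse(ratio >= threshold, "up",
             ifelse(ratio <= 1 / threshold, "down", "unchanged")))
      rows[[length(rows) + 1L]] <-
        data.frame(enzyme = e, factor = k, metabolite = EICO_STATE,
                   baseline_nM = unname(base),
                   inhibited_nM = unname(ss$concentrations),
                   ratio = unname(ratio), classification = unname(cls),
                   stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("eico_drugscreen", "data.frame"),
            threshold = threshold)
}
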