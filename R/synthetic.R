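#' Generate a synthetic ground-truth scenario
#'
#' Draws a ground-truth parameterization of the model (the shipped constants
#' jittered log-normally) together with the six strain/treatment conditions,
#' for end-to-end testing of calibration and the perturbation screens without
#' any external data. The literature-sourced R1 Michaelis constant is not
#' jittered (it is pinned during calibration too). Regeneration from the same
#' seed is bit-identical.
#'
#' @param seed Integer RNG seed.
#' @param perturbation_scale Log-normal sdlog of the parameter jitter
#'   (0 gives the shipped constants exactly).
#' @param condition_scale Optional log-normal jitter of the DDC activity
#'   ratios (default 0: the tabulated conditions).
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise (default 0.2).
#' @param replicates Replicates per strain/condition (default 3, the study
#'   design).
#' @param model Base model whose constants are jittered.
#' @return Object of class `eico_scenario`: `seed`, `true_parameters`
#'   (named vector), `model` (with the true parameters), `conditions`
#'   (list of six [eico_condition()]), `noise_cv`, `replicates`.
#' @export
generate_scenario <- function(seed, perturbation_scale = 0.2,
                              condition_scale = 0, noise_cv = 0.2,
                              replicates = 3L, model = eico_model()) {
  if (perturbation_scale < 0 || condition_scale < 0)
    stop("jitter scales must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (replicates < 1L) stop("replicates must be >= 1")
  base <- get_constants(model)
  jitter_ids <- setdiff(names(base), "R1.k_m")
  conditions <- eico_conditions()
  scen <- with_preserved_seed(seed, {
    truth <- base
    if (perturbation_scale > 0)
      truth[jitter_ids] <- truth[jitter_ids] *
        rlnorm(length(jitter_ids), 0, perturbation_scale)
    if (condition_scale > 0) {
      conditions <- lapply(conditions, function(cond) {
        if (cond$treatment == "control") return(cond)
        r <- cond$ratios * rlnorm(length(cond$ratios), 0, condition_scale)
        r["PLA2"] <- r["PERK"]  # the two entries are one measurement
        eico_condition(cond$strain, "ddc", r, cond$pc_um)
      })
    }
    list(truth = truth, conditions = conditions)
  })
  structure(list(seed = as.integer(seed),
                 true_parameters = scen$truth,
                 model = set_constants(model, scen$truth),
                 conditions = scen$conditions,
                 noise_cv = noise_cv, replicates = as.integer(replicates)),
            class = "eico_scenario")
}

#' @export
print.eico_scenario <- function(x, ...) {
  cat(sprintf("<eico_scenario> seed %d, %d conditions, noise CV %.2f, %d replicates\n",
              x$seed, length(x$conditions), x$noise_cv, x$replicates))
  invisible(x)
}

# Draw `replicates` log-normal measurements around steady-state
# concentrations (expectation preserved, CV = noise_cv) and summarize as
# median and median absolute deviation. noise_cv = 0 returns the steady
# states exactly.
draw_measurements <- function(strain, treatment, conc, noise_cv, replicates) {
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- lapply(EICO_STATE, function(mid) {
    mu <- conc[[mid]]
    reps <- if (noise_cv == 0 || mu == 0) rep(mu, replicates)
            else rlnorm(replicates, log(mu) - sdlog^2 / 2, sdlog)
    data.frame(strain = strain, treatment = treatment, metabolite = mid,
               median_nM = median(reps), mad_nM = mad(reps),
               n = replicates, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a metabolite measurement table
#'
#' Computes the ground-truth steady state of every scenario condition and
#' draws replicate measurements log-normally around it with the scenario's
#' coefficient of variation, reporting per-group median and median absolute
#' deviation (the summary convention of the mass-spectrometry data the
#' pipeline consumes).
#'
#' @param scenario An [generate_scenario()] result.
#' @param tol Steady-state tolerance.
#' @return data.frame of class `eico_measurements`: `strain`, `treatment`,
#'   `metabolite`, `median_nM`, `mad_nM`, `n`.
#' @export
simulate_measurements <- function(scenario, tol = 1e-6) {
  stopifnot(inherits(scenario, "eico_scenario"))
  steadies <- lapply(scenario$conditions, function(cond) {
    ss <- steady_state(scenario$model, cond, tol = tol)
    if (!ss$converged)
      stop("scenario rejected: condition ", cond$strain, "/",
           cond$treatment, " did not reach steady state")
    ss
  })
  tab <- with_preserved_seed(scenario$seed + 1L, {
    do.call(rbind, lapply(names(steadies), function(key) {
      cond <- scenario$conditions[[key]]
      draw_measurements(cond$strain, cond$treatment,
                        steadies[[key]]$concentrations,
                        scenario$noise_cv, scenario$replicates)
    }))
  })
  rownames(tab) <- NULL
  class(tab) <- c("eico_measurements", "data.frame")
  tab
}

#' Synthetic omics tables for the expression-mapping module
#'
#' Emits expression, protein and PC tables that reproduce the scenario's
#' conditions exactly when passed through [build_condition()], including
#' decoy Gpx isoenzyme rows (the designated Gpx gene carries the smallest
#' adjusted p-value) and the low-expressed non-differential genes
#' (Pla2g4a, Alox5, Alox15, Ptgds) so the isoenzyme-selection and
#' non-differential rules are exercised.
#'
#' @param scenario An [generate_scenario()] result.
#' @param base_rpkm Expression level given to differential genes in the
#'   control state (RPKM).
#' @return List with data.frames `expression`, `protein`, `pc`.
#' @export
generate_omics_tables <- function(scenario, base_rpkm = 50) {
  stopifnot(inherits(scenario, "eico_scenario"))
  expr <- list(); prot <- list(); pcs <- list()
  decoys <- data.frame(
    gene = c("Gpx1", "Gpx2", "Gpx6", "Gpx7"),
    rpkm = c(120, 3, 0.4, 8),
    padj = c(2e-3, 0.4, 0.9, 0.07))
  for (strain in EICO_STRAINS) {
    ddc <- scenario$conditions[[paste0(strain, ".ddc")]]
    ctrl <- scenario$conditions[[paste0(strain, ".control")]]
    r <- ddc$ratios
    gene_rows <- rbind(
      data.frame(gene = "Ptgs1", strain = strain, control_rpkm = base_rpkm,
                 ddc_rpkm = base_rpkm * r[["PTGS1"]], padj = 1e-12),
      data.frame(gene = "Alox5ap", strain = strain, control_rpkm = base_rpkm,
                 ddc_rpkm = base_rpkm * r[["ALOX5AP"]], padj = 1e-10),
      data.frame(gene = "Prkcd", strain = strain, control_rpkm = base_rpkm,
                 ddc_rpkm = base_rpkm * r[["PKCD"]], padj = 1e-15),
      data.frame(gene = "Gpx3", strain = strain, control_rpkm = 200,
                 ddc_rpkm = 200 * r[["GPX"]], padj = 2.66e-41),
      data.frame(gene = decoys$gene, strain = strain,
                 control_rpkm = decoys$rpkm, ddc_rpkm = decoys$rpkm,
                 padj = decoys$padj),
      # low-expressed, non-differential pathway genes
      data.frame(gene = c("Pla2g4a", "Alox5", "Alox15"), strain = strain,
                 control_rpkm = 0.5, ddc_rpkm = 0.5,
                 padj = c(0.3, 0.13, 0.62)),
      data.frame(gene = "Ptgds", strain = strain, control_rpkm = 30,
                 ddc_rpkm = 30, padj = 0.64))
    expr[[strain]] <- gene_rows
    prot[[strain]] <- data.frame(
      analyte = c("p-ERK", "p-STAT3"), strain = strain,
      ratio = c(r[["PERK"]], r[["PSTAT3"]]))
    pcs[[strain]] <- data.frame(
      strain = strain, treatment = c("control", "ddc"),
      pc_um = c(ctrl$pc_um, ddc$pc_um))
  }
  out <- list(expression = do.call(rbind, expr),
              protein = do.call(rbind, prot),
              pc = do.call(rbind, pcs))
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  out
}

#' Build the calibration spec of a scenario
#'
#' Convenience: turns a scenario plus a measurement table into the
#' [objective_spec()] for one strain (median concentrations as the
#' experimental values).
#'
#' @param scenario An [generate_scenario()] result.
#' @param measurements A [simulate_measurements()] table (or compatible).
#' @param strain Training strain (default `"B6"`).
#' @param model Model to calibrate (default: shipped constants, i.e. the
#'   truth is *not* handed to the optimizer when the scenario is jittered).
#' @param ... Passed to [objective_spec()].
#' @return An `eico_objective_spec`.
#' @export
scenario_spec <- function(scenario, measurements, strain = "B6",
                          model = eico_model(), ...) {
  pull <- function(tr) {
    sub <- measurements[measurements$strain == strain &
                        measurements$treatment == tr, ]
    setNames(sub$median_nM, sub$metabolite)
  }
  objective_spec(model,
                 control = scenario$conditions[[paste0(strain, ".control")]],
                 ddc = scenario$conditions[[paste0(strain, ".ddc")]],
                 experimental_control = pull("control"),
                 experimental_ddc = pull("ddc"), ...)
}
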