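# Shared fixtures: the paper-constants model and Table-style conditions are
# deterministic, so build them once per test run.
the <- new.env(parent = emptyenv())

base_model <- function() {
  if (is.null(the$model)) the$model <- eico_model()
  the$model
}

base_conditions <- function() {
  if (is.null(the$conditions)) the$conditions <- eico_conditions()
  the$conditions
}

cond_of <- function(strain, treatment) {
  base_conditions()[[paste(strain, treatment, sep = ".")]]
}

# Cache steady states of the six tabulated conditions across test files.
cached_steady <- function(strain, treatment, tol = 1e-6) {
  key <- paste(strain, treatment, sep = ".")
  if (is.null(the$steady)) the$steady <- list()
  if (is.null(the$steady[[key]]))
    the$steady[[key]] <- steady_state(base_model(), cond_of(strain, treatment),
                                      tol = tol)
  the$steady[[key]]
}

SPECIES7 <- c("AA", "5-HPETE", "LTA4", "15-HPETE", "15-HETE", "PGH2", "PGD2")

# Independent brute-force oracle: the twelve rate laws written out one by
# one from the constants table (no code shared with the package internals),
# integrated with fixed-step explicit Euler.
oracle_rhs_fn <- function(constants, ratios, pc_nM) {
  p <- stats::setNames(constants$value,
                       paste(constants$reaction, constants$parameter, sep = "."))
  u <- ratios
  function(y) {
    AA <- y[["AA"]]; H5 <- y[["5-HPETE"]]; LTA4 <- y[["LTA4"]]
    H15 <- y[["15-HPETE"]]; HE15 <- y[["15-HETE"]]
    PGH2 <- y[["PGH2"]]; PGD2 <- y[["PGD2"]]
    mm <- function(vmax, act, S, km, I, ki) vmax * act * S / (km * (1 + I / ki) + S)
    v1 <- mm(p["R1.v_max"], u[["PERK"]], pc_nM, p["R1.k_m"], AA, p["R1.k_i"])
    v2 <- mm(p["R2.v_max"], u[["ALOX5"]] * u[["ALOX5AP"]], AA, p["R2.k_m"], H5, p["R2.k_i"])
    v3 <- p["R3.k_cat"] * H5
    v4 <- mm(p["R4.v_max"], u[["ALOX5"]] * u[["ALOX5AP"]], H5, p["R4.k_m"], LTA4, p["R4.k_i"])
    v5 <- p["R5.k_cat"] * LTA4
    v6 <- mm(p["R6.v_max"], u[["ALOX15"]] * u[["PKCD"]] * u[["PSTAT3"]], AA,
             p["R6.k_m"], H15, p["R6.k_i"])
    v7 <- mm(p["R7.v_max"], u[["GPX"]], H15, p["R7.k_m"], HE15, p["R7.k_i"])
    v8 <- p["R8.k_cat"] * HE15
    v9 <- mm(p["R9.v_max"], u[["PTGS1"]], AA, p["R9.k_m"], PGH2, p["R9.k_i"])
    v10 <- p["R10.v_max"] * u[["PTGDS"]] * PGH2
    v11 <- p["R11.k_cat"] * PGD2
    v12 <- p["R12.k_cat"] * AA
    c(AA = v1 - v2 - v6 - v9 - v12,
      "5-HPETE" = v2 - v3 - v4,
      LTA4 = v4 - v5,
      "15-HPETE" = v6 - v7,
      "15-HETE" = v7 - v8,
      PGH2 = v9 - v10,
      PGD2 = v10 - v11)
  }
}

euler_integrate <- function(condition, t_end, dt, init = rep(0, 7),
                            constants = eico_constants()) {
  rhs <- oracle_rhs_fn(constants, condition$ratios, condition$pc_um * 1000)
  y <- stats::setNames(as.numeric(init), SPECIES7)
  for (i in seq_len(round(t_end / dt))) {
    y <- pmax(y + dt * unname(rhs(y)), 0)
    names(y) <- SPECIES7
  }
  y
}
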