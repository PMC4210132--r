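#' Build the arachidonic-acid/eicosanoid kinetic model
#'
#' Constructs the twelve-reaction network: release of arachidonic acid (AA)
#' from phosphatidylcholine (PC) by PLA2 under p-ERK control (R1), the
#' 5-lipoxygenase branch to 5-HPETE and leukotriene A4 (R2, R4), the
#' 15-lipoxygenase branch to 15-HPETE and 15-HETE (R6, R7), the prostaglandin
#' branch to PGH2 and PGD2 (R9, R10), and five first-order degradation sinks
#' (R3, R5, R8, R11, R12). PC is a clamped boundary species; every other
#' metabolite is a state variable of the induced ODE system.
#'
#' Enzyme-catalysed reactions use irreversible Michaelis-Menten kinetics with
#' competitive product/feedback inhibition,
#' \deqn{v = V_{max} \prod_j u_j \frac{[S]}{K_m (1 + [I]/K_i) + [S]},}
#' where the \eqn{u_j} are unitless activity ratios (1 in the control state,
#' the DDC/control fold change otherwise). Enzymes enter as these
#' multipliers on a 1.0 nM basal concentration folded into \eqn{V_{max}},
#' which is why the tabulated \eqn{V_{max}} unit exponent equals the number
#' of activators of the reaction. R10 is linear in its substrate,
#' \eqn{v = V_{max}\, u_{PTGDS} [PGH2]}, and the sinks are first-order decays
#' \eqn{v = k_{cat} [S]}.
#'
#' Two structural choices that the published material leaves ambiguous are
#' exposed as switches and recorded in the returned object:
#' \describe{
#'   \item{`r7_activator`}{The enzyme converting 15-HPETE to 15-HETE. The
#'     network diagram and the drug-screen narrative attribute R7 to
#'     glutathione peroxidase (GPX, the default, and the only choice under
#'     which GPX perturbations can act at all); the parameter table names
#'     ALOX15 instead.}
#'   \item{`r1_scaling`}{Whether R1 is scaled once (`"single"`, default) or
#'     twice (`"double"`) by the p-ERK fold change. The tabulated PLA2 row
#'     *is* the p-ERK RPPA ratio (the PLA2 gene itself, Pla2g4a, is expressed
#'     below 1 RPKM and not differentially), so `"single"` applies that
#'     measurement once through the PERK activity, whereas `"double"`
#'     multiplies the PLA2 and PERK entries and thereby squares it.}
#' }
#'
#' @param constants Constants table as returned by [eico_constants()].
#' @param r7_activator `"GPX"` (default) or `"ALOX15"`.
#' @param r1_scaling `"single"` (default) or `"double"`.
#' @return An object of class `eico_model` with elements `metabolites`,
#'   `reactions`, `activities`, `constants`, `r7_activator`, `r1_scaling`.
#' @examples
#' m <- eico_model()
#' m
#' @export
eico_model <- function(constants = eico_constants(),
                       r7_activator = c("GPX", "ALOX15"),
                       r1_scaling = c("single", "double")) {
  r7_activator <- match.arg(r7_activator)
  r1_scaling <- match.arg(r1_scaling)

  metabolites <- data.frame(
    id = EICO_SPECIES,
    name = c("phosphatidylcholine", "arachidonic acid",
             "5-hydroperoxyeicosatetraenoic acid", "leukotriene A4",
             "15-hydroperoxyeicosatetraenoic acid",
             "15-hydroxyeicosatetraenoic acid",
             "prostaglandin H2", "prostaglandin D2"),
    fixed = EICO_SPECIES == "PC",
    stringsAsFactors = FALSE
  )

  topo <- list(
    R1  = list(substrate = "PC",       product = "AA",
               activators = c("PLA2", "PERK"),       inhibitor = "AA"),
    R2  = list(substrate = "AA",       product = "5-HPETE",
               activators = c("ALOX5", "ALOX5AP"),   inhibitor = "5-HPETE"),
    R3  = list(substrate = "5-HPETE",  product = NA_character_,
               activators = character(), inhibitor = NA_character_),
    R4  = list(substrate = "5-HPETE",  product = "LTA4",
               activators = c("ALOX5", "ALOX5AP"),   inhibitor = "LTA4"),
    R5  = list(substrate = "LTA4",     product = NA_character_,
               activators = character(), inhibitor = NA_character_),
    R6  = list(substrate = "AA",       product = "15-HPETE",
               activators = c("ALOX15", "PKCD", "PSTAT3"),
               inhibitor = "15-HPETE"),
    R7  = list(substrate = "15-HPETE", product = "15-HETE",
               activators = r7_activator,            inhibitor = "15-HETE"),
    R8  = list(substrate = "15-HETE",  product = NA_character_,
               activators = character(), inhibitor = NA_character_),
    R9  = list(substrate = "AA",       product = "PGH2",
               activators = "PTGS1",                 inhibitor = "PGH2"),
    R10 = list(substrate = "PGH2",     product = "PGD2",
               activators = "PTGDS",                 inhibitor = NA_character_),
    R11 = list(substrate = "PGD2",     product = NA_character_,
               activators = character(), inhibitor = NA_character_),
    R12 = list(substrate = "AA",       product = NA_character_,
               activators = character(), inhibitor = NA_character_)
  )

  reactions <- lapply(names(topo), function(rid) {
    rows <- constants[constants$reaction == rid, , drop = FALSE]
    if (!nrow(rows)) stop("constants table has no rows for reaction ", rid)
    form <- unique(rows$form)
    if (length(form) != 1L)
      stop("inconsistent form for reaction ", rid)
    params <- setNames(rows$value, rows$parameter)
    if (any(!is.finite(params)) || any(params <= 0))
      stop("kinetic constants of ", rid, " must be strictly positive")
    tp <- topo[[rid]]
    scaling <- tp$activators
    if (rid == "R1" && r1_scaling == "single") scaling <- "PERK"
    list(id = rid, substrate = tp$substrate, product = tp$product,
         form = form, params = params,
         param_strings = setNames(rows$value_str, rows$parameter),
         activators = tp$activators, scaling_ids = scaling,
         inhibitor = tp$inhibitor)
  })
  names(reactions) <- names(topo)

  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         activities = data.frame(id = EICO_ENZYMES, basal_nM = 1.0,
                                 stringsAsFactors = FALSE),
         constants = constants,
         r7_activator = r7_activator, r1_scaling = r1_scaling),
    class = "eico_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  mids <- model$metabolites$id
  eids <- model$activities$id
  for (r in model$reactions) {
    ids <- c(r$substrate, if (!is.na(r$product)) r$product,
             if (!is.na(r$inhibitor)) r$inhibitor)
    bad <- setdiff(ids, mids)
    if (length(bad))
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    bad <- setdiff(r$activators, eids)
    if (length(bad))
      stop("reaction ", r$id, " references unknown activity(ies): ",
           paste(bad, collapse = ", "))
  }
  if (sum(model$metabolites$fixed) != 1L || !model$metabolites$fixed[1L])
    stop("exactly one fixed species (PC) is expected")
  invisible(model)
}

#' @export
print.eico_model <- function(x, ...) {
  sinks <- vapply(x$reactions, function(r) is.na(r$product), logical(1))
  cat("<eico_model> arachidonic-acid/eicosanoid metabolism\n")
  cat(sprintf("  %d metabolites (%d clamped: PC), %d reactions (%d sinks), %d activities\n",
              nrow(x$metabolites), sum(x$metabolites$fixed),
              length(x$reactions), sum(sinks), nrow(x$activities)))
  cat(sprintf("  R7 catalysed by %s; R1 %s-scaled by the p-ERK ratio\n",
              x$r7_activator, x$r1_scaling))
  invisible(x)
}

#' Evaluate the flux of one reaction
#'
#' @param reaction One element of `model$reactions`, or a reaction id together
#'   with a `model`.
#' @param concentrations Named numeric vector of metabolite concentrations in
#'   nM (must resolve every id the rate law references; all values >= 0).
#' @param activities Named numeric vector of unitless activity ratios
#'   (all >= 0).
#' @param model Optional [eico_model()] when `reaction` is given as an id.
#' @return Flux in nM/s (non-negative).
#' @examples
#' m <- eico_model()
#' evaluate_rate("R3", c("5-HPETE" = 100), c(), model = m)  # 0.12 nM/s
#' @export
evaluate_rate <- function(reaction, concentrations, activities, model = NULL) {
  if (is.character(reaction)) {
    if (is.null(model)) stop("supply `model` when `reaction` is an id")
    reaction <- model$reactions[[reaction]]
    if (is.null(reaction)) stop("unknown reaction id")
  }
  ids <- c(reaction$substrate, if (!is.na(reaction$inhibitor)) reaction$inhibitor)
  missing_ids <- setdiff(ids, names(concentrations))
  if (length(missing_ids))
    stop("unresolved metabolite id(s): ", paste(missing_ids, collapse = ", "))
  missing_act <- setdiff(reaction$scaling_ids, names(activities))
  if (length(missing_act))
    stop("unresolved activity id(s): ", paste(missing_act, collapse = ", "))
  if (any(concentrations[ids] < 0))
    stop("concentrations must be non-negative")
  u <- if (length(reaction$scaling_ids))
    unname(activities[reaction$scaling_ids]) else numeric()
  if (any(u < 0)) stop("activity ratios must be non-negative")
  S <- unname(concentrations[reaction$substrate])
  p <- reaction$params
  switch(reaction$form,
    decay = p[["k_cat"]] * S,
    linear = p[["v_max"]] * prod(u) * S,
    mm = {
      I <- if (is.na(reaction$inhibitor)) 0
           else unname(concentrations[reaction$inhibitor])
      p[["v_max"]] * prod(u) * S /
        (p[["k_m"]] * (1 + I / p[["k_i"]]) + S)
    },
    stop("unknown rate-law form: ", reaction$form))
}

# Compile model topology + a condition into index arrays for a vectorized
# right-hand side. The kinetic constants enter in a second stage
# (`with_constants`) so that optimizers can swap them cheaply.
compile_condition <- function(model, ratios, pc_nM) {
  state_idx <- setNames(seq_along(EICO_STATE), EICO_STATE)
  rx <- model$reactions
  n <- length(rx)
  is_mm <- vapply(rx, function(r) r$form == "mm", logical(1))
  actprod <- vapply(rx, function(r)
    if (length(r$scaling_ids)) prod(ratios[r$scaling_ids]) else 1, numeric(1))
  # indices into c(pc, y) for substrates and c(0, y) for inhibitors
  s_idx <- vapply(rx, function(r)
    if (r$substrate == "PC") 1L else state_idx[[r$substrate]] + 1L, integer(1))
  i_idx <- vapply(rx, function(r)
    if (is.na(r$inhibitor)) 1L else state_idx[[r$inhibitor]] + 1L, integer(1))
  smat <- matrix(0, length(EICO_STATE), n,
                 dimnames = list(EICO_STATE, names(rx)))
  for (k in seq_len(n)) {
    r <- rx[[k]]
    if (r$substrate != "PC") smat[state_idx[[r$substrate]], k] <- -1
    if (!is.na(r$product)) smat[state_idx[[r$product]], k] <-
      smat[state_idx[[r$product]], k] + 1
  }
  rate_key <- vapply(rx, function(r) paste0(r$id, ".",
    if (r$form == "decay") "k_cat" else "v_max"), character(1))
  km_key <- vapply(rx, function(r)
    if (r$form == "mm") paste0(r$id, ".k_m") else NA_character_, character(1))
  ki_key <- vapply(rx, function(r)
    if (r$form == "mm" && !is.na(r$inhibitor)) paste0(r$id, ".k_i")
    else NA_character_, character(1))

  with_constants <- function(constants) {
    scale <- unname(constants[rate_key]) * actprod
    km <- unname(ifelse(is.na(km_key), 1, constants[km_key]))
    ki <- unname(ifelse(is.na(ki_key), 1, constants[ki_key]))
    fluxes <- function(y) {
      y <- pmax(y, 0)
      S <- c(pc_nM, y)[s_idx]
      I <- c(0, y)[i_idx]
      v <- scale * S
      v[is_mm] <- v[is_mm] / (km[is_mm] * (1 + I[is_mm] / ki[is_mm]) + S[is_mm])
      v
    }
    list(
      fluxes = fluxes,
      rhs = function(y) as.vector(smat %*% fluxes(y))
    )
  }
  list(with_constants = with_constants, smat = smat)
}

# Convenience: function(y) -> list(dy, fluxes) for a fixed model.
compile_rhs <- function(model, ratios, pc_nM) {
  cc <- compile_condition(model, ratios, pc_nM)
  fns <- cc$with_constants(get_constants(model))
  smat <- cc$smat
  function(y) {
    v <- fns$fluxes(y)
    list(dy = as.vector(smat %*% v), fluxes = v)
  }
}

#' ODE right-hand side of the model
#'
#' Time derivative of every non-fixed metabolite (nM/s): the sum of producing
#' fluxes minus the sum of consuming fluxes. The clamped PC species
#' contributes to fluxes but carries no derivative.
#'
#' @param model An [eico_model()].
#' @param state Named (or ordered) numeric vector over the seven non-fixed
#'   metabolites, in nM.
#' @param condition An [eico_condition()] supplying activity ratios and the
#'   PC clamp.
#' @return Named numeric vector of derivatives in nM/s.
#' @export
eico_rhs <- function(model, state, condition) {
  if (length(state) != length(EICO_STATE))
    stop("state must have length ", length(EICO_STATE),
         " (one entry per non-fixed metabolite)")
  if (any(state < 0)) stop("state entries must be non-negative")
  if (!is.null(names(state))) state <- state[EICO_STATE]
  f <- compile_rhs(model, condition$ratios, condition$pc_um * 1000)
  setNames(f(as.numeric(state))$dy, EICO_STATE)
}

#' Reaction fluxes at a given state
#'
#' @inheritParams eico_rhs
#' @return Named numeric vector of the twelve reaction fluxes in nM/s.
#' @export
eico_fluxes <- function(model, state, condition) {
  if (!is.null(names(state))) state <- state[EICO_STATE]
  f <- compile_rhs(model, condition$ratios, condition$pc_um * 1000)
  setNames(f(as.numeric(state))$fluxes, names(model$reactions))
}

#' Override kinetic constants of a model
#'
#' @param model An [eico_model()].
#' @param par Named numeric vector, names of the form `"R2.v_max"`,
#'   `"R7.k_i"`, `"R11.k_cat"`.
#' @return A new `eico_model` with the constants replaced (the input model is
#'   unmodified).
#' @export
set_constants <- function(model, par) {
  if (is.null(names(par)) || any(!nzchar(names(par))))
    stop("`par` must be a fully named numeric vector")
  constants <- model$constants
  for (nm in names(par)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("bad parameter name (want \"R<k>.<parameter>\"): ", nm)
    i <- which(constants$reaction == parts[1] & constants$parameter == parts[2])
    if (length(i) != 1L) stop("unknown parameter: ", nm)
    if (!is.finite(par[[nm]]) || par[[nm]] <= 0)
      stop("kinetic constants must be strictly positive: ", nm)
    constants$value[i] <- par[[nm]]
    constants$value_str[i] <- format(par[[nm]], digits = 17, scientific = FALSE,
                                     trim = TRUE)
  }
  eico_model(constants, r7_activator = model$r7_activator,
             r1_scaling = model$r1_scaling)
}

#' Extract kinetic constants as a named vector
#'
#' @param model An [eico_model()].
#' @return Named numeric vector (`"R1.v_max"`, ...).
#' @export
get_constants <- function(model) {
  with(model$constants, setNames(value, paste(reaction, parameter, sep = ".")))
}
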