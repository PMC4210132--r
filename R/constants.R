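#' Kinetic constants of the arachidonic-acid/eicosanoid model
#'
#' Reads the versioned constants table shipped with the package (or a
#' user-supplied file with the same schema): one row per kinetic constant with
#' columns `reaction`, `form`, `parameter`, `value`, `unit`. Values are kept
#' both as numerics and as the original decimal strings so that write/read
#' round trips are bit-identical.
#'
#' @param path Path to a constants TSV/CSV; `NULL` for the shipped table.
#' @return A data.frame with columns `reaction`, `form`, `parameter`,
#'   `value` (numeric), `value_str` (character, as printed) and `unit`.
#' @export
eico_constants <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kinetic_constants.tsv", package = "eicosim")
  tab <- read_table(path, schema = "constants")
  tab
}

#' Strain/treatment conditions of the model
#'
#' The enzyme activity ratios and phosphatidylcholine (PC) concentrations of
#' the three mouse strains (AJ, B6, PWD) under control and DDC treatment.
#' Control conditions carry all ratios at 1; DDC ratios are fold changes of
#' DDC-treated over control expression (gene level) or protein level (p-ERK,
#' p-STAT3). PC is a measured concentration in uM.
#'
#' @param path Path to a conditions TSV/CSV; `NULL` for the shipped table.
#' @return A named list of six [eico_condition] objects
#'   (`"AJ.control"`, `"AJ.ddc"`, ...).
#' @export
eico_conditions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "strain_conditions.tsv", package = "eicosim")
  tab <- read_table(path, schema = "conditions")
  conditions_from_table(tab)
}

#' Build the list of conditions from a long-format table
#'
#' @param tab data.frame with columns `strain`, `treatment`, `symbol`,
#'   `value`, `unit` (enzyme rows in unit `ratio`, the PC row in `uM`).
#' @return Named list of [eico_condition] objects keyed `strain.treatment`.
#' @export
conditions_from_table <- function(tab) {
  out <- list()
  for (s in unique(tab$strain)) {
    for (tr in unique(tab$treatment[tab$strain == s])) {
      sub <- tab[tab$strain == s & tab$treatment == tr, ]
      pc <- sub$value[sub$symbol == "PC"]
      if (length(pc) != 1L)
        stop("condition ", s, "/", tr, ": expected exactly one PC row")
      enz <- sub[sub$symbol != "PC", ]
      ratios <- setNames(enz$value, enz$symbol)
      out[[paste(s, tr, sep = ".")]] <-
        eico_condition(s, tr, ratios = ratios, pc_um = pc)
    }
  }
  out
}

#' A single strain-by-treatment condition
#'
#' @param strain One of `"AJ"`, `"B6"`, `"PWD"`.
#' @param treatment `"control"` or `"ddc"`.
#' @param ratios Named numeric vector of unitless activity ratios for all ten
#'   enzymes/regulators. For a control condition every ratio must be exactly 1.
#' @param pc_um Clamped phosphatidylcholine concentration in uM (converted to
#'   nM internally at simulation time).
#' @return An object of class `eico_condition`.
#' @export
eico_condition <- function(strain, treatment, ratios, pc_um) {
  strain <- match.arg(strain, EICO_STRAINS)
  treatment <- match.arg(treatment, c("control", "ddc"))
  missing_ids <- setdiff(EICO_ENZYMES, names(ratios))
  if (length(missing_ids))
    stop("condition is missing activity ratios for: ",
         paste(missing_ids, collapse = ", "))
  ratios <- ratios[EICO_ENZYMES]
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("all activity ratios must be finite and > 0")
  if (treatment == "control" && any(ratios != 1))
    stop("control conditions must have all activity ratios equal to 1")
  if (!is.finite(pc_um) || pc_um < 0)
    stop("pc_um must be a non-negative number")
  structure(list(strain = strain, treatment = treatment,
                 ratios = ratios, pc_um = pc_um),
            class = "eico_condition")
}

#' @export
print.eico_condition <- function(x, ...) {
  cat(sprintf("<eico_condition> %s / %s  (PC = %g uM)\n",
              x$strain, x$treatment, x$pc_um))
  print(round(x$ratios, 3))
  invisible(x)
}

# Look up one of the six shipped conditions.
get_condition <- function(strain, treatment, conditions = NULL) {
  if (inherits(strain, "eico_condition")) return(strain)
  if (is.null(conditions)) conditions <- eico_conditions()
  key <- paste(match.arg(strain, EICO_STRAINS),
               match.arg(treatment, c("control", "ddc")), sep = ".")
  cond <- conditions[[key]]
  if (is.null(cond)) stop("unknown condition: ", key)
  cond
}
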