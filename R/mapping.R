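# Gene symbols behind each modelled activity. GPX is approximated by a
# family of isoenzymes and resolved per data set by select_isoenzyme();
# PERK and PSTAT3 come from RPPA protein ratios, not from expression.
EICO_GENE_MAP <- list(
  PTGS1 = "Ptgs1", ALOX5AP = "Alox5ap", PKCD = "Prkcd",
  PLA2 = "Pla2g4a", ALOX5 = "Alox5", ALOX15 = "Alox15", PTGDS = "Ptgds"
)
EICO_GPX_PATTERN <- "^Gpx"

#' Pick the isoenzyme that represents a reaction
#'
#' When several isoenzymes can catalyse the same reaction, the most
#' significantly differentially expressed gene is chosen (smallest adjusted
#' p-value); ties are broken by higher mean expression, then by alphabetical
#' gene symbol.
#'
#' @param candidates data.frame with columns `gene`, `mean_rpkm`, `padj`.
#' @param significance_cutoff Unused for selection itself (the winner is the
#'   minimum p-value regardless); kept so callers can log whether the winner
#'   is actually significant.
#' @return The selected gene symbol (with the selection logged as a message).
#' @export
select_isoenzyme <- function(candidates, significance_cutoff = 0.05) {
  if (!is.data.frame(candidates) || !nrow(candidates))
    stop("candidates must be a non-empty data.frame")
  need <- c("gene", "mean_rpkm", "padj")
  missing_cols <- setdiff(need, names(candidates))
  if (length(missing_cols))
    stop("candidates is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(candidates$padj < 0 | candidates$padj > 1))
    stop("padj must lie in [0, 1]")
  if (any(candidates$mean_rpkm < 0)) stop("mean_rpkm must be >= 0")
  ord <- order(candidates$padj, -candidates$mean_rpkm, candidates$gene)
  winner <- candidates$gene[ord[1]]
  eico_log("INFO", sprintf(
    "isoenzyme selection: %s (padj = %.3g, mean %.3g RPKM%s) out of {%s}",
    winner, candidates$padj[ord[1]], candidates$mean_rpkm[ord[1]],
    if (candidates$padj[ord[1]] <= significance_cutoff) ""
    else ", not significant",
    paste(sort(candidates$gene), collapse = ", ")))
  winner
}

#' Treated-over-control activity ratio
#'
#' @param treated_value,control_value Expression or protein levels
#'   (RPKM or arbitrary consistent units).
#' @return `treated_value / control_value`; if the control value is not
#'   positive the gene is unmappable and the ratio falls back to 1 with a
#'   warning (non-differential assumption).
#' @export
activity_ratio <- function(treated_value, control_value) {
  if (!is.finite(control_value) || control_value <= 0) {
    warning("control value is not positive; falling back to ratio 1")
    return(1)
  }
  treated_value / control_value
}

#' Build a strain condition from omics tables
#'
#' Maps expression, protein and phosphatidylcholine tables onto the ten
#' activity ratios of a [eico_condition()]:
#' PTGS1 <- Ptgs1, ALOX5AP <- Alox5ap, PKCD <- Prkcd, GPX <- the selected Gpx
#' isoenzyme, PERK and PSTAT3 <- the p-ERK / p-STAT3 RPPA ratios, and the
#' low-expressed, non-differential genes (Pla2g4a, Alox5, Alox15, Ptgds)
#' fixed at 1. The PLA2 activity entry carries the p-ERK ratio, mirroring
#' the initial-value convention of the model (PLA2 release activity is driven
#' by ERK phosphorylation; the PLA2 gene itself is not differential). Control
#' requests return all ratios at exactly 1.
#'
#' @param expression data.frame: `gene`, `strain`, `control_rpkm`,
#'   `ddc_rpkm`, `padj`.
#' @param protein data.frame: `analyte` (`"p-ERK"`, `"p-STAT3"`), `strain`,
#'   `ratio` (DDC/control).
#' @param pc data.frame: `strain`, `treatment`, `pc_um`.
#' @param strain,treatment Condition selectors.
#' @param rpkm_floor Genes whose mean expression is below this (RPKM) are
#'   treated as present-but-unaffected (ratio 1); default 1.
#' @param significance_cutoff Adjusted p-value above which a gene is treated
#'   as non-differential (ratio 1); default 0.05.
#' @return An [eico_condition()].
#' @export
build_condition <- function(expression, protein, pc, strain,
                            treatment = c("control", "ddc"),
                            rpkm_floor = 1, significance_cutoff = 0.05) {
  strain <- match.arg(strain, EICO_STRAINS)
  treatment <- match.arg(treatment)
  pc_row <- pc[pc$strain == strain & pc$treatment == treatment, , drop = FALSE]
  if (nrow(pc_row) != 1L)
    stop("pc table must have exactly one row for ", strain, "/", treatment)
  pc_um <- pc_row$pc_um

  if (treatment == "control") {
    ratios <- setNames(rep(1, length(EICO_ENZYMES)), EICO_ENZYMES)
    return(eico_condition(strain, "control", ratios, pc_um))
  }

  ex <- expression[expression$strain == strain, , drop = FALSE]
  gene_ratio <- function(gene) {
    row <- ex[ex$gene == gene, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("expression table: expected one row for gene ", gene,
           " in strain ", strain, ", found ", nrow(row))
    mean_rpkm <- (row$control_rpkm + row$ddc_rpkm) / 2
    if (row$padj > significance_cutoff || mean_rpkm < rpkm_floor) return(1)
    activity_ratio(row$ddc_rpkm, row$control_rpkm)
  }
  protein_ratio <- function(analyte) {
    row <- protein[protein$strain == strain & protein$analyte == analyte, ,
                   drop = FALSE]
    if (nrow(row) != 1L)
      stop("protein table: expected one row for ", analyte, " in strain ",
           strain, ", found ", nrow(row))
    if (row$ratio <= 0) stop("protein ratio must be > 0 for ", analyte)
    row$ratio
  }

  gpx_rows <- ex[grepl(EICO_GPX_PATTERN, ex$gene), , drop = FALSE]
  if (!nrow(gpx_rows))
    stop("expression table has no Gpx isoenzyme rows for strain ", strain)
  gpx_cand <- data.frame(gene = gpx_rows$gene,
                         mean_rpkm = (gpx_rows$control_rpkm +
                                      gpx_rows$ddc_rpkm) / 2,
                         padj = gpx_rows$padj)
  gpx_gene <- select_isoenzyme(gpx_cand, significance_cutoff)

  perk <- protein_ratio("p-ERK")
  pstat3 <- protein_ratio("p-STAT3")
  ratios <- c(
    PTGS1 = gene_ratio(EICO_GENE_MAP$PTGS1),
    ALOX5AP = gene_ratio(EICO_GENE_MAP$ALOX5AP),
    PKCD = gene_ratio(EICO_GENE_MAP$PKCD),
    GPX = gene_ratio(gpx_gene),
    ALOX5 = gene_ratio(EICO_GENE_MAP$ALOX5),
    ALOX15 = gene_ratio(EICO_GENE_MAP$ALOX15),
    PTGDS = gene_ratio(EICO_GENE_MAP$PTGDS),
    PLA2 = perk,
    PERK = perk,
    PSTAT3 = pstat3
  )
  eico_condition(strain, "ddc", ratios, pc_um)
}
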