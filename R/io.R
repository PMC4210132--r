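# Table schemas: required columns and their types ("chr" or "num").
EICO_SCHEMAS <- list(
  constants    = c(reaction = "chr", form = "chr", parameter = "chr",
                   value = "num", unit = "chr"),
  conditions   = c(strain = "chr", treatment = "chr", symbol = "chr",
                   value = "num", unit = "chr"),
  measurements = c(strain = "chr", treatment = "chr", metabolite = "chr",
                   median_nM = "num", mad_nM = "num"),
  expression   = c(gene = "chr", strain = "chr", control_rpkm = "num",
                   ddc_rpkm = "num", padj = "num"),
  protein      = c(analyte = "chr", strain = "chr", ratio = "num"),
  pc           = c(strain = "chr", treatment = "chr", pc_um = "num"),
  bounds       = c(parameter = "chr", lower = "num", upper = "num")
)

# Columns that must jointly be unique per schema.
EICO_SCHEMA_KEYS <- list(
  constants = c("reaction", "parameter"),
  conditions = c("strain", "treatment", "symbol"),
  measurements = c("strain", "treatment", "metabolite"),
  expression = c("gene", "strain"),
  protein = c("analyte", "strain"),
  pc = c("strain", "treatment"),
  bounds = "parameter"
)

#' Read and validate a pipeline table
#'
#' Reads a UTF-8 TSV or CSV file (dialect sniffed from the header line),
#' validates it against one of the named schemas, and parses numeric columns
#' locale-independently (decimal point only). Numeric source fields are kept
#' verbatim in a `<column>_str` companion column so that write/read round
#' trips are bit-identical.
#'
#' @param path File path.
#' @param schema One of `"constants"`, `"conditions"`, `"measurements"`,
#'   `"expression"`, `"protein"`, `"pc"`, `"bounds"`.
#' @return Validated data.frame.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(EICO_SCHEMAS))
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = TRUE,
                           quote = "\"", comment.char = "",
                           encoding = "UTF-8", stringsAsFactors = FALSE)
  spec <- EICO_SCHEMAS[[schema]]
  missing_cols <- setdiff(names(spec), names(raw))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s) for schema '%s': %s",
                 path, schema, paste(missing_cols, collapse = ", ")))
  out <- raw
  for (col in names(spec)) {
    if (spec[[col]] == "num") {
      val <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(val) & nzchar(raw[[col]]))
      if (length(bad))
        stop(sprintf("%s: unparsable number in column '%s', row %d: \"%s\"",
                     path, col, bad[1], raw[[col]][bad[1]]))
      out[[col]] <- val
      out[[paste0(col, "_str")]] <- raw[[col]]
    }
  }
  key <- EICO_SCHEMA_KEYS[[schema]]
  keys <- do.call(paste, c(out[key], sep = "\r"))
  if (anyDuplicated(keys)) {
    d <- which(duplicated(keys))[1]
    stop(sprintf("%s: duplicate key (%s) at row %d", path,
                 paste(key, collapse = "+"), d))
  }
  # keep the conventional name for the constants table
  if (schema == "constants") names(out)[names(out) == "value_str"] <- "value_str"
  out
}

#' Write a pipeline table
#'
#' Writes TSV with the verbatim numeric strings (`<col>_str` companions)
#' where available, so that a read/write/read cycle is bit-identical.
#'
#' @param tab A data.frame (typically from [read_table()] or produced by the
#'   package).
#' @param path Output path.
#' @param schema Optional schema name; when given, only schema columns are
#'   written (with `_str` companions substituted for numerics).
#' @export
write_table <- function(tab, path, schema = NULL) {
  out <- as.data.frame(tab)
  if (!is.null(schema)) {
    schema <- match.arg(schema, names(EICO_SCHEMAS))
    spec <- EICO_SCHEMAS[[schema]]
    cols <- lapply(names(spec), function(col) {
      strcol <- paste0(col, "_str")
      if (spec[[col]] == "num" && strcol %in% names(out)) out[[strcol]]
      else out[[col]]
    })
    out <- setNames(as.data.frame(cols, stringsAsFactors = FALSE), names(spec))
  } else {
    out <- out[, !grepl("_str$", names(out)), drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a measurement table into per-condition concentration vectors
#'
#' @param path Measurements TSV/CSV (schema `measurements`).
#' @param strain,treatment Selectors.
#' @return Named numeric vector metabolite -> median nM.
#' @export
read_measurement_vector <- function(path, strain, treatment) {
  tab <- read_table(path, "measurements")
  sub <- tab[tab$strain == strain & tab$treatment == treatment, ]
  if (!nrow(sub)) stop("no measurements for ", strain, "/", treatment)
  setNames(sub$median_nM, sub$metabolite)
}

# Serialize screen / simulation results to long TSVs ------------------------

#' Write a steady-state result as TSV
#' @param ss An `eico_steady`.
#' @param path Output path.
#' @export
write_steady_state <- function(ss, path) {
  stopifnot(inherits(ss, "eico_steady"))
  tab <- data.frame(strain = ss$condition$strain,
                    treatment = ss$condition$treatment,
                    metabolite = names(ss$concentrations),
                    concentration_nM = unname(ss$concentrations),
                    residual = ss$residual_norm, converged = ss$converged)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fold-change table as TSV
#' @param fc An `eico_foldchange`.
#' @param strain Strain label for the output.
#' @param path Output path.
#' @export
write_fold_changes <- function(fc, strain, path) {
  stopifnot(inherits(fc, "eico_foldchange"))
  tab <- cbind(strain = strain, as.data.frame(fc))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
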