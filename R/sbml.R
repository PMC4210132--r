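# SBML Level 3 Version 1 serialization of the kinetic model, written and
# parsed with xml2. Kinetic constants travel as their verbatim decimal
# strings so an export/import round trip is bit-exact.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# SBML SIds may not contain '-' or start with a digit.
sbml_sid <- function(id) {
  out <- gsub("-", "_", id, fixed = TRUE)
  ifelse(grepl("^[0-9]", out), paste0("_", out), out)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

mathml_rate <- function(r) {
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  S <- ci(sbml_sid(r$substrate))
  u <- vapply(r$scaling_ids, function(a) ci(paste0("u_", a)), character(1))
  switch(r$form,
    decay = sprintf("<apply><times/>%s%s</apply>", ci("k_cat"), S),
    linear = sprintf("<apply><times/>%s%s%s</apply>",
                     ci("v_max"), paste(u, collapse = ""), S),
    mm = {
      num <- sprintf("<apply><times/>%s%s%s</apply>",
                     ci("v_max"), paste(u, collapse = ""), S)
      km_term <- if (is.na(r$inhibitor)) ci("k_m") else
        sprintf(paste0("<apply><times/>%s<apply><plus/>",
                       "<cn type=\"integer\"> 1 </cn>",
                       "<apply><divide/>%s%s</apply>",
                       "</apply></apply>"),
                ci("k_m"), ci(sbml_sid(r$inhibitor)), ci("k_i"))
      sprintf("<apply><divide/>%s<apply><plus/>%s%s</apply></apply>",
              num, km_term, S)
    })
}

#' Export the model as SBML Level 3
#'
#' One species per metabolite (PC as a constant boundary species), one
#' reaction per R1-R12 with a MathML kinetic law matching the implemented
#' rate forms and the kinetic constants as local parameters, and one global
#' parameter per enzyme-activity ratio. When a condition is supplied its
#' ratios and PC clamp become the exported initial values; otherwise the
#' control state (all ratios 1) is exported.
#'
#' @param model An [eico_model()].
#' @param path Output file path.
#' @param condition Optional [eico_condition()].
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path, condition = NULL) {
  stopifnot(inherits(model, "eico_model"))
  ratios <- if (is.null(condition))
    setNames(rep(1, length(EICO_ENZYMES)), EICO_ENZYMES) else condition$ratios
  pc_nM <- if (is.null(condition)) 249000 else condition$pc_um * 1000

  species <- vapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    conc <- if (m$fixed) pc_nM else 0
    sprintf(paste0("      <species id=\"%s\" name=\"%s\" compartment=\"liver\"",
                   " initialConcentration=\"%s\"",
                   " hasOnlySubstanceUnits=\"false\"",
                   " boundaryCondition=\"%s\" constant=\"%s\"/>"),
            sbml_sid(m$id), xml_escape(m$id), format(conc, scientific = FALSE),
            tolower(m$fixed), tolower(m$fixed))
  }, character(1))

  params <- vapply(EICO_ENZYMES, function(e) {
    sprintf("      <parameter id=\"u_%s\" value=\"%s\" constant=\"true\"/>",
            e, format(ratios[[e]], scientific = FALSE))
  }, character(1))

  reactions <- vapply(model$reactions, function(r) {
    reac <- sprintf(paste0("        <listOfReactants>\n",
      "          <speciesReference species=\"%s\" stoichiometry=\"1\"",
      " constant=\"true\"/>\n        </listOfReactants>"),
      sbml_sid(r$substrate))
    prod <- if (is.na(r$product)) "" else sprintf(paste0(
      "\n        <listOfProducts>\n",
      "          <speciesReference species=\"%s\" stoichiometry=\"1\"",
      " constant=\"true\"/>\n        </listOfProducts>"),
      sbml_sid(r$product))
    modf <- if (is.na(r$inhibitor)) "" else sprintf(paste0(
      "\n        <listOfModifiers>\n",
      "          <modifierSpeciesReference species=\"%s\"/>\n",
      "        </listOfModifiers>"), sbml_sid(r$inhibitor))
    locals <- paste(vapply(names(r$params), function(p) {
      sprintf("            <localParameter id=\"%s\" value=\"%s\"/>",
              p, r$param_strings[[p]])
    }, character(1)), collapse = "\n")
    sprintf(paste0(
      "      <reaction id=\"%s\" reversible=\"false\" fast=\"false\">\n",
      "%s%s%s\n",
      "        <kineticLaw>\n",
      "          <math xmlns=\"%s\">\n            %s\n          </math>\n",
      "          <listOfLocalParameters>\n%s\n",
      "          </listOfLocalParameters>\n",
      "        </kineticLaw>\n",
      "      </reaction>"),
      r$id, reac, prod, modf, MATHML_NS, mathml_rate(r), locals)
  }, character(1))

  doc <- sprintf(paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"%s\" level=\"3\" version=\"1\">\n",
    "  <model id=\"aa_eicosanoid_metabolism\" name=\"Arachidonic acid/eicosanoid metabolism\">\n",
    "    <listOfCompartments>\n",
    "      <compartment id=\"liver\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/>\n",
    "    </listOfCompartments>\n",
    "    <listOfSpecies>\n%s\n    </listOfSpecies>\n",
    "    <listOfParameters>\n%s\n    </listOfParameters>\n",
    "    <listOfReactions>\n%s\n    </listOfReactions>\n",
    "  </model>\n",
    "</sbml>\n"),
    SBML_NS, paste(species, collapse = "\n"),
    paste(params, collapse = "\n"), paste(reactions, collapse = "\n"))

  # parse before writing so a malformed document can never be emitted
  xml2::read_xml(doc)
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

#' Import a model from SBML
#'
#' Reads a document written by [export_sbml()] (or an equivalent one):
#' kinetic constants are taken verbatim from the local parameters, the R7
#' catalyst and the R1 scaling mode are recovered from the activity ratios
#' referenced by the kinetic-law math.
#'
#' @param path SBML file path.
#' @return List with `model` (an [eico_model()]) and `ratios`/`pc_um`
#'   (the exported condition values).
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  validate_sbml(doc)
  ns <- c(s = SBML_NS, m = MATHML_NS)

  rx <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  rows <- list()
  r7_activator <- "GPX"; r1_scaling <- "single"
  for (node in rx) {
    rid <- xml2::xml_attr(node, "id")
    locals <- xml2::xml_find_all(node, ".//s:localParameter", ns)
    pnames <- xml2::xml_attr(locals, "id")
    pvals <- xml2::xml_attr(locals, "value")
    form <- if ("k_cat" %in% pnames) "decay"
            else if ("k_m" %in% pnames) "mm" else "linear"
    cis <- trimws(xml2::xml_text(xml2::xml_find_all(node, ".//m:ci", ns)))
    us <- sub("^u_", "", cis[startsWith(cis, "u_")])
    if (rid == "R7" && length(us)) r7_activator <- us[1]
    if (rid == "R1") r1_scaling <- if ("PLA2" %in% us) "double" else "single"
    rows[[rid]] <- data.frame(reaction = rid, form = form, parameter = pnames,
                              value = as.numeric(pvals), value_str = pvals,
                              unit = NA_character_, stringsAsFactors = FALSE)
  }
  order_ids <- paste0("R", 1:12)
  constants <- do.call(rbind, rows[order_ids])
  rownames(constants) <- NULL

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  ids <- sub("^u_", "", xml2::xml_attr(pars, "id"))
  ratios <- setNames(as.numeric(xml2::xml_attr(pars, "value")), ids)
  sp <- xml2::xml_find_all(doc, ".//s:species[@boundaryCondition='true']", ns)
  pc_um <- as.numeric(xml2::xml_attr(sp, "initialConcentration")) / 1000

  model <- eico_model(constants, r7_activator = r7_activator,
                      r1_scaling = r1_scaling)
  list(model = model, ratios = ratios, pc_um = pc_um)
}

#' Structural validation of an SBML document
#'
#' Checks the properties the package relies on: SBML Level 3 namespace, a
#' single model, a compartment, species with ids and compartments, exactly
#' one constant boundary species, reactions whose species references resolve,
#' and a kinetic law with MathML under every reaction.
#'
#' @param doc An `xml_document` or a file path.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_sbml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  ns <- c(s = SBML_NS, m = MATHML_NS)
  if (!identical(xml2::xml_name(doc), "sbml") ||
      !identical(xml2::xml_ns(doc)[["d1"]], SBML_NS))
    stop("not an SBML Level 3 core document")
  if (length(xml2::xml_find_all(doc, "./s:model", ns)) != 1L)
    stop("expected exactly one <model>")
  species <- xml2::xml_find_all(doc, ".//s:species", ns)
  if (!length(species)) stop("no species defined")
  sids <- xml2::xml_attr(species, "id")
  if (anyNA(sids) || anyDuplicated(sids)) stop("species ids missing/duplicated")
  if (any(is.na(xml2::xml_attr(species, "compartment"))))
    stop("species without compartment")
  boundary <- xml2::xml_attr(species, "boundaryCondition") == "true"
  if (sum(boundary, na.rm = TRUE) != 1L)
    stop("expected exactly one boundary (clamped) species")
  rx <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  if (!length(rx)) stop("no reactions defined")
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:speciesReference | .//s:modifierSpeciesReference", ns),
    "species")
  bad <- setdiff(refs, sids)
  if (length(bad))
    stop("species reference(s) to undefined species: ", paste(bad, collapse = ", "))
  for (node in rx) {
    if (!length(xml2::xml_find_all(node, ".//s:kineticLaw/m:math", ns)))
      stop("reaction ", xml2::xml_attr(node, "id"), " lacks kinetic-law math")
  }
  invisible(TRUE)
}
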