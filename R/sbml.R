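# SBML Level 3 + FBC v2 serialization. Element lookup uses local-name() so
# files parse regardless of the namespace prefixes a writer chose; fbc
# attributes are matched with and without prefix for the same reason.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML (Level 3, FBC)
#'
#' Supports the FBC v2 encoding: flux bounds as parameters referenced by
#' \code{fbc:lowerFluxBound}/\code{fbc:upperFluxBound}, the active objective's
#' flux objective, and \code{fbc:geneProductAssociation} trees
#' (\code{fbc:and}/\code{fbc:or}/\code{fbc:geneProductRef}). Species with
#' \code{boundaryCondition="true"} are dropped from the stoichiometry.
#'
#' @param path SBML file path.
#' @param exchange optional explicit exchange reaction ids; default detects
#'   reactions with a single nonzero stoichiometric entry.
#' @return MetabolicModel
#' @export
read_sbml_model <- function(path, exchange = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in ", path, ": ", conditionMessage(e)))

  find_all <- function(node, name)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  attr_any <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hit <- c(at[name], at[paste0("fbc:", name)])
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) NA_character_ else unname(hit[[1L]])
  }

  # parameters (flux bound values)
  pars <- find_all(doc, "parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  # species
  sp <- find_all(doc, "species")
  if (length(sp) == 0L) stop("SBML parse failure: no species in ", path)
  sp_id <- xml2::xml_attr(sp, "id")
  sp_boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]

  # gene products: id -> label (label preferred as the working gene id)
  gps <- find_all(doc, "geneProduct")
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")) |
             xml2::xml_attr(gps, "label") == "",
           vapply(gps, attr_any, character(1), name = "id"),
           xml2::xml_attr(gps, "label")),
    vapply(gps, attr_any, character(1), name = "id"))

  # objective: active objective's single flux objective
  objs <- find_all(doc, "fluxObjective")
  if (length(objs) == 0L) stop("SBML parse failure: no fluxObjective in ", path)
  objective <- attr_any(objs[[1L]], "reaction")

  rxns <- find_all(doc, "reaction")
  if (length(rxns) == 0L) stop("SBML parse failure: no reactions in ", path)
  rxn_id <- vapply(rxns, function(r) xml2::xml_attr(r, "id"), character(1))
  if (anyNA(rxn_id)) stop("SBML parse failure: reaction without id in ", path)

  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxn_id))
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  gpr <- list()
  for (i in seq_along(rxns)) {
    r <- rxns[[i]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(r, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (ref in refs) {
        spid <- xml2::xml_attr(ref, "species")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        if (spid %in% mets) S[spid, i] <- S[spid, i] + sgn * coef
      }
    }
    lbid <- attr_any(r, "lowerFluxBound")
    ubid <- attr_any(r, "upperFluxBound")
    if (is.na(lbid) || is.na(ubid) || !lbid %in% names(parval) ||
        !ubid %in% names(parval))
      stop("SBML parse failure: reaction '", rxn_id[i],
           "' lacks resolvable fbc flux bounds")
    lb[i] <- parval[[lbid]]
    ub[i] <- parval[[ubid]]
    gpa <- xml2::xml_find_first(
      r, "./*[local-name()='geneProductAssociation']/*")
    if (!inherits(gpa, "xml_missing"))
      gpr[[rxn_id[i]]] <- sbml_gpa_tree(gpa, gp_label)
  }
  metabolic_model(S, lb, ub, objective, gpr = gpr, exchange = exchange)
}

sbml_gpa_tree <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    at <- xml2::xml_attrs(node)
    gid <- c(at["fbc:geneProduct"], at["geneProduct"])
    gid <- unname(gid[!is.na(gid)][1L])
    lab <- if (gid %in% names(gp_label)) gp_label[[gid]] else gid
    return(list(op = "leaf", gene = lab))
  }
  if (!nm %in% c("and", "or"))
    stop("SBML parse failure: unexpected element '", nm,
         "' in geneProductAssociation")
  kids <- lapply(xml2::xml_children(node), sbml_gpa_tree, gp_label = gp_label)
  gpr_node(nm, kids)
}

#' Write a metabolic model to SBML (Level 3, FBC v2)
#'
#' @param model MetabolicModel
#' @param path output file path.
#' @export
write_sbml_model <- function(model, path) {
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_CORE_NS, SBML_FBC_NS),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (m in model$metabolites)
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      m))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[i]
    lines <- c(lines,
      sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>',
              r, num(model$lb[i])),
      sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>',
              r, num(model$ub[i])))
  }
  lines <- c(lines, '    </listOfParameters>')
  genes <- model_genes(model)
  if (length(genes) > 0L) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>')
    for (g in genes)
      lines <- c(lines, sprintf(
        '      <fbc:geneProduct fbc:id="gp_%s" fbc:label="%s"/>',
        gsub("[^A-Za-z0-9_]", "_", g), g))
    lines <- c(lines, '    </fbc:listOfGeneProducts>')
  }
  lines <- c(lines,
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            model$objective),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '    <listOfReactions>')
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[i]
    col <- stats::setNames(model$S[, i], model$metabolites)
    rev <- if (model$lb[i] < 0) "true" else "false"
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
      r, rev, r, r))
    for (side in c(-1, 1)) {
      ms <- model$metabolites[sign(col) == side]
      if (length(ms) == 0L) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, sprintf('        <%s>', tag))
      for (m in ms)
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          m, num(abs(col[m]))))
      lines <- c(lines, sprintf('        </%s>', tag))
    }
    if (r %in% names(model$gpr)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 sbml_gpa_lines(model$gpr[[r]], indent = 10L),
                 '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

sbml_gpa_lines <- function(tree, indent) {
  pad <- strrep(" ", indent)
  if (tree$op == "leaf")
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="gp_%s"/>',
                   pad, gsub("[^A-Za-z0-9_]", "_", tree$gene)))
  c(sprintf("%s<fbc:%s>", pad, tree$op),
    unlist(lapply(tree$children, sbml_gpa_lines, indent = indent + 2L)),
    sprintf("%s</fbc:%s>", pad, tree$op))
}
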