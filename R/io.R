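## Model and table I/O: the JSON model dialect, SBML L3 + fbc v2, and the
## TSV side formats (medium, expression, probe maps, scores, outputs).

#' Read or write a model in the package's JSON dialect
#'
#' Schema: \code{\{compounds: [...], reactions: [\{id, stoich: \{compound:
#' coeff\}, lb, ub, gpr, is_exchange\}], biomass_id\}}. A diff-able,
#' figure-free fixture format; round-trips exactly.
#'
#' @param path file path.
#' @return \code{readModelJSON}: a \linkS4class{MetabolicModel}.
#' @export
readModelJSON <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$compounds) || is.null(doc$reactions))
    stop("model JSON: missing 'compounds' or 'reactions'")
  compounds <- unlist(doc$compounds)
  ids <- vapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("model JSON: reaction without id")
    r$id
  }, character(1))
  S <- matrix(0, length(compounds), length(ids),
              dimnames = list(compounds, ids))
  for (r in doc$reactions) {
    for (cpd in names(r$stoich)) {
      if (!cpd %in% compounds)
        stop("model JSON: reaction ", r$id, " references unknown compound ",
             cpd)
      S[cpd, r$id] <- as.numeric(r$stoich[[cpd]])
    }
  }
  num <- function(field, default = NULL)
    vapply(doc$reactions, function(r)
      as.numeric(if (is.null(r[[field]])) default else r[[field]]),
      numeric(1))
  gpr <- vapply(doc$reactions, function(r)
    if (is.null(r$gpr)) "" else as.character(r$gpr), character(1))
  exch <- vapply(doc$reactions, function(r)
    isTRUE(r$is_exchange), logical(1))
  metabolicModel(compounds, ids, S, num("lb", 0), num("ub", 1000), gpr,
                 biomassId = if (is.null(doc$biomass_id)) "" else
                   doc$biomass_id,
                 exchangeIds = ids[exch])
}

#' @rdname readModelJSON
#' @param model a \linkS4class{MetabolicModel}.
#' @return \code{writeModelJSON}: \code{path}, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  rxns <- lapply(seq_along(model@reactions), function(j) {
    col <- model@S[, j]
    nz <- which(col != 0)
    list(id = model@reactions[j],
         stoich = as.list(stats::setNames(as.numeric(col[nz]),
                                          model@compounds[nz])),
         lb = model@lb[j], ub = model@ub[j],
         gpr = model@gprText[j],
         is_exchange = model@reactions[j] %in% model@exchangeIds)
  })
  doc <- list(compounds = as.list(model@compounds), reactions = rxns,
              biomass_id = model@biomassId)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## ---- SBML L3 + fbc v2 -----------------------------------------------------

.sbml.core <- "http://www.sbml.org/sbml/level3/version1/core"
.sbml.fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.gprToFbcXML <- function(tree) {
  if (!is.null(tree$gene))
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', tree$gene))
  inner <- paste(vapply(tree$args, .gprToFbcXML, character(1)), collapse = "")
  sprintf("<fbc:%s>%s</fbc:%s>", tree$op, inner, tree$op)
}

#' Write a model as SBML Level 3 with the fbc version 2 extension
#'
#' Emits species, reactions with stoichiometry and flux-bound parameters,
#' gene-product associations, gene products, and a maximisation objective on
#' the biomass reaction.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModelSBML <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  sp <- paste(sprintf(
    '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    esc(model@compounds)), collapse = "\n")
  pars <- character(0)
  rx <- character(0)
  for (j in seq_along(model@reactions)) {
    rid <- model@reactions[j]
    pars <- c(pars,
              sprintf('      <parameter id="lb_%s" value="%.17g" constant="true"/>', rid, model@lb[j]),
              sprintf('      <parameter id="ub_%s" value="%.17g" constant="true"/>', rid, model@ub[j]))
    col <- model@S[, j]
    reac <- which(col < 0); prod <- which(col > 0)
    side <- function(idx, tag) {
      if (!length(idx)) return("")
      refs <- sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                      model@compounds[idx], abs(as.numeric(col[idx])))
      sprintf("        <%s>\n%s\n        </%s>", tag,
              paste(refs, collapse = "\n"), tag)
    }
    gpa <- if (!is.null(model@gpr[[j]]))
      sprintf("        <fbc:geneProductAssociation>%s</fbc:geneProductAssociation>",
              .gprToFbcXML(model@gpr[[j]])) else ""
    body <- paste(Filter(nzchar, c(side(reac, "listOfReactants"),
                                   side(prod, "listOfProducts"), gpa)),
                  collapse = "\n")
    rx <- c(rx, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">\n%s\n      </reaction>',
      rid, tolower(model@lb[j] < 0), rid, rid, body))
  }
  genes <- modelGenes(model)
  gps <- paste(sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       genes, genes), collapse = "\n")
  objective <- if (nzchar(model@biomassId)) sprintf(
    '    <fbc:listOfObjectives fbc:activeObjective="obj">\n      <fbc:objective fbc:id="obj" fbc:type="maximize">\n        <fbc:listOfFluxObjectives>\n          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>\n        </fbc:listOfFluxObjectives>\n      </fbc:objective>\n    </fbc:listOfObjectives>',
    model@biomassId) else ""
  annotation <- sprintf(
    '    <annotation><exchangeReactions ids="%s"/></annotation>',
    paste(model@exchangeIds, collapse = " "))
  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">
  <model id="model" fbc:strict="true">
%s
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
%s
    </listOfSpecies>
    <listOfParameters>
%s
    </listOfParameters>
    <listOfReactions>
%s
    </listOfReactions>
%s
    <fbc:listOfGeneProducts>
%s
    </fbc:listOfGeneProducts>
  </model>
</sbml>',
    .sbml.core, .sbml.fbc, annotation, sp, paste(pars, collapse = "\n"),
    paste(rx, collapse = "\n"), objective, gps)
  writeLines(doc, path)
  invisible(path)
}

.fbcXMLToGPRText <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    if (is.na(g)) stop("SBML fbc: geneProductRef without fbc:geneProduct")
    return(g)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .fbcXMLToGPRText, character(1))
  if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  if (length(parts) == 1) return(parts)
  stop("SBML fbc: unsupported GPR element <", nm, ">")
}

#' Read a model from SBML Level 3 with fbc
#'
#' Supports the constructs \code{\link{writeModelSBML}} emits: species,
#' reactions with flux-bound parameters (or lb/ub defaulting to
#' irreversible/1000 when absent), fbc gene-product associations, and the
#' active objective (taken as the biomass reaction). Exchange reactions are
#' those with an empty reactant or product side (boundary convention), or the
#' ids listed in the writer's annotation when present.
#'
#' @param path SBML file path.
#' @return A \linkS4class{MetabolicModel}.
#' @export
readModelSBML <- function(path) {
  doc <- xml2::read_xml(path)
  find <- function(node, what)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  sp <- find(doc, "species")
  compounds <- xml2::xml_attr(sp, "id")
  pars <- find(doc, "parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rnodes <- find(doc, "reaction")
  ids <- xml2::xml_attr(rnodes, "id")
  n <- length(ids)
  S <- matrix(0, length(compounds), n, dimnames = list(compounds, ids))
  lb <- numeric(n); ub <- numeric(n); gpr <- character(n)
  onesided <- logical(n)
  for (j in seq_len(n)) {
    node <- rnodes[[j]]
    rid <- ids[j]
    rs <- xml2::xml_find_all(node,
      "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    ps <- xml2::xml_find_all(node,
      "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    fill <- function(refs, sign) {
      for (ref in refs) {
        cpd <- xml2::xml_attr(ref, "species")
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        if (!cpd %in% compounds)
          stop("SBML: reaction ", rid, " references unknown species ", cpd)
        S[cpd, rid] <<- S[cpd, rid] + sign * coef
      }
    }
    fill(rs, -1); fill(ps, 1)
    onesided[j] <- length(rs) == 0 || length(ps) == 0
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[j] <- if (!is.na(lbp) && lbp %in% names(parval)) parval[lbp]
             else if (reversible) -1000 else 0
    ub[j] <- if (!is.na(ubp) && ubp %in% names(parval)) parval[ubp] else 1000
    gpa <- xml2::xml_find_first(node,
      "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids) != 1)
        stop("SBML fbc: malformed geneProductAssociation in reaction ", rid)
      gpr[j] <- tryCatch(.fbcXMLToGPRText(kids[[1]]), error = function(e)
        stop("SBML fbc: ", conditionMessage(e), " (reaction ", rid, ")"))
    }
  }
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  biomass <- if (!inherits(fo, "xml_missing"))
    xml2::xml_attr(fo, "reaction") else ""
  ann <- xml2::xml_find_first(doc, ".//*[local-name()='exchangeReactions']")
  exch <- if (!inherits(ann, "xml_missing"))
    strsplit(xml2::xml_attr(ann, "ids"), " ")[[1]] else ids[onesided]
  metabolicModel(compounds, ids, S, lb, ub, gpr, biomassId = biomass,
                 exchangeIds = intersect(exch, ids))
}

#' Load a metabolic model from file
#'
#' Dispatches on \code{format}, or on the file extension when
#' \code{format = "auto"} (".xml"/".sbml" for SBML, ".json" for the JSON
#' dialect).
#'
#' @param path file path.
#' @param format "auto", "sbml" or "json".
#' @return A \linkS4class{MetabolicModel}.
#' @export
loadModel <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml"
              else if (ext == "json") "json"
              else stop("cannot infer model format from extension '.", ext,
                        "'; pass format explicitly")
  }
  if (format == "sbml") readModelSBML(path) else readModelJSON(path)
}

## ---- TSV side formats -----------------------------------------------------

.readTSV <- function(path, expected) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop(basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Read a growth-medium TSV (columns exchange_id, max_uptake)
#' @param path file path.
#' @return named numeric vector of maximum uptakes.
#' @export
readMediumTSV <- function(path) {
  df <- .readTSV(path, c("exchange_id", "max_uptake"))
  stats::setNames(as.numeric(df$max_uptake), df$exchange_id)
}

#' Read an expression TSV (column gene_id plus z and/or call)
#' @param path file path.
#' @param zThreshold calling threshold when only z-scores are present.
#' @return An \linkS4class{ExpressionProfile}.
#' @export
readExpressionTSV <- function(path, zThreshold = 5) {
  df <- .readTSV(path, "gene_id")
  if (!any(c("z", "call") %in% names(df)))
    stop(basename(path), ": missing column 'z' or 'call'")
  z <- if ("z" %in% names(df))
    stats::setNames(as.numeric(df$z), df$gene_id) else NULL
  call <- if ("call" %in% names(df))
    stats::setNames(as.numeric(df$call), df$gene_id) else NULL
  expressionProfile(call = call, z = z, zThreshold = zThreshold)
}

#' Read a probe-to-gene map TSV (columns probe_id, gene_id)
#' @param path file path.
#' @return data.frame(probe_id, gene_id).
#' @export
readProbeMapTSV <- function(path) .readTSV(path, c("probe_id", "gene_id"))

#' Read a per-gene score TSV (columns gene_id, score)
#'
#' Scores are taken as-is: the provider is responsible for the "lower = more
#' essential" sign convention; no re-signing happens here.
#'
#' @param path file path.
#' @return named numeric vector of scores.
#' @export
readScoresTSV <- function(path) {
  df <- .readTSV(path, c("gene_id", "score"))
  stats::setNames(as.numeric(df$score), df$gene_id)
}

#' Write a reaction classification as TSV (reaction_id, label)
#' @param classification a \linkS4class{ReactionClassification}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClassificationTSV <- function(classification, path) {
  utils::write.table(
    data.frame(reaction_id = names(classification@label),
               label = unname(classification@label)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reaction classification TSV (reaction_id, label)
#' @param path file path.
#' @return A \linkS4class{ReactionClassification}.
#' @export
readClassificationTSV <- function(path) {
  df <- .readTSV(path, c("reaction_id", "label"))
  new("ReactionClassification",
      label = stats::setNames(df$label, df$reaction_id))
}

#' Write an essentiality table as TSV
#' @param table data.frame from \code{\link{geneEssentiality}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEssentialityTSV <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a reconstruction result as JSON
#' @param result a \linkS4class{ReconstructionResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReconstructionJSON <- function(result, path) {
  doc <- list(included = as.list(result@included),
              flux_witness = as.list(result@fluxWitness),
              coverage = result@coverage,
              objective = result@objective,
              iterations = result@iterationLog)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
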