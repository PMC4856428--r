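## Constructors, accessors and show methods for the model containers.

#' Construct a metabolic model
#'
#' @param compounds character compound identifiers.
#' @param reactions character reaction identifiers.
#' @param S stoichiometric matrix (compounds x reactions); anything coercible
#'   to a sparse \pkg{Matrix}.
#' @param lb,ub numeric flux bounds per reaction. A reaction is reversible iff
#'   \code{lb < 0}.
#' @param gpr character GPR rule strings per reaction ("" or NA for none).
#' @param biomassId identifier of the biomass reaction ("" if not defined).
#' @param exchangeIds identifiers of exchange (boundary) reactions.
#' @return A \linkS4class{MetabolicModel}.
#' @examples
#' m <- metabolicModel(
#'   compounds = c("A", "B"),
#'   reactions = c("EX_A", "R1", "BIO"),
#'   S = matrix(c(-1, 0, -1, 1, 0, -1), nrow = 2),
#'   lb = c(-10, 0, 0), ub = c(1000, 1000, 1000),
#'   gpr = c("", "g1", ""), biomassId = "BIO", exchangeIds = "EX_A")
#' nReactions(m)
#' @export
metabolicModel <- function(compounds, reactions, S, lb, ub,
                           gpr = rep("", length(reactions)),
                           biomassId = "", exchangeIds = character(0)) {
  gpr <- ifelse(is.na(gpr), "", gpr)
  trees <- lapply(gpr, parseGPR)
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(compounds, reactions)
  new("MetabolicModel", compounds = as.character(compounds),
      reactions = as.character(reactions), S = S,
      lb = as.numeric(lb), ub = as.numeric(ub),
      gpr = trees, gprText = as.character(gpr),
      biomassId = as.character(biomassId),
      exchangeIds = as.character(exchangeIds))
}

#' @rdname metabolicModel
#' @param object,x a \linkS4class{MetabolicModel}.
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @rdname metabolicModel
#' @export
setMethod("reactionIds", "MetabolicModel", function(x) x@reactions)

#' @rdname metabolicModel
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname metabolicModel
#' @export
setMethod("compoundIds", "MetabolicModel", function(x) x@compounds)

#' @rdname metabolicModel
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @rdname metabolicModel
#' @export
setMethod("stoichiometry", "MetabolicModel", function(x) x@S)

#' @rdname metabolicModel
#' @export
setGeneric("lowerBounds", function(x) standardGeneric("lowerBounds"))
#' @rdname metabolicModel
#' @export
setMethod("lowerBounds", "MetabolicModel",
          function(x) stats::setNames(x@lb, x@reactions))

#' @rdname metabolicModel
#' @export
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))
#' @rdname metabolicModel
#' @export
setMethod("upperBounds", "MetabolicModel",
          function(x) stats::setNames(x@ub, x@reactions))

#' @rdname metabolicModel
#' @export
setGeneric("isReversible", function(x) standardGeneric("isReversible"))
#' @rdname metabolicModel
#' @export
setMethod("isReversible", "MetabolicModel",
          function(x) stats::setNames(x@lb < 0, x@reactions))

#' @rdname metabolicModel
#' @export
setGeneric("gprRules", function(x) standardGeneric("gprRules"))
#' @rdname metabolicModel
#' @export
setMethod("gprRules", "MetabolicModel",
          function(x) stats::setNames(x@gpr, x@reactions))

#' @rdname metabolicModel
#' @export
setGeneric("biomassId", function(x) standardGeneric("biomassId"))
#' @rdname metabolicModel
#' @export
setMethod("biomassId", "MetabolicModel", function(x) x@biomassId)

#' @rdname metabolicModel
#' @export
setGeneric("exchangeIds", function(x) standardGeneric("exchangeIds"))
#' @rdname metabolicModel
#' @export
setMethod("exchangeIds", "MetabolicModel", function(x) x@exchangeIds)

#' @rdname metabolicModel
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))
#' @rdname metabolicModel
#' @export
setMethod("nReactions", "MetabolicModel", function(x) length(x@reactions))

#' @rdname metabolicModel
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))
#' @rdname metabolicModel
#' @export
setMethod("nCompounds", "MetabolicModel", function(x) length(x@compounds))

#' Genes appearing in any GPR rule of the model
#' @param x a \linkS4class{MetabolicModel}.
#' @return character vector of gene identifiers.
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))
#' @rdname modelGenes
#' @export
setMethod("modelGenes", "MetabolicModel",
          function(x) sort(unique(unlist(lapply(x@gpr, gprGenes)))))

#' @export
setMethod("show", "MetabolicModel", function(object) {
  nrev <- sum(object@lb < 0)
  cat("MetabolicModel:", length(object@compounds), "compounds,",
      length(object@reactions), "reactions",
      sprintf("(%d reversible, %d exchange)\n", nrev,
              length(object@exchangeIds)))
  if (nzchar(object@biomassId))
    cat("  biomass:", object@biomassId, "\n")
  ng <- length(modelGenes(object))
  cat("  genes:", ng, "\n")
})

setMethod("show", "SplitModel", function(object) {
  cat("SplitModel:", length(object@steps), "irreversible steps from",
      length(object@parent@reactions), "reactions",
      sprintf("(%d reversible pairs)\n", nrow(object@pairs)))
})

setMethod("show", "FVAResult", function(object) {
  cat("FVAResult:", length(object@vmax), "steps,",
      length(object@blocked), "blocked",
      sprintf("(v_biomass* = %g)\n", object@vbiomassStar))
})

setMethod("show", "ReactionClassification", function(object) {
  tab <- table(factor(object@label, levels = c("H", "M", "L")))
  cat("ReactionClassification:", paste(names(tab), as.integer(tab),
                                       sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile:", length(object@geneCall), "gene calls (",
      sum(object@geneCall > 0), "present /", sum(object@geneCall < 0),
      "absent );", length(object@geneZ), "z-scores\n")
})

setMethod("show", "ReconstructionConfig", function(object) {
  cat(sprintf("ReconstructionConfig: schema=%s (wH=%g, wM=%g, wL=%g), delta=%g\n",
              ifelse(is.na(object@schema), "custom", object@schema),
              object@wH, object@wM, object@wL, object@delta))
  cat(sprintf("  v_biomass*=%s, actTol=%g, feasTol=%g, maxIterations=%d\n",
              ifelse(is.na(object@vbiomassStar), "1% of wild-type max",
                     format(object@vbiomassStar)),
              object@actTol, object@feasTol, object@maxIterations))
})

setMethod("show", "ReconstructionResult", function(object) {
  cat("ReconstructionResult:", length(object@included), "reactions included\n")
  cov <- object@coverage
  fmt <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("  coverage: H =", fmt(cov$H), "(ceiling", paste0(fmt(cov$H_ceiling), ")"),
      " L =", fmt(cov$L), "\n")
  cat("  iterations:", length(object@iterationLog),
      " final objective:", format(object@objective), "\n")
})

setMethod("show", "LPSolution", function(object) {
  cat("LPSolution: objective", format(object@objective), "with",
      sum(object@z > 0.5), "of", length(object@z),
      "activation variables above 0.5\n")
})

#' Accessors for split models and flux/FVA results
#' @param x a \linkS4class{SplitModel}, \linkS4class{FluxState} or
#'   \linkS4class{FVAResult}.
#' @return the corresponding slot, named by step where applicable.
#' @export
setGeneric("stepIds", function(x) standardGeneric("stepIds"))
#' @rdname stepIds
#' @export
setMethod("stepIds", "SplitModel", function(x) x@steps)

#' @rdname stepIds
#' @export
setGeneric("stepOrigin", function(x) standardGeneric("stepOrigin"))
#' @rdname stepIds
#' @export
setMethod("stepOrigin", "SplitModel",
          function(x) stats::setNames(x@origin, x@steps))

#' @rdname stepIds
#' @export
setGeneric("stepUpper", function(x) standardGeneric("stepUpper"))
#' @rdname stepIds
#' @export
setMethod("stepUpper", "SplitModel",
          function(x) stats::setNames(x@stepUpper, x@steps))

#' @rdname stepIds
#' @export
setGeneric("reversiblePairs", function(x) standardGeneric("reversiblePairs"))
#' @rdname stepIds
#' @export
setMethod("reversiblePairs", "SplitModel", function(x) x@pairs)

#' @rdname stepIds
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))
#' @rdname stepIds
#' @export
setMethod("fluxes", "FluxState", function(x) x@v)
#' @rdname stepIds
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @rdname stepIds
#' @export
setMethod("objectiveValue", "FluxState", function(x) x@objective)
#' @rdname stepIds
#' @export
setMethod("objectiveValue", "LPSolution", function(x) x@objective)
#' @rdname stepIds
#' @export
setMethod("objectiveValue", "ReconstructionResult", function(x) x@objective)

#' @rdname stepIds
#' @export
setGeneric("vmax", function(x) standardGeneric("vmax"))
#' @rdname stepIds
#' @export
setMethod("vmax", "FVAResult", function(x) x@vmax)
#' @rdname stepIds
#' @export
setGeneric("blockedSteps", function(x) standardGeneric("blockedSteps"))
#' @rdname stepIds
#' @export
setMethod("blockedSteps", "FVAResult", function(x) x@blocked)

#' Accessors for classifications, profiles and reconstruction results
#' @param x the object.
#' @return the corresponding slot.
#' @export
setGeneric("reactionLabels", function(x) standardGeneric("reactionLabels"))
#' @rdname reactionLabels
#' @export
setMethod("reactionLabels", "ReactionClassification", function(x) x@label)

#' @rdname reactionLabels
#' @export
setGeneric("geneCalls", function(x) standardGeneric("geneCalls"))
#' @rdname reactionLabels
#' @export
setMethod("geneCalls", "ExpressionProfile", function(x) x@geneCall)

#' @rdname reactionLabels
#' @export
setGeneric("geneZScores", function(x) standardGeneric("geneZScores"))
#' @rdname reactionLabels
#' @export
setMethod("geneZScores", "ExpressionProfile", function(x) x@geneZ)

#' @rdname reactionLabels
#' @export
setGeneric("includedReactions", function(x) standardGeneric("includedReactions"))
#' @rdname reactionLabels
#' @export
setMethod("includedReactions", "ReconstructionResult", function(x) x@included)

#' @rdname reactionLabels
#' @export
setGeneric("fluxWitness", function(x) standardGeneric("fluxWitness"))
#' @rdname reactionLabels
#' @export
setMethod("fluxWitness", "ReconstructionResult", function(x) x@fluxWitness)

#' @rdname reactionLabels
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))
#' @rdname reactionLabels
#' @export
setMethod("coverage", "ReconstructionResult", function(x) x@coverage)

#' @rdname reactionLabels
#' @export
setGeneric("iterationLog", function(x) standardGeneric("iterationLog"))
#' @rdname reactionLabels
#' @export
setMethod("iterationLog", "ReconstructionResult", function(x) x@iterationLog)

#' Construct an expression profile
#'
#' Either +1/-1 calls, or z-scores plus a calling threshold (z >= threshold is
#' present), or both. When both are supplied the calls win and the z-scores
#' are carried along unchanged.
#'
#' @param call named numeric +1/-1 calls (optional).
#' @param z named numeric gene z-scores (optional).
#' @param zThreshold calling threshold applied to \code{z} when no calls are
#'   given.
#' @return An \linkS4class{ExpressionProfile}.
#' @export
expressionProfile <- function(call = NULL, z = NULL, zThreshold = 5) {
  if (is.null(call) && is.null(z))
    stop("expressionProfile needs calls or z-scores")
  if (is.null(call)) call <- callGenes(z, zThreshold)
  new("ExpressionProfile",
      geneZ = if (is.null(z)) stats::setNames(numeric(0), character(0)) else z,
      geneCall = call)
}

#' Build a reconstruction configuration
#'
#' The three published weighting schemas set (wH, wM, wL) to (alpha, 1,
#' alpha^2), (alpha, 1, alpha) and (alpha^2, 1, alpha) for schema 1, 2, 3;
#' schema 1 penalises lowly-expressed flux hardest, schema 3 rewards
#' highly-expressed reactions hardest. Explicit weights override the schema.
#'
#' @param schema 1, 2 or 3.
#' @param alpha weight magnitude (default 1e3).
#' @param delta activation fraction in (0, 1]: a reaction counts as active
#'   when it carries at least \code{delta * vmax} flux (default 0.1).
#' @param weights optional numeric c(wH, wM, wL) overriding the schema.
#' @param vbiomassStar minimum biomass flux; NA (default) means 1\% of the
#'   wild-type maximum, computed when needed.
#' @param actTol activity threshold on fluxes (default 1e-6).
#' @param feasTol solver feasibility tolerance (default 1e-9).
#' @param objTol relative objective tolerance for direction re-admission.
#' @param maxIterations cap on cycle-elimination rounds.
#' @param fixAll fix every offending pair per round (default) or one.
#' @return A \linkS4class{ReconstructionConfig}.
#' @examples
#' reconstructionConfig(schema = 3)
#' @export
reconstructionConfig <- function(schema = 3, alpha = 1e3, delta = 0.1,
                                 weights = NULL, vbiomassStar = NA_real_,
                                 actTol = 1e-6, feasTol = 1e-9,
                                 objTol = 1e-6, maxIterations = 50L,
                                 fixAll = TRUE) {
  if (is.null(weights)) {
    if (!schema %in% 1:3) stop("schema must be 1, 2 or 3")
    weights <- switch(schema,
                      c(alpha, 1, alpha^2),
                      c(alpha, 1, alpha),
                      c(alpha^2, 1, alpha))
    schema <- as.integer(schema)
  } else {
    stopifnot(length(weights) == 3)
    schema <- NA_integer_
  }
  new("ReconstructionConfig", delta = delta, alpha = alpha, schema = schema,
      wH = weights[1], wM = weights[2], wL = weights[3],
      vbiomassStar = as.numeric(vbiomassStar), actTol = actTol,
      feasTol = feasTol, objTol = objTol,
      maxIterations = as.integer(maxIterations), fixAll = fixAll)
}
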