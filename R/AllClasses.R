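#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

#' Genome-scale metabolic model
#'
#' Reference-model container: stoichiometry, flux bounds, reversibility
#' (implied by a negative lower bound), parsed GPR rules, the biomass reaction
#' and the exchange (boundary) reactions. Flux units are mmol/gDW/h by
#' convention but opaque to all algorithms. Exchange reactions follow the
#' export-positive convention: the column consumes the metabolite, so uptake
#' is the backward direction of a reversible exchange.
#'
#' @slot compounds character, compound identifiers (C).
#' @slot reactions character, reaction identifiers (R).
#' @slot S sparse stoichiometric matrix, C x R.
#' @slot lb,ub numeric flux bounds per reaction.
#' @slot gpr list of parsed GPR trees (NULL elements mean "no gene").
#' @slot gprText character, the original rule strings ("" for none).
#' @slot biomassId identifier of the biomass reaction ("" if undefined).
#' @slot exchangeIds identifiers of exchange reactions.
#' @export
setClass("MetabolicModel",
  representation(compounds = "character", reactions = "character",
                 S = "Matrix", lb = "numeric", ub = "numeric",
                 gpr = "list", gprText = "character",
                 biomassId = "character", exchangeIds = "character"))

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  C <- length(object@compounds); R <- length(object@reactions)
  if (!all(dim(object@S) == c(C, R)))
    msg <- c(msg, "S must be compounds x reactions")
  if (length(object@lb) != R || length(object@ub) != R)
    msg <- c(msg, "lb/ub must have one entry per reaction")
  if (any(object@lb > object@ub))
    msg <- c(msg, "lb > ub for some reaction")
  if (length(object@gpr) != R || length(object@gprText) != R)
    msg <- c(msg, "gpr/gprText must have one entry per reaction")
  if (anyDuplicated(object@reactions))
    msg <- c(msg, "duplicated reaction ids")
  if (anyDuplicated(object@compounds))
    msg <- c(msg, "duplicated compound ids")
  if (nzchar(object@biomassId) && !(object@biomassId %in% object@reactions))
    msg <- c(msg, "biomassId not among reactions")
  if (!all(object@exchangeIds %in% object@reactions))
    msg <- c(msg, "exchangeIds not among reactions")
  internal <- setdiff(object@reactions, object@exchangeIds)
  if (length(internal)) {
    nz <- Matrix::colSums(abs(object@S[, match(internal, object@reactions),
                                       drop = FALSE]) > 0)
    if (any(nz == 0))
      msg <- c(msg, paste("internal reaction(s) with empty stoichiometry:",
                          paste(internal[nz == 0], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Irreversible split of a metabolic model
#'
#' Every reversible reaction of the parent contributes a forward and a
#' backward step; irreversible reactions contribute one step. All step lower
#' bounds are zero; a reversible parent with bounds [l, u] yields forward
#' upper u and backward upper -l.
#'
#' @slot parent the parent \linkS4class{MetabolicModel}.
#' @slot steps character step identifiers.
#' @slot origin character, parent reaction id per step.
#' @slot direction numeric +1/-1 per step (sign applied to the parent column).
#' @slot stepUpper numeric nonnegative upper bound per step.
#' @slot pairs data.frame with columns \code{reaction}, \code{fwd}, \code{bwd}
#'   (step indices) for originally reversible reactions.
#' @slot Ssplit sparse compounds x steps matrix.
#' @export
setClass("SplitModel",
  representation(parent = "MetabolicModel", steps = "character",
                 origin = "character", direction = "numeric",
                 stepUpper = "numeric", pairs = "data.frame",
                 Ssplit = "Matrix"))

setValidity("SplitModel", function(object) {
  msg <- character(0)
  n <- length(object@steps)
  if (length(object@origin) != n || length(object@direction) != n ||
      length(object@stepUpper) != n)
    msg <- c(msg, "origin/direction/stepUpper must have one entry per step")
  if (any(object@stepUpper < 0)) msg <- c(msg, "negative step upper bound")
  if (!all(object@direction %in% c(-1, 1))) msg <- c(msg, "direction must be +/-1")
  if (ncol(object@Ssplit) != n) msg <- c(msg, "Ssplit column count mismatch")
  if (length(msg)) msg else TRUE
})

#' Steady-state flux distribution on a split model
#' @slot v named nonnegative flux per step.
#' @slot objective objective value of the LP that produced it.
#' @export
setClass("FluxState",
  representation(v = "numeric", objective = "numeric"))

#' Flux variability result (maxima only)
#' @slot vmax named maximum attainable flux per step under the steady-state,
#'   bound and minimum-biomass constraints.
#' @slot blocked character, steps whose maximum does not exceed \code{feasTol}.
#' @slot feasTol feasibility tolerance used for the blocked call.
#' @slot vbiomassStar the minimum-biomass constraint active during the scan.
#' @export
setClass("FVAResult",
  representation(vmax = "numeric", blocked = "character",
                 feasTol = "numeric", vbiomassStar = "numeric"))

#' Ternary reaction classification
#' @slot label named character, "H"/"M"/"L" per reaction of the model.
#' @export
setClass("ReactionClassification",
  representation(label = "character"))

setValidity("ReactionClassification", function(object) {
  if (!all(object@label %in% c("H", "M", "L")))
    "labels must be H, M or L" else TRUE
})

#' Expression evidence for classification
#'
#' Holds per-gene z-scores (optional) and the derived or supplied +1/-1
#' present/absent calls.
#'
#' @slot geneZ named numeric z-scores (may be empty).
#' @slot geneCall named numeric +1/-1 calls.
#' @export
setClass("ExpressionProfile",
  representation(geneZ = "numeric", geneCall = "numeric"))

setValidity("ExpressionProfile", function(object) {
  if (length(object@geneCall) && !all(object@geneCall %in% c(-1, 1)))
    "gene calls must be +1 or -1" else TRUE
})

#' Reconstruction configuration
#'
#' Tunables of the weighted-LP reconstruction: the activation fraction delta
#' in (0, 1], the weight magnitude alpha, the weighting schema (1, 2 or 3)
#' or explicit weights, the minimum biomass flux, and numerical tolerances.
#'
#' @slot delta activation fraction of Eq-style coupling (0 < delta <= 1).
#' @slot alpha weight magnitude (> 1).
#' @slot schema integer 1, 2 or 3 (NA when explicit weights are supplied).
#' @slot wH,wM,wL objective weights.
#' @slot vbiomassStar minimum biomass flux; NA means "1\% of wild-type max".
#' @slot actTol activity threshold on fluxes.
#' @slot feasTol solver feasibility tolerance.
#' @slot objTol relative objective tolerance for re-admission decisions.
#' @slot maxIterations iteration cap of the cycle-elimination loop.
#' @slot fixAll fix all offending pairs per round (TRUE) or one per round.
#' @export
setClass("ReconstructionConfig",
  representation(delta = "numeric", alpha = "numeric", schema = "integer",
                 wH = "numeric", wM = "numeric", wL = "numeric",
                 vbiomassStar = "numeric", actTol = "numeric",
                 feasTol = "numeric", objTol = "numeric",
                 maxIterations = "integer", fixAll = "logical"))

setValidity("ReconstructionConfig", function(object) {
  msg <- character(0)
  if (object@delta <= 0 || object@delta > 1) msg <- c(msg, "delta must be in (0, 1]")
  if (any(c(object@wH, object@wM, object@wL) <= 0)) msg <- c(msg, "weights must be > 0")
  if (!is.na(object@vbiomassStar) && object@vbiomassStar < 0)
    msg <- c(msg, "vbiomassStar must be >= 0")
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Relaxed-LP solution of the reconstruction problem
#' @slot flux \linkS4class{FluxState} over the split steps.
#' @slot z named activation variables of the highly-expressed steps, in [0,1].
#' @slot reducedCosts named reduced costs for all LP variables (step fluxes
#'   as their step id, activation variables as "z.<step id>").
#' @slot objective LP objective value.
#' @export
setClass("LPSolution",
  representation(flux = "FluxState", z = "numeric",
                 reducedCosts = "numeric", objective = "numeric"))

#' Context-specific reconstruction result
#' @slot included character, parent reaction ids of the extracted subnetwork.
#' @slot fluxWitness named net flux per included reaction in the final LP.
#' @slot iterationLog list of per-iteration records.
#' @slot coverage list with elements \code{H}, \code{L} (fractions included)
#'   and \code{H_ceiling} (feasibility-adjusted maximum H fraction).
#' @slot objective final LP objective.
#' @slot objectiveIntegral final objective re-scored with 0/1 activation
#'   semantics (comparable to the MILP oracle).
#' @slot finalFluxes named step fluxes of the final LP solution.
#' @slot config the \linkS4class{ReconstructionConfig} used.
#' @export
setClass("ReconstructionResult",
  representation(included = "character", fluxWitness = "numeric",
                 iterationLog = "list", coverage = "list",
                 objective = "numeric", objectiveIntegral = "numeric",
                 finalFluxes = "numeric",
                 config = "ReconstructionConfig"))
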