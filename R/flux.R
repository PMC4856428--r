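## Reversible splitting, growth-medium application, FBA and FVA.

#' Split reversible reactions into irreversible steps
#'
#' Each reversible reaction (lb < 0) contributes a forward step (column as in
#' the parent, upper bound ub) and a backward step (negated column, upper
#' bound -lb); irreversible reactions contribute a single step. All step
#' lower bounds are zero.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return A \linkS4class{SplitModel}.
#' @export
splitReversible <- function(model) {
  rev <- model@lb < 0
  steps <- character(0); origin <- character(0)
  direction <- numeric(0); upper <- numeric(0)
  fwd.idx <- integer(0); bwd.idx <- integer(0); pair.rxn <- character(0)
  for (j in seq_along(model@reactions)) {
    rid <- model@reactions[j]
    if (rev[j]) {
      steps <- c(steps, paste0(rid, "_f"), paste0(rid, "_b"))
      origin <- c(origin, rid, rid)
      direction <- c(direction, 1, -1)
      upper <- c(upper, model@ub[j], -model@lb[j])
      fwd.idx <- c(fwd.idx, length(steps) - 1L)
      bwd.idx <- c(bwd.idx, length(steps))
      pair.rxn <- c(pair.rxn, rid)
    } else {
      steps <- c(steps, rid)
      origin <- c(origin, rid)
      direction <- c(direction, 1)
      upper <- c(upper, model@ub[j])
    }
  }
  Ssplit <- model@S[, match(origin, model@reactions), drop = FALSE]
  Ssplit <- Ssplit %*% Matrix::Diagonal(x = direction)
  dimnames(Ssplit) <- list(model@compounds, steps)
  new("SplitModel", parent = model, steps = steps, origin = origin,
      direction = direction, stepUpper = upper,
      pairs = data.frame(reaction = pair.rxn, fwd = fwd.idx, bwd = bwd.idx,
                         stringsAsFactors = FALSE),
      Ssplit = Ssplit)
}

## step indices of a parent reaction
.stepsOf <- function(split, rid) which(split@origin == rid)

## the biomass forward step index (biomass is never consumed backwards)
.biomassStep <- function(split) {
  rid <- split@parent@biomassId
  if (!nzchar(rid)) stop("model has no biomass reaction configured")
  idx <- .stepsOf(split, rid)
  idx[split@direction[idx] > 0][1]
}

#' Apply a growth-medium definition to a split model
#'
#' The uptake direction of an exchange reaction is the step whose column
#' produces mass (net positive stoichiometry), following the export-positive
#' convention. Uptake steps of exchanges listed in \code{medium} get the given
#' maximum uptake as upper bound; uptake steps of all other exchanges are
#' closed (upper bound 0). Secretion directions are left untouched.
#'
#' @param split a \linkS4class{SplitModel}.
#' @param medium named numeric vector, exchange reaction id -> maximum uptake.
#' @return The modified \linkS4class{SplitModel}.
#' @export
applyMedium <- function(split, medium) {
  ex <- split@parent@exchangeIds
  unknown <- setdiff(names(medium), ex)
  if (length(unknown))
    stop("medium lists non-exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  upper <- split@stepUpper
  for (rid in ex) {
    for (i in .stepsOf(split, rid)) {
      produces <- sum(split@Ssplit[, i]) > 0
      if (produces)
        upper[i] <- if (rid %in% names(medium)) unname(medium[rid]) else 0
    }
  }
  split@stepUpper <- upper
  split
}

## Assemble and solve an LP over the split steps:
##   optimise  obj . v   s.t.  Ssplit v = 0,  lower <= v <= stepUpper
.splitLP <- function(split, obj, maximize = TRUE, lower = NULL,
                     upper = NULL, feasTol = 1e-9) {
  n <- length(split@steps)
  if (is.null(lower)) lower <- numeric(n)
  if (is.null(upper)) upper <- split@stepUpper
  lpSolveDense(obj, split@Ssplit, rep("==", nrow(split@Ssplit)),
               numeric(nrow(split@Ssplit)), lower, upper,
               maximize = maximize, tol = feasTol)
}

#' Flux balance analysis: maximise one step's flux
#'
#' @param split a \linkS4class{SplitModel} (medium already applied).
#' @param objectiveStep step id or parent reaction id to maximise; defaults to
#'   the biomass reaction.
#' @param lower optional named numeric of extra step lower bounds (e.g. a
#'   minimum biomass flux).
#' @param feasTol solver tolerance.
#' @return A \linkS4class{FluxState}.
#' @export
fbaMax <- function(split, objectiveStep = NULL, lower = NULL,
                   feasTol = 1e-9) {
  n <- length(split@steps)
  if (is.null(objectiveStep)) {
    oi <- .biomassStep(split)
  } else {
    oi <- match(objectiveStep, split@steps)
    if (is.na(oi)) {
      idx <- .stepsOf(split, objectiveStep)
      idx <- idx[split@direction[idx] > 0]
      if (!length(idx)) stop("unknown objective step: ", objectiveStep)
      oi <- idx[1]
    }
  }
  lo <- numeric(n)
  if (!is.null(lower)) {
    ii <- match(names(lower), split@steps)
    if (anyNA(ii)) stop("unknown step in lower bounds")
    lo[ii] <- lower
  }
  obj <- numeric(n); obj[oi] <- 1
  sol <- .splitLP(split, obj, maximize = TRUE, lower = lo, feasTol = feasTol)
  if (sol$status != "optimal")
    stop("FBA problem is ", sol$status)
  new("FluxState", v = stats::setNames(sol$x, split@steps),
      objective = sol$objective)
}

#' Flux variability analysis (maxima)
#'
#' For every split step, maximises its flux subject to steady state, the step
#' bounds and a minimum biomass flux. Steps whose maximum does not exceed
#' \code{feasTol} are reported blocked. One LP is solved per step.
#'
#' @param split a \linkS4class{SplitModel} (medium already applied).
#' @param vbiomassStar minimum biomass flux enforced during the scan.
#' @param feasTol solver tolerance.
#' @return An \linkS4class{FVAResult}.
#' @export
computeFvaMax <- function(split, vbiomassStar = 0, feasTol = 1e-9) {
  n <- length(split@steps)
  bio <- .biomassStep(split)
  lo <- numeric(n); lo[bio] <- vbiomassStar
  if (split@stepUpper[bio] < vbiomassStar)
    stop("infeasible: biomass upper bound below v_biomass*")
  vm <- numeric(n)
  for (i in seq_len(n)) {
    if (split@stepUpper[i] <= feasTol) { vm[i] <- 0; next }
    obj <- numeric(n); obj[i] <- 1
    sol <- .splitLP(split, obj, maximize = TRUE, lower = lo,
                    feasTol = feasTol)
    if (sol$status != "optimal")
      stop("FVA base problem is ", sol$status,
           "; consider lowering v_biomass*")
    vm[i] <- sol$objective
  }
  vm[vm < 0] <- 0
  names(vm) <- split@steps
  new("FVAResult", vmax = vm, blocked = split@steps[vm <= feasTol],
      feasTol = feasTol, vbiomassStar = vbiomassStar)
}

#' Net fluxes of a split flux state on the parent reactions
#'
#' Maps step fluxes back to the parent model: forward minus backward for
#' originally reversible reactions.
#'
#' @param split the \linkS4class{SplitModel}.
#' @param v named step flux vector (or a \linkS4class{FluxState}).
#' @return named numeric net flux per parent reaction.
#' @export
netFluxes <- function(split, v) {
  if (is(v, "FluxState")) v <- v@v
  rxns <- split@parent@reactions
  net <- stats::setNames(numeric(length(rxns)), rxns)
  for (i in seq_along(split@steps))
    net[split@origin[i]] <- net[split@origin[i]] +
      split@direction[i] * v[i]
  net
}

#' Wild-type maximum biomass flux of a split model
#' @param split a \linkS4class{SplitModel} (medium applied).
#' @param feasTol solver tolerance.
#' @return numeric scalar.
#' @export
wildTypeBiomass <- function(split, feasTol = 1e-9) {
  objectiveValue(fbaMax(split, feasTol = feasTol))
}

#' Restrict a model to a reaction subset
#'
#' Keeps the listed reactions with their bounds and GPRs; drops compounds no
#' longer touched by any kept reaction. Medium restrictions applied to a
#' split model can be folded back first via \code{\link{boundsFromSplit}}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param reactions character reaction ids to keep.
#' @return A \linkS4class{MetabolicModel}.
#' @export
subsetModel <- function(model, reactions) {
  keep <- match(reactions, model@reactions)
  if (anyNA(keep)) stop("unknown reaction id(s) in subset")
  S <- model@S[, keep, drop = FALSE]
  cpd.keep <- Matrix::rowSums(abs(S) > 0) > 0
  metabolicModel(compounds = model@compounds[cpd.keep],
                 reactions = model@reactions[keep],
                 S = S[cpd.keep, , drop = FALSE],
                 lb = model@lb[keep], ub = model@ub[keep],
                 gpr = model@gprText[keep],
                 biomassId = if (model@biomassId %in% model@reactions[keep])
                   model@biomassId else "",
                 exchangeIds = intersect(model@exchangeIds,
                                         model@reactions[keep]))
}

#' Parent-model bounds implied by a split model's step bounds
#'
#' Inverse of the split: per parent reaction, ub = forward step upper and
#' lb = -(backward step upper) (0 if irreversible). Used to carry medium
#' restrictions into an extracted submodel.
#'
#' @param split a \linkS4class{SplitModel}.
#' @return list(lb, ub) named by parent reaction.
#' @export
boundsFromSplit <- function(split) {
  rxns <- split@parent@reactions
  lb <- stats::setNames(numeric(length(rxns)), rxns)
  ub <- lb
  for (i in seq_along(split@steps)) {
    rid <- split@origin[i]
    if (split@direction[i] > 0) ub[rid] <- split@stepUpper[i]
    else lb[rid] <- -split@stepUpper[i]
  }
  list(lb = lb, ub = ub)
}
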