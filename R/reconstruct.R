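## The context-specific reconstruction LP and its iterative refinement.
##
## Variables: one nonnegative flux v_i per split step (capped by the FVA
## maximum) and one activation variable z_i in [0, 1] per non-blocked step
## of a highly-expressed (H) reaction, coupled by
##     delta * vmax_i * z_i <= v_i.
## Objective (minimised):
##     sum_{i in L} wL * v_i / (delta * vmax_i)
##   + sum_{i in M} wM * v_i / (delta * vmax_i)
##   - wH * sum_{i in H} z_i
## The 1/(delta*vmax) scaling makes cost and activation independent of the
## stoichiometric scale of each reaction. Because reversible reactions are
## split without a complementarity constraint, H pairs can earn both of their
## activation rewards by running a net-zero two-cycle; these spurious cycles
## are removed iteratively using the reduced costs of the activation
## variables to choose which direction to keep.

#' Resolve the minimum biomass flux of a configuration
#'
#' NA in the configuration means "1\% of the wild-type maximum biomass",
#' computed on the split model as given.
#'
#' @param split a \linkS4class{SplitModel} (medium applied).
#' @param config a \linkS4class{ReconstructionConfig}.
#' @return numeric scalar.
#' @export
resolveBiomassStar <- function(split, config) {
  if (!is.na(config@vbiomassStar)) return(config@vbiomassStar)
  0.01 * wildTypeBiomass(split, feasTol = config@feasTol)
}

#' Build the reconstruction LP
#'
#' Assembles objective, constraint matrix and bounds for the relaxed
#' reconstruction LP. Blocked steps (FVA maximum at or below the feasibility
#' tolerance) carry no objective term, get no activation variable and are
#' fixed to zero.
#'
#' @param split a \linkS4class{SplitModel} (medium applied).
#' @param classification a \linkS4class{ReactionClassification}.
#' @param fva an \linkS4class{FVAResult} for \code{split}.
#' @param config a \linkS4class{ReconstructionConfig}.
#' @param vbiomassStar resolved minimum biomass flux.
#' @return A list with the LP pieces (\code{obj}, \code{mat}, \code{dir},
#'   \code{rhs}, \code{lb}, \code{ub}) and index maps: \code{vIdx} (step ->
#'   column), \code{zIdx} (named by step, columns of activation variables),
#'   \code{hSteps}, \code{labels} (per step).
#' @export
buildObjective <- function(split, classification, fva, config,
                           vbiomassStar = resolveBiomassStar(split, config)) {
  n <- length(split@steps)
  vm <- fva@vmax
  blocked <- vm <= fva@feasTol
  lab <- classification@label[split@origin]
  hSteps <- which(lab == "H" & !blocked)
  nz <- length(hSteps)
  zIdx <- stats::setNames(n + seq_len(nz), split@steps[hSteps])
  ncol <- n + nz

  obj <- numeric(ncol)
  scale <- 1 / (config@delta * pmax(vm, fva@feasTol))
  ml <- which(lab == "L" & !blocked)
  mm <- which(lab == "M" & !blocked)
  obj[ml] <- config@wL * scale[ml]
  obj[mm] <- config@wM * scale[mm]
  obj[zIdx] <- -config@wH

  C <- nrow(split@Ssplit)
  mat <- Matrix::Matrix(0, C + nz, ncol, sparse = TRUE)
  mat[seq_len(C), seq_len(n)] <- split@Ssplit
  ## coupling rows: delta * vmax * z - v <= 0
  for (k in seq_len(nz)) {
    i <- hSteps[k]
    mat[C + k, i] <- -1
    mat[C + k, zIdx[k]] <- config@delta * vm[i]
  }
  dir <- c(rep("==", C), rep("<=", nz))
  rhs <- numeric(C + nz)

  lb <- numeric(ncol)
  ub <- c(pmin(split@stepUpper, vm), rep(1, nz))
  ub[seq_len(n)][blocked] <- 0
  bio <- .biomassStep(split)
  if (blocked[bio] && vbiomassStar > fva@feasTol)
    stop("internal inconsistency: biomass step blocked under v_biomass* > 0")
  lb[bio] <- vbiomassStar
  ub[bio] <- max(ub[bio], vbiomassStar)

  list(obj = obj, mat = mat, dir = dir, rhs = rhs, lb = lb, ub = ub,
       vIdx = seq_len(n), zIdx = zIdx, hSteps = hSteps, labels = lab,
       vbiomassStar = vbiomassStar)
}

#' Solve the relaxed reconstruction LP
#'
#' @param split a \linkS4class{SplitModel}.
#' @param objective LP pieces from \code{\link{buildObjective}}, possibly with
#'   modified bounds.
#' @param config a \linkS4class{ReconstructionConfig}.
#' @return An \linkS4class{LPSolution} with fluxes, activation variables and
#'   reduced costs (named by step; activation variables as "z.<step>").
#' @export
solveRelaxedLP <- function(split, objective, config) {
  sol <- lpSolveDense(objective$obj, objective$mat, objective$dir,
                      objective$rhs, objective$lb, objective$ub,
                      tol = config@feasTol)
  if (sol$status == "infeasible")
    stop("reconstruction LP infeasible (medium too restrictive for v_biomass*?)")
  if (sol$status != "optimal")
    stop("reconstruction LP: solver status ", sol$status)
  n <- length(split@steps)
  v <- stats::setNames(sol$x[seq_len(n)], split@steps)
  z <- stats::setNames(sol$x[objective$zIdx], names(objective$zIdx))
  zn <- if (length(objective$zIdx))
    paste0("z.", names(objective$zIdx)) else character(0)
  rc <- stats::setNames(sol$reduced_costs, c(split@steps, zn))
  new("LPSolution", flux = new("FluxState", v = v, objective = sol$objective),
      z = z, reducedCosts = rc, objective = sol$objective)
}

#' Detect spurious two-cycles of reversible highly-expressed reactions
#'
#' Reports reversible pairs whose parent is classified H with both the
#' forward and the backward step active above the activity threshold —
#' the net-zero cycles that earn unwarranted activation reward in the
#' relaxed LP. Ordered by descending min(v_f, v_b), ties by reaction id.
#'
#' @param sol an \linkS4class{LPSolution}.
#' @param split the \linkS4class{SplitModel}.
#' @param classification the \linkS4class{ReactionClassification}.
#' @param config the \linkS4class{ReconstructionConfig}.
#' @return data.frame(reaction, fwd, bwd, vf, vb), possibly empty.
#' @export
detectSpuriousPairs <- function(sol, split, classification, config) {
  v <- sol@flux@v
  pr <- split@pairs
  if (!nrow(pr))
    return(data.frame(reaction = character(0), fwd = integer(0),
                      bwd = integer(0), vf = numeric(0), vb = numeric(0)))
  lab <- classification@label[pr$reaction]
  vf <- v[pr$fwd]; vb <- v[pr$bwd]
  sel <- lab == "H" & vf > config@actTol & vb > config@actTol
  out <- data.frame(reaction = pr$reaction[sel], fwd = pr$fwd[sel],
                    bwd = pr$bwd[sel], vf = unname(vf[sel]),
                    vb = unname(vb[sel]), stringsAsFactors = FALSE)
  out[order(-pmin(out$vf, out$vb), out$reaction), , drop = FALSE]
}

## Integral re-scoring of a flux vector under the reconstruction objective:
## activation counts 1 iff the step carries at least delta * vmax flux.
## Comparable to the binary-activation MILP oracle.
.integralObjective <- function(objective, config, v, tol = 1e-6) {
  n <- length(objective$vIdx)
  flux.cost <- sum(objective$obj[seq_len(n)] * v)
  act <- 0L
  for (s in names(objective$zIdx)) {
    i <- objective$zIdx[s] - n       # position in hSteps
    step <- objective$hSteps[i]
    thr <- objective$mat[nrow(objective$mat) - length(objective$zIdx) + i,
                         objective$zIdx[s]]  # delta * vmax_step
    if (v[step] >= thr - tol * (1 + thr)) act <- act + 1L
  }
  flux.cost - config@wH * act
}

#' Reconstruct a context-specific network by iterative LP
#'
#' Solves the relaxed LP, then repeatedly eliminates spurious net-zero
#' two-cycles of reversible H reactions: for each offending pair the step
#' whose activation variable shows the more favourable reduced-cost signal is
#' kept (ties keep the forward step) and the opposite step is fixed to zero.
#' After convergence every direction that was fixed off and whose partner
#' ended up inactive is given one verification LP with only that direction
#' open; if it then earns activation (z > 0) without pushing the objective
#' beyond the accepted tolerance it is re-admitted and the problem re-solved
#' once. The final network consists of the parent reactions carrying net flux
#' above the activity threshold, plus the biomass reaction.
#'
#' @param split a \linkS4class{SplitModel} (medium applied).
#' @param classification a \linkS4class{ReactionClassification}.
#' @param fva an \linkS4class{FVAResult} for \code{split} (biomass-constrained).
#' @param config a \linkS4class{ReconstructionConfig}.
#' @return A \linkS4class{ReconstructionResult}.
#' @export
iterativeReconstruct <- function(split, classification, fva, config) {
  vstar <- resolveBiomassStar(split, config)
  objective <- buildObjective(split, classification, fva, config, vstar)
  fixed.off <- integer(0)             # step indices fixed to zero
  log <- list()

  solve.current <- function() {
    ob <- objective
    ob$ub[fixed.off] <- 0
    zi <- ob$zIdx[split@steps[fixed.off]]
    ob$ub[zi[!is.na(zi)]] <- 0
    solveRelaxedLP(split, ob, config)
  }

  sol <- solve.current()
  first.obj <- sol@objective
  iter <- 0L
  repeat {
    pairs <- detectSpuriousPairs(sol, split, classification, config)
    pairs <- pairs[!(pairs$fwd %in% fixed.off | pairs$bwd %in% fixed.off), ,
                   drop = FALSE]
    if (!nrow(pairs)) break
    iter <- iter + 1L
    if (iter > config@maxIterations) {
      err <- simpleError("cycle elimination did not converge within maxIterations")
      err$iterationLog <- log
      stop(err)
    }
    todo <- if (config@fixAll) seq_len(nrow(pairs)) else 1L
    fixed.now <- character(0)
    for (k in todo) {
      fs <- split@steps[pairs$fwd[k]]; bs <- split@steps[pairs$bwd[k]]
      rcf <- sol@reducedCosts[paste0("z.", fs)]
      rcb <- sol@reducedCosts[paste0("z.", bs)]
      if (is.na(rcf)) rcf <- 0
      if (is.na(rcb)) rcb <- 0
      ## both activation variables sit at their upper bound in a spurious
      ## cycle; the more negative reduced cost marks the direction whose
      ## activation the objective values more -> keep it, fix the other
      keep.fwd <- if (abs(rcf - rcb) <= 1e-9 * (1 + abs(rcf))) TRUE
                  else rcf < rcb
      off <- if (keep.fwd) pairs$bwd[k] else pairs$fwd[k]
      fixed.off <- c(fixed.off, off)
      fixed.now <- c(fixed.now, split@steps[off])
    }
    sol <- solve.current()
    log[[length(log) + 1L]] <-
      list(iteration = iter,
           pairs = pairs$reaction[todo],
           fixed = fixed.now,
           objective = sol@objective)
  }

  ## verification pass: a fixed-off direction whose kept partner is inactive
  ## gets one LP with only itself open; re-admit on earned activation at
  ## negligible objective cost
  if (length(fixed.off)) {
    pr <- split@pairs
    for (off in fixed.off) {
      row <- which(pr$fwd == off | pr$bwd == off)
      partner <- if (pr$fwd[row] == off) pr$bwd[row] else pr$fwd[row]
      if (sol@flux@v[partner] > config@actTol) next
      trial.off <- c(setdiff(fixed.off, off), partner)
      ob <- objective
      ob$ub[trial.off] <- 0
      zi <- ob$zIdx[split@steps[trial.off]]
      ob$ub[zi[!is.na(zi)]] <- 0
      trial <- tryCatch(solveRelaxedLP(split, ob, config),
                        error = function(e) NULL)
      if (is.null(trial)) next
      zname <- split@steps[off]
      zval <- if (zname %in% names(trial@z)) trial@z[zname] else 0
      worse <- trial@objective - sol@objective
      if (zval > config@actTol &&
          worse <= config@objTol * (1 + abs(sol@objective))) {
        fixed.off <- trial.off
        sol <- trial
        log[[length(log) + 1L]] <-
          list(iteration = NA_integer_, readmitted = zname,
               objective = sol@objective)
      }
    }
  }

  v <- sol@flux@v
  net <- netFluxes(split, v)
  bio <- split@parent@biomassId
  included <- union(names(net)[abs(net) > config@actTol], bio)
  included <- included[order(match(included, split@parent@reactions))]
  res <- new("ReconstructionResult",
             included = included,
             fluxWitness = net[included],
             iterationLog = log,
             coverage = list(),
             objective = sol@objective,
             objectiveIntegral = .integralObjective(objective, config, v,
                                                    tol = config@actTol),
             finalFluxes = v,
             config = config)
  res@coverage <- computeCoverage(res, classification, fva, split)
  res
}

#' Coverage of the H and L reaction classes by a reconstruction
#'
#' Fractions of highly- and lowly-expressed reactions included in the
#' extracted subnetwork, plus the feasibility-adjusted ceiling for H: the
#' fraction of H reactions that are not blocked (some H reactions cannot
#' operate in steady state under the imposed medium, so full coverage is not
#' always reachable).
#'
#' @param result a \linkS4class{ReconstructionResult}.
#' @param classification the \linkS4class{ReactionClassification} used.
#' @param fva the \linkS4class{FVAResult} used.
#' @param split the \linkS4class{SplitModel} used.
#' @return list(H, L, H_ceiling, nH, nL); H and L are NA when the
#'   corresponding class is empty.
#' @export
computeCoverage <- function(result, classification, fva, split) {
  lab <- classification@label
  H <- names(lab)[lab == "H"]
  L <- names(lab)[lab == "L"]
  blocked.parent <- vapply(split@parent@reactions, function(rid) {
    idx <- .stepsOf(split, rid)
    all(split@steps[idx] %in% fva@blocked)
  }, logical(1))
  hc <- if (length(H)) length(intersect(result@included, H)) / length(H)
        else NA_real_
  lc <- if (length(L)) length(intersect(result@included, L)) / length(L)
        else NA_real_
  ceiling <- if (length(H))
    sum(!blocked.parent[H]) / length(H) else NA_real_
  list(H = hc, L = lc, H_ceiling = ceiling,
       nH = length(H), nL = length(L))
}

#' End-to-end reconstruction from a model, profile and medium
#'
#' Convenience wrapper: classify reactions, split, apply the medium, run FVA
#' at the configured minimum biomass flux, and reconstruct.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param profile an \linkS4class{ExpressionProfile} (or a precomputed
#'   \linkS4class{ReactionClassification}).
#' @param medium named numeric uptake caps (NULL leaves bounds untouched).
#' @param config a \linkS4class{ReconstructionConfig}.
#' @return A \linkS4class{ReconstructionResult}.
#' @export
reconstructNetwork <- function(model, profile, medium = NULL,
                               config = reconstructionConfig()) {
  classification <- if (is(profile, "ReactionClassification")) profile
                    else classifyReactions(model, profile)
  split <- splitReversible(model)
  if (!is.null(medium)) split <- applyMedium(split, medium)
  vstar <- resolveBiomassStar(split, config)
  config@vbiomassStar <- vstar
  fva <- computeFvaMax(split, vstar, feasTol = config@feasTol)
  iterativeReconstruct(split, classification, fva, config)
}

#' Extract the reconstructed subnetwork as a model
#'
#' Builds a \linkS4class{MetabolicModel} restricted to the included reactions,
#' with the medium-adjusted bounds of the split model folded back in.
#'
#' @param result a \linkS4class{ReconstructionResult}.
#' @param split the \linkS4class{SplitModel} the reconstruction ran on.
#' @return A \linkS4class{MetabolicModel}.
#' @export
extractSubmodel <- function(result, split) {
  bounds <- boundsFromSplit(split)
  model <- split@parent
  model@lb <- unname(bounds$lb[model@reactions])
  model@ub <- unname(bounds$ub[model@reactions])
  subsetModel(model, result@included)
}
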