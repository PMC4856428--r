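## Synthetic models, expression profiles and the MILP reconstruction oracle.
##
## Everything here is generated in code: no downloads, no stored binaries.
## The generators plant verifiable structures (a feasible biomass path,
## spurious reversible cycles, isozyme pairs, blocked branches) so that every
## stage of the pipeline can be tested against construction metadata.

#' Ten-reaction demonstration network with spurious reversible cycles
#'
#' A deterministic 10-reaction + biomass model whose ternary classification is
#' H for reactions 3, 4, 5, 7, 9; M for 2, 8, 10; L for 1 and 6. The biomass
#' path runs uptake (R2, M) -> R3 (H) -> R5 (H) -> biomass, reactions 4 and 9
#' are reversible H reactions that can only carry flux as net-zero two-cycles
#' (each connects two metabolites nothing else touches), and reaction 7 is an
#' H reaction feeding a dead-end metabolite, hence blocked: the relaxed LP
#' activates both cycles, and full H coverage is unreachable.
#'
#' @return list(model, classification, profile) where profile holds the gene
#'   calls that generate the classification.
#' @examples
#' fx <- makeSpuriousCycleDemo()
#' table(reactionLabels(fx$classification))
#' @export
makeSpuriousCycleDemo <- function() {
  compounds <- c("A", "B", "D", "C", "E", "G", "I", "X", "Z")
  reactions <- c("R1", "R2", "R3", "R4", "R5", "R6", "R7", "R8", "R9",
                 "R10", "BIOMASS")
  S <- matrix(0, length(compounds), length(reactions),
              dimnames = list(compounds, reactions))
  S[c("A", "D"), "R1"] <- c(-1, 1)        # L: alternative path A -> D
  S["A", "R2"] <- -1                      # M: exchange of A (uptake backward)
  S[c("A", "B"), "R3"] <- c(-1, 1)        # H
  S[c("C", "E"), "R4"] <- c(-1, 1)        # H, reversible, isolated pair
  S[c("B", "D"), "R5"] <- c(-1, 1)        # H
  S[c("D", "A"), "R6"] <- c(-1, 1)        # L: wasteful loop closure
  S[c("D", "Z"), "R7"] <- c(-1, 1)        # H, dead end -> blocked
  S[c("D", "X"), "R8"] <- c(-1, 1)        # M: secretion route
  S[c("G", "I"), "R9"] <- c(-1, 1)        # H, reversible, isolated pair
  S["X", "R10"] <- -1                     # M: exchange of X (export only)
  S["D", "BIOMASS"] <- -1                 # biomass consumes D
  lb <- c(0, -10, 0, -20, 0, 0, 0, 0, -20, 0, 0)
  ub <- c(20, 20, 20, 20, 20, 20, 20, 20, 20, 20, 20)
  gpr <- c("g1", "", "g3", "g4", "g5", "g6", "g7", "", "g9", "", "")
  model <- metabolicModel(compounds, reactions, S, lb, ub, gpr,
                          biomassId = "BIOMASS",
                          exchangeIds = c("R2", "R10"))
  calls <- c(g1 = -1, g3 = 1, g4 = 1, g5 = 1, g6 = -1, g7 = 1, g9 = 1)
  profile <- expressionProfile(call = calls)
  list(model = model,
       classification = classifyReactions(model, profile),
       profile = profile)
}

#' Random feasible fixture with planted structures
#'
#' Generates a random metabolic model that always admits biomass production
#' (a planted uptake -> chain -> biomass path) plus, optionally: an isolated
#' reversible reaction that can only run as a net-zero cycle, an isozyme pair
#' ("a or b" GPR) on a backbone reaction, and a blocked dead-end branch.
#' Remaining reactions connect random metabolite pairs. Each internal
#' reaction carries a single-gene GPR unless selected as unassociated
#' (classified M). Gene calls are drawn so that called genes are present with
#' probability hFraction / (hFraction + lFraction), and a reaction is left
#' without expression evidence with probability 1 - hFraction - lFraction.
#'
#' @param nMetabolites,nReactions target sizes (the planted path counts
#'   towards them; nReactions >= 8).
#' @param reversibleFraction probability that a random internal reaction is
#'   reversible.
#' @param hFraction,lFraction target fractions of H and L reactions
#'   (fractions must sum to at most 1).
#' @param seed integer seed; fixtures are fully deterministic given it.
#' @param spuriousPair,isozymePair,blockedBranch plant the corresponding
#'   structure.
#' @return list(model, profile, meta); meta records the planted reaction and
#'   gene ids.
#' @export
makeRandomFixture <- function(nMetabolites = 8, nReactions = 16,
                              reversibleFraction = 0.3,
                              hFraction = 0.35, lFraction = 0.3,
                              seed = 1L, spuriousPair = TRUE,
                              isozymePair = TRUE, blockedBranch = TRUE) {
  stopifnot(hFraction + lFraction <= 1, nReactions >= 8, nMetabolites >= 4)
  withr::with_seed(seed, {
    mets <- paste0("M", seq_len(nMetabolites))
    rxn <- list()   # each: id, stoich (named), lb, ub, gpr, exch
    add <- function(id, stoich, lb, ub, gpr = "", exch = FALSE)
      rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                       ub = ub, gpr = gpr, exch = exch)
    meta <- list()

    ## planted biomass path: EX_M1 (uptake 10) -> M1 -> M2 -> biomass;
    ## internal caps sit at 2.5x the uptake so activation thresholds stay
    ## reachable from the medium
    cap <- 25
    add("EX_M1", c(M1 = -1), -10, cap, exch = TRUE)
    add("Vb1", c(M1 = -1, M2 = 1), 0, cap, gpr = "g_b1")
    add("Vb2", c(M2 = -1, M3 = 1), 0, cap,
        gpr = if (isozymePair) "g_iso1 or g_iso2" else "g_b2")
    add("BIOMASS", c(M3 = -1), 0, cap)
    meta$backbone <- c("EX_M1", "Vb1", "Vb2", "BIOMASS")
    if (isozymePair) meta$isozyme_genes <- c("g_iso1", "g_iso2")

    gi <- 0L
    next.gene <- function() { gi <<- gi + 1L; paste0("g", gi) }

    if (spuriousPair) {
      add("Vcyc", c(P1 = -1, P2 = 1), -cap, cap, gpr = next.gene())
      meta$spurious <- "Vcyc"
      meta$spurious_gene <- rxn[[length(rxn)]]$gpr
      mets <- c(mets, "P1", "P2")
    }
    if (blockedBranch) {
      add("Vdead", c(M2 = -1, DEAD = 1), 0, cap, gpr = next.gene())
      meta$blocked <- "Vdead"
      mets <- c(mets, "DEAD")
    }
    ## a secretion valve so random in-flows can drain
    add("EX_M4", c(M4 = -1), 0, cap, exch = TRUE)

    k <- length(rxn)
    core <- paste0("M", seq_len(min(nMetabolites, 6)))
    while (k < nReactions) {
      pick <- sample(core, 2)
      rev <- stats::runif(1) < reversibleFraction
      id <- paste0("V", k)
      add(id, stats::setNames(c(-1, 1), pick), if (rev) -cap else 0, cap,
          gpr = next.gene())
      k <- k + 1L
    }

    ids <- vapply(rxn, `[[`, character(1), "id")
    S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
    for (r in rxn) S[names(r$stoich), r$id] <- r$stoich
    model <- metabolicModel(
      compounds = mets, reactions = ids, S = S,
      lb = vapply(rxn, `[[`, numeric(1), "lb"),
      ub = vapply(rxn, `[[`, numeric(1), "ub"),
      gpr = vapply(rxn, `[[`, character(1), "gpr"),
      biomassId = "BIOMASS",
      exchangeIds = ids[vapply(rxn, `[[`, logical(1), "exch")])

    genes <- modelGenes(model)
    p.measured <- hFraction + lFraction
    p.present <- hFraction / p.measured
    measured <- genes[stats::runif(length(genes)) < p.measured]
    calls <- stats::setNames(
      ifelse(stats::runif(length(measured)) < p.present, 1, -1), measured)
    if (!is.null(meta$spurious_gene)) calls[meta$spurious_gene] <- 1
    if (!length(calls)) calls <- stats::setNames(1, genes[1])
    profile <- expressionProfile(call = calls)
    list(model = model, profile = profile, meta = meta)
  })
}

#' Cohort exposing the H/L weighting trade-off
#'
#' One model plus \code{nProfiles} expression profiles designed so that the
#' three weighting schemas resolve the H-versus-L conflict differently. The
#' model contains, besides a mandatory biomass backbone with one L reaction:
#' \itemize{
#'   \item "cheap" branches where a single L reaction feeds two H reactions
#'     (support cost about wL per two activation rewards: included by
#'     schemas 2 and 3, excluded by schema 1);
#'   \item "expensive" branches where three L reactions in series feed one H
#'     reaction (cost about 3 wL per reward: included only by schema 3);
#'   \item free-standing H reactions (included by every schema) and an L
#'     dead branch (never included).
#' }
#' Profiles share this skeleton and differ in random filler-gene calls.
#'
#' @param nProfiles number of expression profiles (default 20).
#' @param seed integer seed for the filler calls.
#' @return list(model, profiles, medium).
#' @export
makeSchemaCohort <- function(nProfiles = 20, seed = 1L) {
  rxn <- list()
  add <- function(id, stoich, lb, ub, gpr = "", exch = FALSE)
    rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                     ub = ub, gpr = gpr, exch = exch)
  ## backbone (one forced L reaction keeps L coverage > 0 everywhere)
  add("EX_S", c(S = -1), -10, 1000, exch = TRUE)
  add("B1", c(S = -1, P = 1), 0, 1000, gpr = "g_bL")      # L on every profile
  add("B2", c(P = -1, Q = 1), 0, 1000, gpr = "g_bH")      # H on every profile
  add("BIOMASS", c(Q = -1), 0, 1000)
  ## cheap branches: one L feeds two H
  for (j in 1:2) {
    t <- paste0("T", j)
    add(paste0("cheapL", j), stats::setNames(c(-1, 1), c("S", t)), 0, 1000,
        gpr = paste0("g_cL", j))
    ## capped H reactions: their activation threshold needs only a small
    ## fraction of the L reaction's capacity, so the support cost per reward
    ## sits between wM and wL
    add(paste0("cheapHa", j), stats::setNames(c(-1, 1), c(t, paste0("Ua", j))),
        0, 2, gpr = paste0("g_cHa", j))
    add(paste0("cheapHb", j), stats::setNames(c(-1, 1), c(t, paste0("Ub", j))),
        0, 2, gpr = paste0("g_cHb", j))
    add(paste0("EX_Ua", j), stats::setNames(-1, paste0("Ua", j)), 0, 1000,
        exch = TRUE)
    add(paste0("EX_Ub", j), stats::setNames(-1, paste0("Ub", j)), 0, 1000,
        exch = TRUE)
  }
  ## expensive branches: three L in series feed one H
  for (j in 1:2) {
    v <- paste0(c("W1_", "W2_", "W3_"), j)
    add(paste0("expL1_", j), stats::setNames(c(-1, 1), c("S", v[1])), 0, 1000,
        gpr = paste0("g_eL1", j))
    add(paste0("expL2_", j), stats::setNames(c(-1, 1), v[1:2]), 0, 1000,
        gpr = paste0("g_eL2", j))
    add(paste0("expL3_", j), stats::setNames(c(-1, 1), v[2:3]), 0, 1000,
        gpr = paste0("g_eL3", j))
    add(paste0("expH", j), stats::setNames(c(-1, 1), c(v[3], paste0("Y", j))),
        0, 1000, gpr = paste0("g_eH", j))
    add(paste0("EX_Y", j), stats::setNames(-1, paste0("Y", j)), 0, 1000,
        exch = TRUE)
  }
  ## free-standing H reactions and an L dead branch
  add("freeH", c(S = -1, F1 = 1), 0, 1000, gpr = "g_fH")
  add("EX_F1", c(F1 = -1), 0, 1000, exch = TRUE)
  add("deadL", c(S = -1, F2 = 1), 0, 1000, gpr = "g_dL")
  add("EX_F2", c(F2 = -1), 0, 1000, exch = TRUE)

  mets <- unique(unlist(lapply(rxn, function(r) names(r$stoich))))
  ids <- vapply(rxn, `[[`, character(1), "id")
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (r in rxn) S[names(r$stoich), r$id] <- r$stoich
  model <- metabolicModel(
    mets, ids, S,
    lb = vapply(rxn, `[[`, numeric(1), "lb"),
    ub = vapply(rxn, `[[`, numeric(1), "ub"),
    gpr = vapply(rxn, `[[`, character(1), "gpr"),
    biomassId = "BIOMASS",
    exchangeIds = ids[vapply(rxn, `[[`, logical(1), "exch")])

  base <- c(g_bL = -1, g_bH = 1,
            g_cL1 = -1, g_cHa1 = 1, g_cHb1 = 1,
            g_cL2 = -1, g_cHa2 = 1, g_cHb2 = 1,
            g_eL11 = -1, g_eL21 = -1, g_eL31 = -1, g_eH1 = 1,
            g_eL12 = -1, g_eL22 = -1, g_eL32 = -1, g_eH2 = 1,
            g_fH = 1, g_dL = -1)
  filler <- paste0("noise", 1:6)
  profiles <- withr::with_seed(seed, {
    lapply(seq_len(nProfiles), function(i) {
      calls <- c(base, stats::setNames(sample(c(-1, 1), length(filler),
                                              replace = TRUE), filler))
      expressionProfile(call = calls)
    })
  })
  list(model = model, profiles = profiles, medium = NULL)
}

#' Cohort with a structural and a context-dependent essential gene
#'
#' Builds a model where gene \code{g_struct} guards the only producer of one
#' biomass precursor (essential whatever the expression evidence says) and
#' gene \code{g_ctx} guards one of two alternative producers of the second
#' precursor. The competing route carries an isozyme GPR
#' ("g_altA or g_altB") and a larger flux capacity, so when both routes are
#' lowly expressed the reconstruction prefers the alternative. On the sample
#' profiles \code{g_ctx} is present while both isozymes are absent, making
#' \code{g_ctx} essential in (ideally) every sample-derived network but only
#' rarely in call-permuted networks.
#'
#' @param nProfiles number of sample profiles (default 20); profiles differ
#'   only in filler-gene calls.
#' @param seed integer seed.
#' @return list(model, profiles, structural_gene, context_gene).
#' @export
makeEssentialityCohort <- function(nProfiles = 20, seed = 1L) {
  rxn <- list()
  add <- function(id, stoich, lb, ub, gpr = "", exch = FALSE)
    rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich, lb = lb,
                                     ub = ub, gpr = gpr, exch = exch)
  add("EX_S", c(S = -1), -10, 1000, exch = TRUE)
  add("Rcore", c(S = -1, P = 1), 0, 1000, gpr = "g_struct")
  ## the context route is capacity-limited, so whenever both routes are
  ## lowly expressed the flux-minimising LP prefers the alternative
  add("Rctx", c(S = -1, Q = 1), 0, 2, gpr = "g_ctx")
  add("Ralt", c(S = -1, Q = 1), 0, 1000, gpr = "g_altA or g_altB")
  add("BIOMASS", c(P = -1, Q = -1), 0, 1000)
  ## filler pathway so permutations have material to shuffle
  for (j in 1:6) {
    add(paste0("Vf", j), stats::setNames(c(-1, 1), c("S", paste0("F", j))),
        0, 1000, gpr = paste0("g_f", j))
    add(paste0("EX_F", j), stats::setNames(-1, paste0("F", j)), 0, 1000,
        exch = TRUE)
  }
  mets <- unique(unlist(lapply(rxn, function(r) names(r$stoich))))
  ids <- vapply(rxn, `[[`, character(1), "id")
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (r in rxn) S[names(r$stoich), r$id] <- r$stoich
  model <- metabolicModel(
    mets, ids, S,
    lb = vapply(rxn, `[[`, numeric(1), "lb"),
    ub = vapply(rxn, `[[`, numeric(1), "ub"),
    gpr = vapply(rxn, `[[`, character(1), "gpr"),
    biomassId = "BIOMASS",
    exchangeIds = ids[vapply(rxn, `[[`, logical(1), "exch")])

  base <- c(g_struct = 1, g_ctx = 1, g_altA = -1, g_altB = -1)
  filler <- paste0("g_f", 1:6)
  profiles <- withr::with_seed(seed, {
    lapply(seq_len(nProfiles), function(i) {
      calls <- c(base, stats::setNames(sample(c(-1, 1), length(filler),
                                              replace = TRUE), filler))
      expressionProfile(call = calls)
    })
  })
  list(model = model, profiles = profiles,
       structural_gene = "g_struct", context_gene = "g_ctx")
}

#' Exact MILP reconstruction oracle
#'
#' Solves the reconstruction problem with binary activation variables and an
#' explicit complementarity constraint per reversible pair (a binary
#' direction selector y with v_f <= cap_f y and v_b <= cap_b (1 - y)), by
#' branch and bound over the package's LP solver. Intended for small
#' instances only; it defines the exact optimum against which the iterative
#' LP heuristic's gap is measured in tests.
#'
#' @param split a \linkS4class{SplitModel} (medium applied).
#' @param classification a \linkS4class{ReactionClassification}.
#' @param fva an \linkS4class{FVAResult}.
#' @param config a \linkS4class{ReconstructionConfig}.
#' @param nodeLimit branch-and-bound node cap; exceeding it returns status
#'   "node_limit" (oracle unavailable), never a silent answer.
#' @return list(status, objective, included, x).
#' @export
milpOracle <- function(split, classification, fva, config,
                       nodeLimit = 100000L) {
  vstar <- resolveBiomassStar(split, config)
  ob <- buildObjective(split, classification, fva, config, vstar)
  n <- length(split@steps)
  nz <- length(ob$zIdx)
  pr <- split@pairs
  caps <- ob$ub[seq_len(n)]
  use <- which(caps[pr$fwd] > config@feasTol & caps[pr$bwd] > config@feasTol)
  ny <- length(use)

  ncol0 <- length(ob$obj)
  obj <- c(ob$obj, rep(0, ny))
  mat <- cbind(as.matrix(ob$mat), matrix(0, nrow(ob$mat), ny))
  dir <- ob$dir; rhs <- ob$rhs
  for (k in seq_len(ny)) {
    f <- pr$fwd[use[k]]; b <- pr$bwd[use[k]]
    rf <- numeric(ncol0 + ny); rf[f] <- 1; rf[ncol0 + k] <- -caps[f]
    rb <- numeric(ncol0 + ny); rb[b] <- 1; rb[ncol0 + k] <- caps[b]
    mat <- rbind(mat, rf, rb)
    dir <- c(dir, "<=", "<=")
    rhs <- c(rhs, 0, caps[b])
  }
  lb <- c(ob$lb, rep(0, ny))
  ub <- c(ob$ub, rep(1, ny))
  ints <- c(unname(ob$zIdx), ncol0 + seq_len(ny))
  sol <- milpSolveDense(obj, mat, dir, rhs, lb, ub, int_vars = ints,
                        node_limit = nodeLimit)
  if (sol$status != "optimal")
    return(list(status = sol$status, objective = NA_real_,
                included = character(0), x = NULL))
  v <- stats::setNames(sol$x[seq_len(n)], split@steps)
  net <- netFluxes(split, v)
  included <- union(names(net)[abs(net) > config@actTol],
                    split@parent@biomassId)
  included <- included[order(match(included, split@parent@reactions))]
  list(status = "optimal", objective = sol$objective, included = included,
       x = sol$x)
}
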