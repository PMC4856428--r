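# The reconstruction LP, spurious-cycle detection, and the iterative
# procedure, validated against the binary-activation MILP oracle.

demoSetup <- function(schema = 3) {
  fx <- makeSpuriousCycleDemo()
  split <- splitReversible(fx$model)
  cfg <- reconstructionConfig(schema = schema)
  vstar <- resolveBiomassStar(split, cfg)
  fva <- computeFvaMax(split, vstar)
  list(fx = fx, split = split, cfg = cfg, vstar = vstar, fva = fva)
}

test_that("objective coefficients follow the scaled weighting rule", {
  # an L step with vmax = 10, delta = 0.1, wL = alpha^2 costs 1e6 per unit
  s <- demoSetup(schema = 1)
  ob <- buildObjective(s$split, s$fx$classification, s$fva, s$cfg, s$vstar)
  i <- match("R1", stepIds(s$split))           # an L step
  expect_equal(ob$obj[i], 1e6 / (0.1 * vmax(s$fva)[["R1"]]),
               tolerance = 1e-9)
  # an L step with vmax exactly 10 costs wL / (delta * vmax) = 1e6 per unit
  m <- chainModel(cap = 10, gpr = c("", "gA", ""))
  cls <- classifyReactions(m, expressionProfile(call = c(gA = -1)))
  sp <- splitReversible(m)
  fva10 <- computeFvaMax(sp, 0.1)
  ob10 <- buildObjective(sp, cls, fva10, reconstructionConfig(schema = 1), 0.1)
  expect_equal(ob10$obj[match("R1", stepIds(sp))], 1e6, tolerance = 1e-9)
  # H steps carry no flux cost, their activation variable is rewarded -wH
  j <- match("R3", stepIds(s$split))
  expect_identical(ob$obj[j], 0)
  expect_equal(unname(ob$obj[ob$zIdx["R3"]]), -1e3, tolerance = 1e-12)
  # blocked H step: no activation variable, flux fixed to zero
  expect_false("R7" %in% names(ob$zIdx))
  expect_identical(ob$ub[match("R7", stepIds(s$split))], 0)
})

test_that("the relaxed LP activates both directions of reversible H pairs", {
  s <- demoSetup()
  ob <- buildObjective(s$split, s$fx$classification, s$fva, s$cfg, s$vstar)
  sol <- solveRelaxedLP(s$split, ob, s$cfg)
  pairs <- detectSpuriousPairs(sol, s$split, s$fx$classification, s$cfg)
  expect_gte(nrow(pairs), 2)
  expect_setequal(pairs$reaction, c("R4", "R9"))
  # net flux of each spurious pair is (numerically) zero
  expect_true(all(abs(pairs$vf - pairs$vb) <= s$cfg@actTol))
  # activation coupling holds: delta vmax z <= v
  v <- fluxes(sol@flux)
  for (st in names(sol@z))
    expect_gte(v[[st]] + s$cfg@feasTol,
               0.1 * vmax(s$fva)[[st]] * sol@z[[st]])
})

test_that("a network whose only biomass route is irreversible H saturates z", {
  m <- chainModel(cap = 10, gpr = c("", "gA", ""))
  cls <- classifyReactions(m, expressionProfile(call = c(gA = 1)))
  sp <- splitReversible(m)
  cfg <- reconstructionConfig()
  fva <- computeFvaMax(sp, 0.1)
  ob <- buildObjective(sp, cls, fva, cfg, 0.1)
  sol <- solveRelaxedLP(sp, ob, cfg)
  expect_equal(unname(sol@z["R1"]), 1, tolerance = 1e-9)
})

test_that("spurious-pair detection ignores one-directional and non-H pairs", {
  s <- demoSetup()
  v <- stats::setNames(numeric(length(stepIds(s$split))), stepIds(s$split))
  v[c("R4_f", "R4_b")] <- 2
  v["R9_f"] <- 2                       # backward inactive
  sol <- new("LPSolution",
             flux = new("FluxState", v = v, objective = 0),
             z = numeric(0), reducedCosts = numeric(0), objective = 0)
  pairs <- detectSpuriousPairs(sol, s$split, s$fx$classification, s$cfg)
  expect_identical(pairs$reaction, "R4")
  # an L-classified pair both-active would not be reported by this detector
  calls <- geneCalls(s$fx$profile); calls["g4"] <- -1
  cls2 <- classifyReactions(s$fx$model, expressionProfile(call = calls))
  pairs2 <- detectSpuriousPairs(sol, s$split, cls2, s$cfg)
  expect_false("R4" %in% pairs2$reaction)
})

test_that("iterative reconstruction removes the cycles and keeps biomass", {
  s <- demoSetup()
  res <- iterativeReconstruct(s$split, s$fx$classification, s$fva, s$cfg)
  inc <- includedReactions(res)
  expect_true(all(c("R2", "R3", "R5", "BIOMASS") %in% inc))
  expect_false(any(c("R1", "R6", "R4", "R9") %in% inc))
  # extracted network alone reaches the biomass requirement
  sub <- extractSubmodel(res, s$split)
  expect_gte(wildTypeBiomass(splitReversible(sub)), s$vstar - 1e-9)
  # no originally reversible reaction is active in both directions
  v <- res@finalFluxes
  pr <- reversiblePairs(s$split)
  expect_true(all(pmin(v[pr$fwd], v[pr$bwd]) <= s$cfg@actTol))
})

test_that("a reversible H reaction on the biomass path keeps one direction", {
  # uptake -> A; A <-> B reversible (H); biomass consumes B
  m <- metabolicModel(
    c("A", "B"), c("EX_A", "Rrev", "BIO"),
    S = matrix(c(-1, 0, -1, 1, 0, -1), nrow = 2),
    lb = c(-10, -20, 0), ub = c(20, 20, 20),
    gpr = c("", "gR", ""), biomassId = "BIO", exchangeIds = "EX_A")
  cls <- classifyReactions(m, expressionProfile(call = c(gR = 1)))
  sp <- splitReversible(m)
  cfg <- reconstructionConfig()
  vstar <- resolveBiomassStar(sp, cfg)
  fva <- computeFvaMax(sp, vstar)
  res <- iterativeReconstruct(sp, cls, fva, cfg)
  expect_true("Rrev" %in% includedReactions(res))
  expect_gt(fluxWitness(res)[["Rrev"]], 0)
})

test_that("relaxed LP optimum bounds the MILP optimum from below", {
  cfg <- reconstructionConfig()
  for (seed in 1:5) {
    f <- makeRandomFixture(nReactions = 12, seed = seed)
    sp <- splitReversible(f$model)
    cls <- classifyReactions(f$model, f$profile)
    vstar <- resolveBiomassStar(sp, cfg)
    fva <- computeFvaMax(sp, vstar)
    ob <- buildObjective(sp, cls, fva, cfg, vstar)
    lp <- solveRelaxedLP(sp, ob, cfg)
    or <- milpOracle(sp, cls, fva, cfg)
    expect_identical(or$status, "optimal")
    expect_lte(lp@objective, or$objective + 1e-6 * (1 + abs(or$objective)))
  }
})

test_that("iteration keeps the LP feasible and the objective monotone", {
  s <- demoSetup()
  res <- iterativeReconstruct(s$split, s$fx$classification, s$fva, s$cfg)
  expect_gte(length(iterationLog(res)), 1)
  ob <- buildObjective(s$split, s$fx$classification, s$fva, s$cfg, s$vstar)
  first <- solveRelaxedLP(s$split, ob, s$cfg)
  expect_gte(objectiveValue(res), first@objective - 1e-6)
})

test_that("coverage reports fractions and the blocked-H ceiling", {
  s <- demoSetup()
  res <- iterativeReconstruct(s$split, s$fx$classification, s$fva, s$cfg)
  cov <- coverage(res)
  expect_equal(cov$H, 2 / 5, tolerance = 1e-12)       # R3, R5 of 5 H
  expect_equal(cov$H_ceiling, 4 / 5, tolerance = 1e-12)  # R7 blocked
  expect_equal(cov$L, 0, tolerance = 1e-12)
  # empty H class reports NA, not zero
  cls.noH <- new("ReactionClassification",
                 label = stats::setNames(rep("M", nReactions(s$fx$model)),
                                         reactionIds(s$fx$model)))
  res2 <- iterativeReconstruct(s$split, cls.noH, s$fva, s$cfg)
  expect_true(is.na(coverage(res2)$H))
})

test_that("rescaling a reaction column and bounds leaves the network unchanged", {
  cfg <- reconstructionConfig()
  f <- makeRandomFixture(seed = 3)
  base <- reconstructNetwork(f$model, f$profile, NULL, cfg)
  for (k in c(0.1, 10)) {
    m2 <- f$model
    j <- match("Vb1", reactionIds(m2))
    # the same reaction written in different flux units
    m2@S[, j] <- m2@S[, j] * k
    m2@lb[j] <- m2@lb[j] / k
    m2@ub[j] <- m2@ub[j] / k
    res <- reconstructNetwork(m2, f$profile, NULL, cfg)
    expect_setequal(includedReactions(res), includedReactions(base))
  }
})

test_that("reconstruction fails clearly when the medium starves biomass", {
  fx <- makeSpuriousCycleDemo()
  cfg <- reconstructionConfig(vbiomassStar = 0.1)
  expect_error(
    reconstructNetwork(fx$model, fx$classification, c(R2 = 0), cfg),
    "infeasible")
})
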