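# Reversible splitting, medium application, FBA and FVA.

test_that("splitting counts steps and assigns bounds per direction", {
  m <- metabolicModel(c("A", "B"), c("R1", "R2"),
                      matrix(c(-1, 1, 1, -1), 2), lb = c(0, -5),
                      ub = c(10, 10), exchangeIds = character(0))
  sp <- splitReversible(m)
  expect_identical(length(stepIds(sp)), 3L)
  expect_identical(nrow(reversiblePairs(sp)), 1L)
  expect_identical(unname(stepUpper(sp)["R2_b"]), 5)
  expect_identical(unname(stepUpper(sp)["R2_f"]), 10)
  # backward column is the negated parent column
  expect_identical(as.numeric(sp@Ssplit[, "R2_b"]),
                   -as.numeric(stoichiometry(m)[, "R2"]))
  # fully irreversible model: identity split
  m2 <- chainModel()
  m2@lb[1] <- 0                       # close the exchange's uptake
  sp2 <- splitReversible(m2)
  expect_identical(stepIds(sp2), reactionIds(m2))
  expect_identical(nrow(reversiblePairs(sp2)), 0L)
})

test_that("medium application closes unlisted uptakes and flags unknown ids", {
  m <- metabolicModel(
    c("A", "B", "C"), c("EX_A", "EX_B", "R1", "BIO"),
    S = matrix(c(-1, 0, 0, 0, -1, 0, -1, -1, 1, 0, 0, -1), nrow = 3),
    lb = c(-20, -20, 0, 0), ub = c(1000, 1000, 1000, 1000),
    biomassId = "BIO", exchangeIds = c("EX_A", "EX_B"))
  sp <- applyMedium(splitReversible(m), c(EX_A = 10))
  expect_identical(unname(stepUpper(sp)["EX_A_b"]), 10)
  expect_identical(unname(stepUpper(sp)["EX_B_b"]), 0)
  # secretion directions stay open
  expect_identical(unname(stepUpper(sp)["EX_A_f"]), 1000)
  expect_error(applyMedium(splitReversible(m), c(R1 = 5)), "non-exchange")
  # a zero bound is equivalent to omission
  sp0 <- applyMedium(splitReversible(m), c(EX_A = 10, EX_B = 0))
  expect_identical(unname(stepUpper(sp0)), unname(stepUpper(sp)))
})

test_that("FBA on a linear chain attains the uptake cap", {
  sp <- splitReversible(chainModel(cap = 10))
  fs <- fbaMax(sp)
  expect_equal(objectiveValue(fs), 10, tolerance = 1e-9)
  # steady state holds
  expect_lt(max(abs(sp@Ssplit %*% fluxes(fs))), 1e-8)
  # unproducible biomass precursor gives optimum 0
  m <- chainModel()
  m@ub[2] <- 0                        # block the conversion
  fs0 <- fbaMax(splitReversible(m))
  expect_equal(objectiveValue(fs0), 0, tolerance = 1e-9)
})

test_that("FBA optimum equals brute-force vertex enumeration on toy models", {
  set.seed(21)
  for (rep in 1:10) {
    # random 2-compound, <=5 step instances
    n <- sample(4:5, 1)
    A <- matrix(sample(c(-1, 0, 1), 2 * n, replace = TRUE), 2, n)
    ub <- round(runif(n, 1, 10), 1)
    obj <- numeric(n); obj[sample(n, 1)] <- 1
    sol <- ternflux:::lpSolveDense(obj, A, rep("==", 2), c(0, 0),
                                   numeric(n), ub, maximize = TRUE)
    ref <- vertexEnumMax(obj, A, c(0, 0), numeric(n), ub)
    if (sol$status == "optimal")
      expect_equal(sol$objective, ref, tolerance = 1e-7)
  }
})

test_that("FVA finds chain maxima, dead ends, and matches per-step oracle", {
  skip_if_not_installed("pracma")
  sp <- splitReversible(chainModel(cap = 10))
  fva <- computeFvaMax(sp, vbiomassStar = 0.1)
  expect_equal(unname(vmax(fva)[c("R1", "BIOMASS")]), c(10, 10),
               tolerance = 1e-9)
  # dead-end side reaction is blocked
  fx <- makeSpuriousCycleDemo()
  spf <- splitReversible(fx$model)
  fvf <- computeFvaMax(spf, 0.1)
  expect_identical(blockedSteps(fvf), "R7")
  # independent per-step LPs on random fixtures
  for (seed in 1:3) {
    f <- makeRandomFixture(seed = seed)
    s <- splitReversible(f$model)
    vstar <- 0.01 * wildTypeBiomass(s)
    mine <- vmax(computeFvaMax(s, vstar))
    ref <- oracleFVA(s, vstar)
    ok <- !is.na(ref)
    expect_true(all(abs(mine[ok] - ref[ok]) <=
                      1e-7 * pmax(1, abs(ref[ok]))))
  }
})

test_that("raising the biomass requirement never raises any FVA maximum", {
  fx <- makeSpuriousCycleDemo()
  sp <- splitReversible(fx$model)
  lo <- vmax(computeFvaMax(sp, 0.1))
  hi <- vmax(computeFvaMax(sp, 5))
  expect_true(all(hi <= lo + 1e-8))
})

test_that("forcing flux through a blocked step is infeasible", {
  fx <- makeSpuriousCycleDemo()
  sp <- splitReversible(fx$model)
  fva <- computeFvaMax(sp, 0.1)
  for (b in blockedSteps(fva)) {
    lower <- stats::setNames(1e-3, b)
    expect_error(fbaMax(sp, lower = lower), "infeasible|FBA problem")
  }
})

test_that("split flux states map back to valid parent-model states", {
  for (seed in 4:6) {
    f <- makeRandomFixture(seed = seed)
    sp <- splitReversible(f$model)
    fs <- fbaMax(sp)
    net <- netFluxes(sp, fs)
    # parent steady state and bounds
    expect_lt(max(abs(stoichiometry(f$model) %*% net)), 1e-7)
    expect_true(all(net >= lowerBounds(f$model) - 1e-7))
    expect_true(all(net <= upperBounds(f$model) + 1e-7))
  }
})

test_that("subsetModel keeps bounds and drops orphan compounds", {
  fx <- makeSpuriousCycleDemo()
  sub <- subsetModel(fx$model, c("R2", "R3", "R5", "BIOMASS"))
  expect_identical(nReactions(sub), 4L)
  expect_false("Z" %in% compoundIds(sub))
  expect_identical(biomassId(sub), "BIOMASS")
  expect_error(subsetModel(fx$model, "nope"), "unknown reaction")
})
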