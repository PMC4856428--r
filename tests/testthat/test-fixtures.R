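# Generators and the MILP oracle.

test_that("the demonstration fixture has the documented label multiset", {
  fx <- makeSpuriousCycleDemo()
  tab <- table(reactionLabels(fx$classification)[paste0("R", 1:10)])
  expect_identical(as.integer(tab[c("H", "M", "L")]), c(5L, 3L, 2L))
  expect_identical(nReactions(fx$model), 11L)   # ten reactions plus biomass
})

test_that("random fixtures are deterministic and validate", {
  f1 <- makeRandomFixture(seed = 99)
  f2 <- makeRandomFixture(seed = 99)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(f1$model, p1)
  writeModelJSON(f2$model, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(geneCalls(f1$profile), geneCalls(f2$profile))
  expect_true(validObject(f1$model))
  # and round-trip through the JSON dialect
  m <- readModelJSON(p1)
  expect_identical(m@gprText, f1$model@gprText)
})

test_that("planted structures behave as constructed", {
  f <- makeRandomFixture(seed = 12)
  sp <- splitReversible(f$model)
  vstar <- 0.01 * wildTypeBiomass(sp)
  fva <- computeFvaMax(sp, vstar)
  # blocked branch is FVA-blocked
  expect_true(f$meta$blocked %in% blockedSteps(fva))
  # isozyme pair: either single knockout is non-essential
  tab <- geneEssentiality(f$model, genes = f$meta$isozyme_genes)
  expect_false(any(tab$essential))
  # the spurious pair's two steps can only run together (net zero)
  pair <- reversiblePairs(sp)
  i <- which(pair$reaction == f$meta$spurious)
  for (dirstep in c(pair$fwd[i], pair$bwd[i])) {
    other <- setdiff(c(pair$fwd[i], pair$bwd[i]), dirstep)
    sp0 <- sp
    sp0@stepUpper[other] <- 0
    fva0 <- computeFvaMax(sp0, vstar)
    expect_lte(vmax(fva0)[dirstep], 1e-9)
  }
})

test_that("the MILP oracle matches hand enumeration on a trivial model", {
  # uptake (M) -> conversion (H) -> biomass: the only sensible network is
  # everything, with one activation earned
  m <- chainModel(cap = 10, gpr = c("", "gA", ""))
  cls <- classifyReactions(m, expressionProfile(call = c(gA = 1)))
  sp <- splitReversible(m)
  cfg <- reconstructionConfig(vbiomassStar = 0.1)
  fva <- computeFvaMax(sp, 0.1)
  or <- milpOracle(sp, cls, fva, cfg)
  expect_identical(or$status, "optimal")
  expect_setequal(or$included, c("EX_A", "R1", "BIOMASS"))
  # hand-computed: flux 1 through the chain (activation threshold of R1),
  # uptake and biomass cost 2 * wM * 0.1 each at vmax 10, reward wH
  delta <- 0.1
  vneed <- delta * vmax(fva)[["R1"]]
  cost <- vneed / (delta * vmax(fva)[["EX_A_b"]]) +
    vneed / (delta * vmax(fva)[["BIOMASS"]])
  expect_equal(or$objective, cost - cfg@wH, tolerance = 1e-6)
})

test_that("oracle solutions contain no net-zero reversible H cycles", {
  fx <- makeSpuriousCycleDemo()
  sp <- splitReversible(fx$model)
  cfg <- reconstructionConfig()
  vstar <- resolveBiomassStar(sp, cfg)
  fva <- computeFvaMax(sp, vstar)
  or <- milpOracle(sp, fx$classification, fva, cfg)
  expect_identical(or$status, "optimal")
  v <- or$x[seq_along(stepIds(sp))]
  pr <- reversiblePairs(sp)
  expect_true(all(pmin(v[pr$fwd], v[pr$bwd]) <= cfg@actTol))
})

test_that("oracle included set equals the iterative result when no cycles arise", {
  m <- chainModel(cap = 10, gpr = c("", "gA", ""))
  cls <- classifyReactions(m, expressionProfile(call = c(gA = 1)))
  sp <- splitReversible(m)
  cfg <- reconstructionConfig(vbiomassStar = 0.1)
  fva <- computeFvaMax(sp, 0.1)
  res <- iterativeReconstruct(sp, cls, fva, cfg)
  or <- milpOracle(sp, cls, fva, cfg)
  expect_setequal(includedReactions(res), or$included)
  expect_length(iterationLog(res), 0)
})
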