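# Model container validity and the JSON / SBML / TSV interfaces.

test_that("constructor validates dimensions, bounds and ids", {
  expect_error(
    metabolicModel(c("A"), c("R1"), matrix(0, 1, 1), lb = 1, ub = -1),
    "lb > ub")
  expect_error(
    metabolicModel(c("A"), c("R1"), matrix(0, 1, 1), 0, 1,
                   biomassId = "nope"),
    "biomassId")
  # internal reaction with empty column is rejected, exchange is fine
  expect_error(
    metabolicModel(c("A"), c("R1", "R2"), matrix(c(-1, 0), 1), c(0, 0),
                   c(1, 1)),
    "empty stoichiometry")
  m <- metabolicModel(c("A"), c("R1", "R2"), matrix(c(-1, 0), 1), c(0, 0),
                      c(1, 1), exchangeIds = "R2")
  expect_s4_class(m, "MetabolicModel")
})

test_that("minimal JSON fixture loads with the expected dimensions", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "compounds": ["A", "B"],
    "reactions": [
      {"id": "EX_A", "stoich": {"A": -1}, "lb": -10, "ub": 1000,
       "gpr": "", "is_exchange": true},
      {"id": "R1", "stoich": {"A": -1, "B": 1}, "lb": 0, "ub": 1000,
       "gpr": "g1", "is_exchange": false},
      {"id": "BIO", "stoich": {"B": -1}, "lb": 0, "ub": 1000,
       "gpr": "", "is_exchange": false}
    ],
    "biomass_id": "BIO"
  }', path)
  m <- readModelJSON(path)
  expect_identical(nCompounds(m), 2L)
  expect_identical(nReactions(m), 3L)
  expect_identical(biomassId(m), "BIO")
  expect_identical(exchangeIds(m), "EX_A")
  expect_identical(unname(isReversible(m)), c(TRUE, FALSE, FALSE))
})

test_that("JSON writer round-trips models byte-identically", {
  fx <- makeSpuriousCycleDemo()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(fx$model, p1)
  m2 <- readModelJSON(p1)
  expect_identical(reactionIds(m2), reactionIds(fx$model))
  expect_identical(as.matrix(stoichiometry(m2)),
                   as.matrix(stoichiometry(fx$model)))
  expect_identical(m2@gprText, fx$model@gprText)
  expect_identical(m2@lb, fx$model@lb)
  writeModelJSON(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("SBML round-trip preserves the model", {
  fx <- makeSpuriousCycleDemo()
  path <- withr::local_tempfile(fileext = ".xml")
  writeModelSBML(fx$model, path)
  m2 <- readModelSBML(path)
  expect_identical(reactionIds(m2), reactionIds(fx$model))
  expect_identical(
    as.matrix(stoichiometry(m2))[compoundIds(fx$model), ],
    as.matrix(stoichiometry(fx$model)))
  expect_identical(m2@lb, fx$model@lb)
  expect_identical(m2@ub, fx$model@ub)
  expect_identical(biomassId(m2), biomassId(fx$model))
  expect_setequal(exchangeIds(m2), exchangeIds(fx$model))
  # GPR trees survive (possibly with extra parentheses in the text)
  expect_identical(m2@gpr, fx$model@gpr)
})

test_that("nested GPR associations survive SBML round-trip", {
  m <- metabolicModel(c("A", "B"), c("R1", "BIO"),
                      matrix(c(-1, 1, 0, -1), 2), c(0, 0), c(5, 5),
                      gpr = c("(gA and gB) or gC", ""), biomassId = "BIO")
  path <- withr::local_tempfile(fileext = ".xml")
  writeModelSBML(m, path)
  m2 <- readModelSBML(path)
  expect_identical(m2@gpr[[1]], m@gpr[[1]])
})

test_that("a malformed GPR in SBML names the offending reaction", {
  path <- withr::local_tempfile(fileext = ".xml")
  fx <- makeSpuriousCycleDemo()
  writeModelSBML(fx$model, path)
  doc <- readLines(path)
  doc <- sub('fbc:geneProduct="g3"', "", doc)   # break R3's association
  writeLines(doc, path)
  expect_error(readModelSBML(path), "R3")
})

test_that("loadModel dispatches on extension and checks existence", {
  expect_error(loadModel("/nonexistent/file.json"), "no such file")
  fx <- makeSpuriousCycleDemo()
  pj <- withr::local_tempfile(fileext = ".json")
  px <- withr::local_tempfile(fileext = ".xml")
  writeModelJSON(fx$model, pj)
  writeModelSBML(fx$model, px)
  expect_identical(reactionIds(loadModel(pj)), reactionIds(fx$model))
  expect_identical(reactionIds(loadModel(px)), reactionIds(fx$model))
  pt <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", pt)
  expect_error(loadModel(pt), "format")
})

test_that("TSV side formats read and write correctly", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exchange_id\tmax_uptake", "EX_A\t10", "EX_B\t2.5"), p)
  med <- readMediumTSV(p)
  expect_identical(med, c(EX_A = 10, EX_B = 2.5))

  writeLines(c("gene_id\tcall", "g1\t1", "g2\t-1"), p)
  prof <- readExpressionTSV(p)
  expect_identical(geneCalls(prof), c(g1 = 1, g2 = -1))

  writeLines(c("gene_id\tz", "g1\t7.2", "g2\t0.4"), p)
  prof <- readExpressionTSV(p, zThreshold = 5)
  expect_identical(unname(geneCalls(prof)), c(1, -1))

  writeLines(c("gene_id\tscore", "g1\t-2.5", "g2\t3"), p)
  expect_identical(readScoresTSV(p), c(g1 = -2.5, g2 = 3))

  writeLines(c("gene_id\twrong", "g1\t1"), p)
  expect_error(readExpressionTSV(p), "missing")

  fx <- makeSpuriousCycleDemo()
  writeClassificationTSV(fx$classification, p)
  cls <- readClassificationTSV(p)
  expect_identical(reactionLabels(cls), reactionLabels(fx$classification))
})
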