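# Call permutation, essentiality frequencies, the one-sided KS test and the
# negative-score fraction.

test_that("permutations preserve the call multiset and honour the seed", {
  prof <- expressionProfile(call = c(A = 1, B = -1, C = 1, D = -1, E = -1))
  perms <- permuteCalls(prof, c("A", "B", "C"), nPermutations = 10, seed = 4)
  expect_length(perms, 10)
  for (p in perms) {
    calls <- geneCalls(p)
    expect_identical(sort(calls[c("A", "B", "C")]),
                     sort(c(A = 1, B = -1, C = 1)), ignore_attr = TRUE)
    # untouched genes keep their call
    expect_identical(calls[c("D", "E")], c(D = -1, E = -1))
  }
  again <- permuteCalls(prof, c("A", "B", "C"), nPermutations = 10, seed = 4)
  expect_identical(lapply(perms, geneCalls), lapply(again, geneCalls))
  other <- permuteCalls(prof, c("A", "B", "C"), nPermutations = 10, seed = 5)
  expect_false(identical(lapply(perms, geneCalls),
                         lapply(other, geneCalls)))
  expect_error(permuteCalls(prof, "A", nPermutations = 0), "positive")
  expect_error(permuteCalls(prof, "nope", 1), "subset")
})

test_that("frequency tables count essential calls per group", {
  tab <- function(genes, ess)
    data.frame(gene = genes, essential = ess,
               knockout_biomass = 0, skipped = FALSE)
  samples <- list(tab(c("a", "b"), c(TRUE, FALSE)),
                  tab(c("a", "b"), c(TRUE, TRUE)),
                  tab(c("a", "b"), c(TRUE, FALSE)),
                  tab(c("a", "b"), c(FALSE, FALSE)))
  random <- list(tab(c("a", "b"), c(FALSE, FALSE)),
                 tab(c("a", "b"), c(TRUE, FALSE)))
  fr <- essentialityFrequency(samples, random)
  expect_equal(fr$freq_sample[fr$gene == "a"], 0.75)
  expect_equal(fr$freq_sample[fr$gene == "b"], 0.25)
  expect_equal(fr$freq_random[fr$gene == "a"], 0.5)
  expect_equal(fr$freq_random[fr$gene == "b"], 0)
  # invariant to input order
  fr2 <- essentialityFrequency(rev(samples), rev(random))
  expect_identical(fr, fr2)
})

test_that("one-sided KS handles the degenerate and extreme cases", {
  same <- ksOneSided(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p.value, 1)
  below <- ksOneSided(1:5, 6:10)          # complete separation, m = n = 5
  expect_identical(below$statistic, 1)
  expect_equal(below$p.value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_error(ksOneSided(numeric(0), 1), "non-empty")
})

test_that("exact KS p-values match independent enumeration for m+n <= 12", {
  set.seed(42)
  cases <- list(
    list(m = 3, n = 4), list(m = 2, n = 6), list(m = 5, n = 5),
    list(m = 4, n = 8), list(m = 6, n = 6), list(m = 1, n = 7))
  for (cs in cases) {
    x <- round(rnorm(cs$m), 2)
    y <- round(rnorm(cs$n, mean = 0.5), 2)
    mine <- ksOneSided(x, y, exact = TRUE)
    expect_equal(mine$p.value, ksExactEnum(x, y), tolerance = 1e-12,
                 label = sprintf("m=%d n=%d", cs$m, cs$n))
  }
  # ties in the pooled sample are handled consistently too
  x <- c(1, 1, 2); y <- c(1, 2, 2, 3)
  expect_equal(ksOneSided(x, y, exact = TRUE)$p.value, ksExactEnum(x, y),
               tolerance = 1e-12)
})

test_that("the KS statistic agrees with the reference implementation", {
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(sample(5:15, 1)); y <- rnorm(sample(5:15, 1))
    expect_equal(ksOneSided(x, y, exact = FALSE)$statistic,
                 unname(suppressWarnings(
                   stats::ks.test(x, y, alternative = "greater")$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("asymptotic p decreases in D and stays within [0, 1]", {
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20) + 2
  r1 <- ksOneSided(x, y, exact = FALSE)
  r2 <- ksOneSided(x, y + 10, exact = FALSE)
  expect_true(r1$p.value >= r2$p.value)
  expect_true(all(c(r1$p.value, r2$p.value) >= 0 &
                    c(r1$p.value, r2$p.value) <= 1))
})

test_that("negative fraction counts strict negatives among scored genes", {
  scores <- c(g1 = -1, g2 = 2, g3 = -3, g4 = 4)
  expect_equal(negativeFraction(scores, names(scores)), 0.5)
  expect_equal(negativeFraction(c(gx = -0.1), "gx"), 1)
  expect_equal(negativeFraction(c(gz = 0), "gz"), 0)   # zero is non-negative
  expect_error(negativeFraction(scores, "unscored"), "undefined")
})

test_that("score comparison wires the pieces together", {
  tab <- data.frame(gene = paste0("g", 1:8),
                    essential = c(rep(TRUE, 3), rep(FALSE, 5)),
                    knockout_biomass = 0, skipped = FALSE)
  scores <- stats::setNames(c(-3, -2, -1, 1, 2, 3, 4, 5), paste0("g", 1:8))
  cmp <- compareScores(tab, scores)
  expect_identical(cmp$ks_statistic, 1)
  expect_equal(cmp$negative_fraction_essential, 1)
  expect_equal(cmp$negative_fraction_all, 3 / 8)
  expect_lt(cmp$ks_pvalue, 0.05)
})

test_that("a structurally essential gene is essential under every classification", {
  # enumerate all 2^4 call assignments of the cohort's core genes (fillers
  # pinned): the gene guarding the sole producer of one biomass precursor
  # must come out essential in the network reconstructed from each of them
  co <- makeEssentialityCohort(nProfiles = 1, seed = 1)
  core <- c("g_struct", "g_ctx", "g_altA", "g_altB")
  fillers <- setdiff(modelGenes(co$model), core)
  cfg <- reconstructionConfig(schema = 3)
  split <- splitReversible(co$model)
  for (mask in 0:15) {
    calls <- stats::setNames(ifelse(bitwAnd(mask, 2^(0:3)) > 0, 1, -1), core)
    calls[fillers] <- 1
    res <- reconstructNetwork(co$model, expressionProfile(call = calls),
                              NULL, cfg)
    sub <- extractSubmodel(res, split)
    tab <- geneEssentiality(sub, genes = "g_struct")
    expect_true(tab$essential, label = paste("call mask", mask))
  }
})
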