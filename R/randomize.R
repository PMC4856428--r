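## Random-permutation backgrounds and comparison statistics.

#' Permute gene calls among the metabolic genes
#'
#' Generates expression profiles in which the +1/-1 calls are shuffled among
#' the metabolic genes only (preserving the multiset of calls); genes outside
#' \code{metabolicGenes} keep their call. Deterministic given the seed: the
#' k-th permutation is drawn from a stream seeded with \code{seed + k - 1}.
#'
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param metabolicGenes character, the genes whose calls are shuffled.
#' @param nPermutations number of permuted profiles (default 10).
#' @param seed integer master seed.
#' @return list of \linkS4class{ExpressionProfile}.
#' @export
permuteCalls <- function(profile, metabolicGenes, nPermutations = 10,
                         seed = 1L) {
  if (nPermutations <= 0) stop("nPermutations must be positive")
  if (!all(metabolicGenes %in% names(profile@geneCall)))
    stop("metabolicGenes must be a subset of the profile's genes")
  lapply(seq_len(nPermutations), function(k) {
    calls <- profile@geneCall
    rng <- .deriveSeed(seed, k)
    withr::with_seed(rng, {
      calls[metabolicGenes] <- sample(calls[metabolicGenes])
    })
    new("ExpressionProfile", geneZ = profile@geneZ, geneCall = calls)
  })
}

## derived stream seeds stay below 2^31
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

#' Per-gene essentiality frequencies across network groups
#'
#' @param sampleTables list of essentiality tables (as returned by
#'   \code{\link{geneEssentiality}}) for the sample-derived networks.
#' @param randomTables list of tables for the permutation-derived networks.
#' @param genes gene universe; defaults to the union of all tables' genes.
#'   A gene absent from a table counts as non-essential in that network.
#' @return data.frame(gene, freq_sample, freq_random, count_sample,
#'   count_random, n_sample, n_random).
#' @export
essentialityFrequency <- function(sampleTables, randomTables = list(),
                                  genes = NULL) {
  if (!length(sampleTables)) stop("need at least one sample table")
  all.tabs <- c(sampleTables, randomTables)
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(all.tabs, `[[`, "gene"))))
  count.in <- function(tabs) {
    vapply(genes, function(g) {
      sum(vapply(tabs, function(t) {
        i <- match(g, t$gene)
        !is.na(i) && isTRUE(t$essential[i])
      }, logical(1)))
    }, numeric(1))
  }
  cs <- count.in(sampleTables)
  cr <- count.in(randomTables)
  ns <- length(sampleTables); nr <- length(randomTables)
  data.frame(gene = genes,
             freq_sample = cs / ns,
             freq_random = if (nr) cr / nr else NA_real_,
             count_sample = cs, count_random = cr,
             n_sample = ns, n_random = nr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the first sample is stochastically smaller than the second
#' (its empirical CDF lies above), via the statistic
#' D+ = sup_x [F1(x) - F2(x)]. The p-value uses the one-sided asymptotic
#' Smirnov formula exp(-2 m n D^2 / (m + n)) capped at 1, or exact
#' enumeration over all assignments of the pooled values to the two groups
#' when \code{exact} (default for m + n <= 16).
#'
#' @param essentialScores numeric scores of the putatively shifted-down group.
#' @param otherScores numeric scores of the reference group.
#' @param exact logical; exact enumeration (combinatorial, only for small
#'   samples) or the asymptotic formula.
#' @return list(statistic, p.value, exact).
#' @export
ksOneSided <- function(essentialScores, otherScores,
                       exact = (length(essentialScores) +
                                length(otherScores)) <= 16) {
  m <- length(essentialScores); n <- length(otherScores)
  if (!m || !n) stop("both score vectors must be non-empty")
  dplus <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(stats::ecdf(x)(pts) - stats::ecdf(y)(pts))
  }
  D <- dplus(essentialScores, otherScores)
  if (exact) {
    pooled <- c(essentialScores, otherScores)
    idx <- utils::combn(m + n, m)
    hits <- 0L
    for (j in seq_len(ncol(idx))) {
      xs <- pooled[idx[, j]]
      ys <- pooled[-idx[, j]]
      if (dplus(xs, ys) >= D - 1e-12) hits <- hits + 1L
    }
    p <- hits / ncol(idx)
  } else {
    p <- min(1, exp(-2 * m * n * D^2 / (m + n)))
  }
  list(statistic = D, p.value = p, exact = exact)
}

#' Fraction of a gene set with negative scores
#'
#' Among the genes of \code{geneSet} that have a score, the fraction with a
#' strictly negative one (a score of exactly 0 counts as non-negative).
#'
#' @param scores named numeric, gene -> score (lower = more essential; the
#'   caller supplies scores already on that sign convention).
#' @param geneSet character gene ids.
#' @return numeric fraction in [0, 1].
#' @export
negativeFraction <- function(scores, geneSet) {
  sc <- scores[intersect(geneSet, names(scores))]
  if (!length(sc))
    stop("no scored genes in the set: negative fraction undefined")
  mean(sc < 0)
}

#' Compare predicted essential genes with external essentiality scores
#'
#' Runs the one-sided KS test of the essential genes' scores against the
#' other metabolic genes' scores (alternative: essential genes have lower
#' scores) and reports the negative-score fractions among essential genes and
#' among all scored genes.
#'
#' @param essentiality an essentiality table from
#'   \code{\link{geneEssentiality}}.
#' @param scores named numeric per-gene scores, lower = more essential
#'   (already sign-adjusted by the provider; this function never re-signs).
#' @param exact passed to \code{\link{ksOneSided}}.
#' @return list(ks_statistic, ks_pvalue, negative_fraction_essential,
#'   negative_fraction_all).
#' @export
compareScores <- function(essentiality, scores, exact = NULL) {
  ess <- essentiality$gene[essentiality$essential %in% TRUE]
  oth <- setdiff(essentiality$gene, ess)
  es <- scores[intersect(ess, names(scores))]
  os <- scores[intersect(oth, names(scores))]
  if (!length(es)) stop("no scored essential genes")
  if (!length(os)) stop("no scored non-essential genes")
  ks <- if (is.null(exact)) ksOneSided(es, os)
        else ksOneSided(es, os, exact = exact)
  list(ks_statistic = ks$statistic,
       ks_pvalue = ks$p.value,
       negative_fraction_essential = negativeFraction(scores, ess),
       negative_fraction_all = negativeFraction(scores, essentiality$gene))
}

#' Sample-vs-random essentiality background for a cohort
#'
#' For each expression profile: reconstruct the context-specific network and
#' compute its essentiality table; then permute the metabolic gene calls
#' \code{nPermutations} times, reconstruct each permuted network (same
#' schema) and compute its table. Returns the per-gene frequency table of the
#' two groups.
#'
#' @param model reference \linkS4class{MetabolicModel}.
#' @param profiles list of \linkS4class{ExpressionProfile}.
#' @param medium named numeric uptake caps (or NULL).
#' @param config a \linkS4class{ReconstructionConfig}.
#' @param nPermutations permuted networks per profile (default 10).
#' @param seed integer master seed.
#' @param essentialTol passed to \code{\link{geneEssentiality}}.
#' @return list(frequency = data.frame, sampleTables, randomTables).
#' @export
essentialityBackground <- function(model, profiles, medium = NULL,
                                   config = reconstructionConfig(),
                                   nPermutations = 10, seed = 1L,
                                   essentialTol = 1e-6) {
  genes <- modelGenes(model)
  run.one <- function(profile) {
    res <- reconstructNetwork(model, profile, medium, config)
    split <- splitReversible(model)
    if (!is.null(medium)) split <- applyMedium(split, medium)
    sub <- extractSubmodel(res, split)
    geneEssentiality(sub, genes = intersect(genes, modelGenes(sub)),
                     essentialTol = essentialTol)
  }
  sampleTables <- lapply(profiles, run.one)
  randomTables <- list()
  for (s in seq_along(profiles)) {
    perms <- permuteCalls(profiles[[s]],
                          intersect(genes, names(profiles[[s]]@geneCall)),
                          nPermutations, seed = .deriveSeed(seed, s))
    randomTables <- c(randomTables, lapply(perms, run.one))
  }
  list(frequency = essentialityFrequency(sampleTables, randomTables,
                                         genes = genes),
       sampleTables = sampleTables, randomTables = randomTables)
}
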