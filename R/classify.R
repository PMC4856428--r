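## From expression evidence to the ternary H/M/L reaction classification.

#' Aggregate probe-level z-scores to gene level
#'
#' The gene value is the median of the z-scores of its mapped probe sets. A
#' probe mapped to several genes contributes to each of them; genes with no
#' probe are absent from the output (never zero-filled).
#'
#' @param probeZ named numeric, probe-set id -> z-score.
#' @param probe2gene data.frame with columns \code{probe_id}, \code{gene_id}
#'   (one row per mapping; a probe may appear several times).
#' @return named numeric, gene id -> median z-score.
#' @examples
#' aggregateProbes(c(p1 = 2, p2 = 4, p3 = 6),
#'                 data.frame(probe_id = c("p1", "p2", "p3"),
#'                            gene_id = c("g", "g", "g")))
#' @export
aggregateProbes <- function(probeZ, probe2gene) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe2gene)))
  z <- probeZ[probe2gene$probe_id]
  keep <- !is.na(z)
  med <- tapply(z[keep], probe2gene$gene_id[keep], stats::median)
  out <- stats::setNames(as.numeric(med), names(med))
  out[sort(names(out))]
}

#' Present/absent gene calls from z-scores
#'
#' A gene is called present (+1) when its z-score reaches the threshold,
#' absent (-1) otherwise. The default threshold of 5 reflects stringent
#' single-sample calling conventions for microarray evidence;
#' precomputed calls are the preferred input and bypass this step entirely.
#'
#' @param geneZ named numeric gene z-scores.
#' @param zThreshold calling threshold (default 5).
#' @return named numeric of +1/-1 calls.
#' @export
callGenes <- function(geneZ, zThreshold = 5) {
  if (is.na(zThreshold)) stop("zThreshold must not be NA")
  stats::setNames(ifelse(geneZ >= zThreshold, 1, -1), names(geneZ))
}

#' Classify reactions as highly/medium/lowly expressed
#'
#' Evaluates each reaction's GPR rule on the +1/-1 gene calls under the
#' ternary algebra (AND = min, OR = max, unmeasured gene = 0): score +1 gives
#' H, 0 gives M, -1 gives L. Reactions with no GPR (spontaneous or
#' orphan reactions) are classified M.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param profile an \linkS4class{ExpressionProfile} (or named call vector).
#' @return A \linkS4class{ReactionClassification}.
#' @export
classifyReactions <- function(model, profile) {
  calls <- if (is(profile, "ExpressionProfile")) profile@geneCall else profile
  score <- vapply(model@gpr, evalGPRTernary, numeric(1), calls = calls)
  lab <- c("L", "M", "H")[score + 2]
  new("ReactionClassification",
      label = stats::setNames(lab, model@reactions))
}
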