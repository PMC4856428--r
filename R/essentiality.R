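## FBA-based gene essentiality with the wild-type reference-flux skip rule.

#' Reactions disabled by a gene knockout
#'
#' A reaction is disabled when its GPR rule evaluates to FALSE with the given
#' gene deleted and every other gene functional. Reactions without a GPR are
#' never disabled. An unknown gene yields an empty set.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param gene gene identifier.
#' @return character vector of reaction ids.
#' @examples
#' m <- metabolicModel(c("A", "B"), c("R1", "R2"),
#'                     matrix(c(-1, 1, 1, -1), 2), c(0, 0), c(10, 10),
#'                     gpr = c("g1 or g2", "g1 and g2"))
#' knockoutReactions(m, "g2")   # only R2 is lost
#' @export
knockoutReactions <- function(model, gene) {
  dead <- vapply(model@gpr, function(tr) {
    !is.null(tr) && !evalGPRBool(tr, gene)
  }, logical(1))
  model@reactions[dead]
}

#' Gene essentiality analysis by single-gene knockout FBA
#'
#' A gene is essential when deleting it (zeroing the bounds of every reaction
#' its GPR loss disables) drops the maximum biomass flux below
#' \code{essentialTol}. To avoid one FBA per gene, a wild-type reference flux
#' distribution is computed first: the flux vector attaining the wild-type
#' biomass maximum with minimum total flux through gene-associated reactions.
#' A knockout touching only reactions that carry no flux in that reference
#' distribution cannot change the optimum, so the gene is skipped as
#' non-essential without an LP.
#'
#' @param model a \linkS4class{MetabolicModel} (typically a reconstructed
#'   subnetwork with medium-adjusted bounds).
#' @param genes genes to test; default all genes in the model's GPRs.
#' @param essentialTol biomass flux below which the knockout counts as lethal.
#'   The default \code{1e-6} reads "unable to produce biomass" as a numerically
#'   zero optimum; pass the reconstruction's minimum biomass flux for the
#'   stricter reading.
#' @param actTol activity threshold used by the skip rule.
#' @param feasTol solver tolerance.
#' @param skip use the reference-distribution skip rule (default TRUE;
#'   FALSE forces one knockout FBA per gene).
#' @return data.frame(gene, essential, knockout_biomass, skipped). Genes with
#'   a failed knockout solve get \code{NA} biomass and are flagged in the
#'   \code{solver_ok} attribute.
#' @export
geneEssentiality <- function(model, genes = modelGenes(model),
                             essentialTol = 1e-6, actTol = 1e-6,
                             feasTol = 1e-9, skip = TRUE) {
  split <- splitReversible(model)
  wt <- fbaMax(split, feasTol = feasTol)
  wt.max <- objectiveValue(wt)
  if (wt.max < essentialTol)
    stop("wild-type network cannot produce biomass above essentialTol")

  ref <- NULL
  if (skip) {
    ## minimise total flux through gene-associated reactions at fixed
    ## (wild-type maximal) biomass
    has.gene <- !vapply(model@gpr, is.null, logical(1))
    gene.rxns <- model@reactions[has.gene]
    gene.steps <- which(split@origin %in% gene.rxns)
    obj <- numeric(length(split@steps))
    obj[gene.steps] <- 1
    bio <- .biomassStep(split)
    lo <- numeric(length(split@steps))
    lo[bio] <- wt.max * (1 - 1e-9)
    sol <- .splitLP(split, obj, maximize = FALSE, lower = lo,
                    feasTol = feasTol)
    if (sol$status != "optimal")
      stop("reference flux distribution LP is ", sol$status)
    ref <- stats::setNames(sol$x, split@steps)
  }

  n <- length(genes)
  essential <- logical(n); kos <- numeric(n); skipped <- logical(n)
  solver.ok <- rep(TRUE, n)
  for (g in seq_len(n)) {
    rxns <- knockoutReactions(model, genes[g])
    steps <- which(split@origin %in% rxns)
    if (!length(steps)) {
      essential[g] <- FALSE; kos[g] <- wt.max; skipped[g] <- FALSE
      next
    }
    if (skip && all(ref[steps] <= actTol)) {
      essential[g] <- FALSE; kos[g] <- wt.max; skipped[g] <- TRUE
      next
    }
    ko.split <- split
    ko.split@stepUpper[steps] <- 0
    opt <- tryCatch(objectiveValue(fbaMax(ko.split, feasTol = feasTol)),
                    error = function(e) NA_real_)
    if (is.na(opt)) { solver.ok[g] <- FALSE; kos[g] <- NA_real_; next }
    kos[g] <- opt
    essential[g] <- opt < essentialTol
  }
  out <- data.frame(gene = genes, essential = essential,
                    knockout_biomass = kos, skipped = skipped,
                    stringsAsFactors = FALSE)
  attr(out, "wild_type_biomass") <- wt.max
  attr(out, "solver_ok") <- solver.ok
  out
}
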