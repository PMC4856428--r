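## Gene-protein-reaction (GPR) rules: parsing and evaluation.
##
## A GPR is a boolean expression over gene identifiers ("g1 and (g2 or g3)").
## Internally a rule is a nested list: either list(gene = "id") or
## list(op = "and"/"or", args = list(...)). NULL means "no gene associated".

.gprTokenize <- function(text) {
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, list(m))[[1]]
}

#' Parse a GPR rule string into an expression tree
#'
#' Accepts \code{and}/\code{or} (any case), \code{&}/\code{&&},
#' \code{|}/\code{||} and parentheses; everything else is a gene identifier.
#' \code{or} binds looser than \code{and}. Empty or whitespace-only strings
#' parse to \code{NULL}, the explicit "no gene associated" marker.
#'
#' @param text GPR rule string (or \code{NA}/\code{NULL}).
#' @return A GPR tree (nested list), or \code{NULL} for no rule.
#' @examples
#' parseGPR("g1 and (g2 or g3)")
#' @export
parseGPR <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(NULL)
  toks <- .gprTokenize(text)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  is.op <- function(t, which) {
    !is.na(t) && tolower(t) %in% which
  }
  parse.expr <- function() {
    node <- parse.term()
    args <- list(node)
    while (is.op(peek(), c("or", "|", "||"))) {
      advance()
      args[[length(args) + 1L]] <- parse.term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse.term <- function() {
    node <- parse.factor()
    args <- list(node)
    while (is.op(peek(), c("and", "&", "&&"))) {
      advance()
      args[[length(args) + 1L]] <- parse.factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse.factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in '", text, "'")
    if (t == "(") {
      advance()
      node <- parse.expr()
      if (!identical(peek(), ")"))
        stop("GPR parse error: missing ')' in '", text, "'")
      advance()
      return(node)
    }
    if (t == ")" || is.op(t, c("and", "&", "&&", "or", "|", "||")))
      stop("GPR parse error: unexpected token '", t, "' in '", text, "'")
    advance()
    list(gene = t)
  }
  out <- parse.expr()
  if (pos <= length(toks))
    stop("GPR parse error: trailing token '", toks[pos], "' in '", text, "'")
  out
}

#' Genes referenced by a GPR tree
#' @param tree GPR tree from \code{\link{parseGPR}} (or \code{NULL}).
#' @return character vector of gene identifiers (unique, possibly empty).
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (!is.null(tree$gene)) return(tree$gene)
  unique(unlist(lapply(tree$args, gprGenes)))
}

#' Evaluate a GPR tree on ternary gene calls
#'
#' Ternary algebra over \{-1, 0, +1\}: AND = min, OR = max. Genes absent from
#' \code{calls} (no expression evidence) score 0, so an unmeasured gene never
#' forces a reaction into the lowly-expressed class.
#'
#' @param tree GPR tree; \code{NULL} returns 0 (no evidence).
#' @param calls named numeric vector of +1/-1 present/absent gene calls.
#' @return -1, 0 or +1.
#' @export
evalGPRTernary <- function(tree, calls) {
  if (is.null(tree)) return(0)
  if (!is.null(tree$gene)) {
    v <- calls[tree$gene]
    if (is.na(v)) return(0)
    return(unname(v))
  }
  vals <- vapply(tree$args, evalGPRTernary, numeric(1), calls = calls)
  if (tree$op == "and") min(vals) else max(vals)
}

#' Evaluate a GPR tree as a boolean under a gene knockout
#'
#' All genes are taken as functional except those in \code{knockout}; used to
#' decide which reactions a deletion disables.
#'
#' @param tree GPR tree; \code{NULL} (no gene) is always functional.
#' @param knockout character vector of deleted gene identifiers.
#' @return logical: does the reaction retain enzymatic support?
#' @export
evalGPRBool <- function(tree, knockout) {
  if (is.null(tree)) return(TRUE)
  if (!is.null(tree$gene)) return(!(tree$gene %in% knockout))
  vals <- vapply(tree$args, evalGPRBool, logical(1), knockout = knockout)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Deparse a GPR tree back to rule text
#' @param tree GPR tree or \code{NULL}.
#' @return character rule string (\code{""} for no rule).
#' @export
deparseGPR <- function(tree) {
  if (is.null(tree)) return("")
  if (!is.null(tree$gene)) return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- deparseGPR(a)
    if (is.null(a$gene) && !identical(a$op, tree$op)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
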