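# Independent oracles used across tests. These never call the package's own
# solver paths: pracma::linprog (an unrelated simplex implementation) for LPs,
# exhaustive enumeration elsewhere.

# max/min obj over { x : Aeq x = beq, lb <= x <= ub } via pracma, with bounds
# encoded as inequality rows (pracma assumes x >= 0).
oracleLP <- function(obj, Aeq, beq, ub, lb = NULL, maximize = FALSE) {
  n <- length(obj)
  A <- diag(n); b <- ub
  keep <- is.finite(ub)
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  if (!is.null(lb) && any(lb > 0)) {
    pos <- which(lb > 0)
    A <- rbind(A, -diag(n)[pos, , drop = FALSE])
    b <- c(b, -lb[pos])
  }
  res <- pracma::linprog(if (maximize) -obj else obj, A = A, b = b,
                         Aeq = Aeq, beq = beq, maxiter = 5000)
  if (is.null(res$x)) return(NULL)
  list(x = res$x, objective = if (maximize) -res$fval else res$fval)
}

# brute-force LP maximum by enumerating candidate vertices: every selection of
# m basic columns with the others pinned at a bound combination. Only for tiny
# instances.
vertexEnumMax <- function(obj, Aeq, beq, lb, ub, tol = 1e-8) {
  n <- length(obj); m <- nrow(Aeq)
  best <- -Inf
  bases <- utils::combn(n, m, simplify = FALSE)
  for (basic in bases) {
    nonbasic <- setdiff(seq_len(n), basic)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nonbasic)))
    for (g in seq_len(nrow(grid))) {
      xn <- ifelse(unlist(grid[g, ]), ub[nonbasic], lb[nonbasic])
      if (any(!is.finite(xn))) next
      B <- Aeq[, basic, drop = FALSE]
      xb <- tryCatch(solve(B, beq - Aeq[, nonbasic, drop = FALSE] %*% xn),
                     error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n); x[basic] <- xb; x[nonbasic] <- xn
      if (all(x >= lb - tol & x <= ub + tol))
        best <- max(best, sum(obj * x))
    }
  }
  best
}

# independent per-step FVA: fresh pracma LP per step, no shared state
oracleFVA <- function(split, vstar) {
  S <- as.matrix(stoichiometry(split@parent))[, split@origin, drop = FALSE] %*%
    diag(split@direction, length(split@direction))
  n <- length(stepIds(split))
  ub <- unname(stepUpper(split))
  lb <- numeric(n)
  bio <- which(split@direction > 0 &
                 split@origin == biomassId(split@parent))[1]
  lb[bio] <- vstar
  vapply(seq_len(n), function(i) {
    if (ub[i] <= 1e-9) return(0)
    obj <- numeric(n); obj[i] <- 1
    res <- oracleLP(obj, S, numeric(nrow(S)), ub, lb, maximize = TRUE)
    if (is.null(res)) NA_real_ else res$objective
  }, numeric(1))
}

# exhaustive one-sided two-sample KS p-value: recursive enumeration of all
# group assignments of the pooled sample (deliberately not combn-based, to
# stay independent of the implementation)
ksExactEnum <- function(x, y) {
  dplus <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1)))
  }
  D <- dplus(x, y)
  pooled <- c(x, y)
  m <- length(x); N <- length(pooled)
  hits <- 0L; total <- 0L
  recurse <- function(idx, start, left) {
    if (left == 0L) {
      total <<- total + 1L
      if (dplus(pooled[idx], pooled[-idx]) >= D - 1e-12) hits <<- hits + 1L
      return(invisible())
    }
    for (i in start:(N - left + 1L)) recurse(c(idx, i), i + 1L, left - 1L)
  }
  recurse(integer(0), 1L, m)
  hits / total
}

# three-reaction chain model used in several places:
# EX_A (uptake <= cap) -> conversion A -> B -> biomass consumes B
chainModel <- function(cap = 10, gpr = c("", "gA", "")) {
  metabolicModel(
    compounds = c("A", "B"),
    reactions = c("EX_A", "R1", "BIOMASS"),
    S = matrix(c(-1, 0, -1, 1, 0, -1), nrow = 2),
    lb = c(-cap, 0, 0), ub = c(1000, 1000, 1000),
    gpr = gpr, biomassId = "BIOMASS", exchangeIds = "EX_A")
}
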