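## Dense bounded-variable linear programming.
##
## The reconstruction algorithm is driven by LP solutions *and their reduced
## costs*, so the solver must expose exact simplex duals deterministically.
## Problems in this package are small (tens of rows/columns), hence a dense
## two-phase revised simplex with explicit refactorisation at every iteration:
## slow asymptotically, but numerically transparent and fully reproducible.

#' Solve a dense linear program
#'
#' Minimises (or maximises) \code{obj \%*\% x} subject to
#' \code{mat \%*\% x (dir) rhs} and \code{lb <= x <= ub}, using a two-phase
#' bounded-variable revised simplex method. Reduced costs and row duals of the
#' optimal basis are returned; these are exact simplex quantities (basic
#' variables have reduced cost zero) and are deterministic across runs for
#' identical inputs (Dantzig pricing with index tie-breaks, Bland's rule as
#' anti-cycling fallback).
#'
#' @param obj numeric objective coefficients (length n).
#' @param mat constraint matrix (m x n), dense or \pkg{Matrix} sparse.
#' @param dir character vector of constraint senses, each \code{"=="},
#'   \code{"<="} or \code{">="}.
#' @param rhs numeric right-hand side (length m).
#' @param lb,ub variable bounds; \code{lb} must be finite for every variable,
#'   \code{ub} may be \code{Inf}.
#' @param maximize logical; maximise instead of minimise.
#' @param tol feasibility/pivot tolerance.
#' @param maxit iteration cap across both phases.
#'
#' @return A list with elements \code{status} (\code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"} or \code{"maxit"}), \code{x},
#'   \code{objective}, \code{reduced_costs} (length n, on the minimisation
#'   scale), \code{duals} (length m) and \code{iterations}.
#' @keywords internal
lpSolveDense <- function(obj, mat, dir, rhs, lb, ub,
                         maximize = FALSE, tol = 1e-9, maxit = 20000L) {
  mat <- as.matrix(mat)
  m <- nrow(mat); n0 <- ncol(mat)
  stopifnot(length(obj) == n0, length(dir) == m, length(rhs) == m,
            length(lb) == n0, length(ub) == n0)
  if (any(!is.finite(lb)))
    stop("lpSolveDense requires finite lower bounds on all variables")
  if (any(lb > ub + tol))
    stop("lpSolveDense: lb > ub")
  obj <- as.numeric(obj)
  if (maximize) obj <- -obj

  ## slack variables turn every row into an equality
  n.slack <- sum(dir != "==")
  A <- cbind(mat, matrix(0, m, n.slack), diag(1, m, m))  # slacks + artificials
  lbv <- c(lb, rep(0, n.slack), rep(0, m))
  ubv <- c(ub, rep(Inf, n.slack), rep(Inf, m))
  sl <- n0
  for (i in seq_len(m)) {
    if (dir[i] == "<=") { sl <- sl + 1L; A[i, sl] <- 1 }
    else if (dir[i] == ">=") { sl <- sl + 1L; A[i, sl] <- -1 }
    else if (dir[i] != "==") stop("unknown constraint sense: ", dir[i])
  }
  n.real <- n0 + n.slack
  art.idx <- n.real + seq_len(m)
  n <- n.real + m

  ## start: structural variables nonbasic at lb, artificials basic, signed so
  ## that the starting basic values are nonnegative
  resid <- as.numeric(rhs - A[, seq_len(n.real), drop = FALSE] %*% lbv[seq_len(n.real)])
  for (i in seq_len(m)) if (resid[i] < 0) A[i, art.idx[i]] <- -1
  basis <- art.idx
  atup <- rep(FALSE, n)   # meaningful for nonbasic variables only

  run.phase <- function(cost, basis, atup, it0, phase1) {
    it <- it0
    bland.after <- it0 + 50L * (n + m)
    cscale <- 1 + max(abs(cost))
    repeat {
      if (it >= maxit)
        return(list(status = "maxit", iterations = it))
      nonbasic <- setdiff(seq_len(n), basis)
      xN <- ifelse(atup[nonbasic], ubv[nonbasic], lbv[nonbasic])
      B <- A[, basis, drop = FALSE]
      fac <- tryCatch(list(
        xB = as.numeric(solve(B, rhs - A[, nonbasic, drop = FALSE] %*% xN)),
        y = as.numeric(solve(t(B), cost[basis]))),
        error = function(e) NULL)
      if (is.null(fac))
        return(list(status = "singular", iterations = it))
      xB <- fac$xB; y <- fac$y
      dN <- cost[nonbasic] -
        as.numeric(crossprod(A[, nonbasic, drop = FALSE], y))

      free <- ubv[nonbasic] - lbv[nonbasic] > tol
      viol <- ifelse(atup[nonbasic], dN, -dN)       # positive => improving move
      cand <- which(free & viol > tol * cscale)
      if (!length(cand)) {
        x <- numeric(n); x[nonbasic] <- xN; x[basis] <- xB
        d <- numeric(n); d[nonbasic] <- dN
        return(list(status = "optimal", basis = basis, atup = atup,
                    x = x, y = y, d = d, iterations = it))
      }
      if (it > bland.after) {
        j.loc <- cand[which.min(nonbasic[cand])]    # Bland's rule
      } else {
        best <- max(viol[cand])
        tied <- cand[viol[cand] >= best * (1 - 1e-12)]
        j.loc <- tied[which.min(nonbasic[tied])]
      }
      j <- nonbasic[j.loc]
      up <- !atup[j]                  # entering increases from lb, else decreases
      w <- as.numeric(solve(B, A[, j]))
      ws <- if (up) w else -w         # xB changes by -ws * t

      ts <- rep(Inf, m)
      to.upper <- rep(FALSE, m)
      dec <- which(ws > tol)          # basic decreases toward its lb
      if (length(dec)) ts[dec] <- (xB[dec] - lbv[basis[dec]]) / ws[dec]
      inc <- which(ws < -tol & is.finite(ubv[basis]))
      if (length(inc)) { ts[inc] <- (ubv[basis[inc]] - xB[inc]) / (-ws[inc]); to.upper[inc] <- TRUE }
      ts[ts < 0] <- 0                 # degeneracy guard
      tflip <- ubv[j] - lbv[j]
      tmin.basic <- if (all(!is.finite(ts))) Inf else min(ts)
      if (!is.finite(tmin.basic) && !is.finite(tflip))
        return(list(status = "unbounded", iterations = it))
      if (tflip <= tmin.basic) {      # bound flip, basis unchanged
        atup[j] <- !atup[j]
      } else {
        hit <- which(ts <= tmin.basic + tol * (1 + tmin.basic))
        leave <- hit[which.min(basis[hit])]
        lv <- basis[leave]
        basis[leave] <- j
        atup[lv] <- to.upper[leave]
      }
      it <- it + 1L
    }
  }

  cost1 <- c(rep(0, n.real), rep(1, m))
  ph1 <- run.phase(cost1, basis, atup, 0L, TRUE)
  if (ph1$status != "optimal")
    return(list(status = if (ph1$status == "unbounded") "infeasible" else ph1$status,
                x = NULL, objective = NA_real_,
                reduced_costs = NULL, duals = NULL, iterations = ph1$iterations))
  if (sum(ph1$x[art.idx]) > 1e-7 * (1 + max(abs(rhs))))
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                reduced_costs = NULL, duals = NULL, iterations = ph1$iterations))
  ubv[art.idx] <- 0                  # artificials pinned to zero in phase 2

  cost2 <- c(obj, rep(0, n.slack + m))
  ph2 <- run.phase(cost2, ph1$basis, ph1$atup, ph1$iterations, FALSE)
  if (ph2$status != "optimal")
    return(list(status = ph2$status, x = NULL, objective = NA_real_,
                reduced_costs = NULL, duals = NULL, iterations = ph2$iterations))
  x <- ph2$x[seq_len(n0)]
  objective <- sum(obj * x)
  list(status = "optimal",
       x = x,
       objective = if (maximize) -objective else objective,
       reduced_costs = ph2$d[seq_len(n0)],
       duals = ph2$y,
       iterations = ph2$iterations)
}

#' Branch-and-bound mixed-integer LP on top of \code{lpSolveDense}
#'
#' Depth-first branch and bound with most-fractional branching and LP bound
#' pruning. Used only by the MILP reconstruction oracle in testing; the
#' production reconstruction path is purely LP-based.
#'
#' @inheritParams lpSolveDense
#' @param int_vars integer indices of variables constrained to be integral.
#' @param node_limit maximum number of branch-and-bound nodes explored.
#' @param int_tol integrality tolerance.
#' @return list(status, x, objective, nodes); status \code{"node_limit"} marks
#'   an exhausted search budget (oracle unavailable), never a silent answer.
#' @keywords internal
milpSolveDense <- function(obj, mat, dir, rhs, lb, ub, int_vars,
                           maximize = FALSE, tol = 1e-9,
                           node_limit = 50000L, int_tol = 1e-6) {
  sgn <- if (maximize) -1 else 1
  best.x <- NULL
  best.obj <- Inf           # minimisation scale
  nodes <- 0L
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit)
      return(list(status = "node_limit", x = best.x,
                  objective = if (is.null(best.x)) NA_real_ else sgn * best.obj,
                  nodes = nodes))
    sol <- lpSolveDense(obj, mat, dir, rhs, nd$lb, nd$ub,
                        maximize = maximize, tol = tol)
    if (sol$status != "optimal") next
    relax <- sgn * sol$objective
    if (is.finite(best.obj) && relax >= best.obj - 1e-9 * (1 + abs(best.obj))) next
    frac <- abs(sol$x[int_vars] - round(sol$x[int_vars]))
    if (all(frac <= int_tol)) {
      best.obj <- relax
      best.x <- sol$x
      next
    }
    jb <- int_vars[which.max(frac)]
    xv <- sol$x[jb]
    lo <- nd; hi <- nd
    lo$ub[jb] <- floor(xv)
    hi$lb[jb] <- ceiling(xv)
    ## explore the nearer side first (pushed last => popped first)
    if (xv - floor(xv) <= 0.5) stack <- c(stack, list(hi), list(lo))
    else stack <- c(stack, list(lo), list(hi))
  }
  if (is.null(best.x))
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                nodes = nodes))
  list(status = "optimal", x = best.x, objective = sgn * best.obj, nodes = nodes)
}
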