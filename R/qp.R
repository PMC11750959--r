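#' Dense convex quadratic program solver (active set)
#'
#' Minimises `0.5 * t(x) %*% Q %*% x + crossprod(cvec, x)` subject to
#' `Aeq %*% x == beq` and `lb <= x <= ub`. `Q` must be symmetric positive
#' definite. The solver is a primal-dual active-set iteration over the box
#' bounds: each step solves the equality-constrained KKT system with the
#' current working set of bounds clamped, then either clamps the most
#' violated bound or releases a bound whose multiplier has the wrong sign.
#' Because the objective is strictly convex the stationary point of each
#' subproblem is unique, and the iteration terminates on well-posed problems.
#'
#' Redundant equality rows are removed by a rank-revealing QR; inconsistent
#' equality systems are reported as infeasible rather than solved in a
#' least-squares sense.
#'
#' @param Q symmetric positive definite matrix (n x n).
#' @param cvec linear term, length n.
#' @param Aeq equality constraint matrix (m x n) or NULL.
#' @param beq equality right-hand side, length m.
#' @param lb,ub box bounds, length n (may contain +/-Inf).
#' @param tol feasibility tolerance (default 1e-9).
#' @param max_iter iteration cap.
#' @return list with `x`, `status` ("optimal", "infeasible",
#'   "inconsistent_equalities"), `eq_residual` (max abs equality violation),
#'   `lambda` (equality multipliers, on the reduced row set), `iterations`.
#' @keywords internal
qp_active_set <- function(Q, cvec = NULL, Aeq = NULL, beq = NULL,
                          lb = NULL, ub = NULL, tol = 1e-9,
                          max_iter = NULL) {
  n <- nrow(Q)
  stopifnot(ncol(Q) == n)
  if (is.null(cvec)) cvec <- numeric(n)
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  if (any(lb > ub + tol)) {
    bad <- which(lb > ub + tol)
    return(list(x = rep(NA_real_, n), status = "infeasible",
                eq_residual = NA_real_, lambda = NULL, iterations = 0L,
                conflict = paste0("bound ", bad, ": lb > ub")))
  }
  if (is.null(max_iter)) max_iter <- 100L + 20L * n

  # reduce equality system to an independent, consistent row subset
  if (!is.null(Aeq) && nrow(Aeq) > 0L) {
    Aeq <- as.matrix(Aeq)
    qra <- qr(t(Aeq))
    r <- qra$rank
    keep <- qra$pivot[seq_len(r)]
    qrb <- qr(cbind(Aeq, beq))
    if (qrb$rank > r) {
      return(list(x = rep(NA_real_, n), status = "inconsistent_equalities",
                  eq_residual = NA_real_, lambda = NULL, iterations = 0L))
    }
    Aeq <- Aeq[keep, , drop = FALSE]
    beq <- beq[keep]
    m <- nrow(Aeq)
  } else {
    Aeq <- matrix(0, 0L, n); beq <- numeric(0L); m <- 0L
  }

  active <- integer(0L)       # indices of clamped variables
  side <- integer(0L)         # -1 lower, +1 upper
  iter <- 0L
  seen <- character(0L)       # visited working sets, to catch cycling
  infeasible_out <- function(iters)
    list(x = rep(NA_real_, n), status = "infeasible",
         eq_residual = NA_real_, lambda = NULL, iterations = iters)
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("QP active-set iteration failed to converge")
    sig <- paste(active * side, collapse = ",")
    if (sig %in% seen) return(infeasible_out(iter))
    seen <- c(seen, sig)
    k <- length(active)
    E <- matrix(0, k, n)
    if (k > 0L) E[cbind(seq_len(k), active)] <- 1
    bW <- ifelse(side < 0L, lb[active], ub[active])
    K <- rbind(cbind(Q, t(Aeq), t(E)),
               cbind(Aeq, matrix(0, m, m + k)),
               cbind(E, matrix(0, k, m + k)))
    rhs <- c(-cvec, beq, bW)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      # singular working-set system (clamps conflict with equalities):
      # fall back to the minimum-norm least-squares solution, whose
      # equality residual then routes the iteration to "infeasible"
      sv <- svd(K)
      pos <- sv$d > max(sv$d) * 1e-12
      sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
    })
    x <- sol[seq_len(n)]
    lambda <- if (m > 0L) sol[n + seq_len(m)] else numeric(0L)
    mu <- if (k > 0L) sol[n + m + seq_len(k)] else numeric(0L)

    viol_lo <- lb - x
    viol_up <- x - ub
    viol_lo[active] <- -Inf
    viol_up[active] <- -Inf
    worst_lo <- if (any(is.finite(viol_lo))) max(viol_lo) else -Inf
    worst_up <- if (any(is.finite(viol_up))) max(viol_up) else -Inf
    if (max(worst_lo, worst_up) > tol) {
      if (k == n) return(infeasible_out(iter))
      if (worst_lo >= worst_up) {
        j <- which.max(viol_lo); active <- c(active, j); side <- c(side, -1L)
      } else {
        j <- which.max(viol_up); active <- c(active, j); side <- c(side, 1L)
      }
      next
    }
    # optimality of the working set: lower-bound multipliers must be <= 0,
    # upper-bound multipliers >= 0 (stationarity Qx + c + Aeq'l + E'mu = 0)
    bad <- which((side < 0L & mu > tol) | (side > 0L & mu < -tol))
    if (length(bad) > 0L) {
      drop <- bad[which.max(abs(mu[bad]))]
      active <- active[-drop]; side <- side[-drop]
      next
    }
    eq_res <- if (m > 0L) max(abs(Aeq %*% x - beq)) else 0
    status <- if (eq_res <= sqrt(tol)) "optimal" else "infeasible"
    return(list(x = x, status = status, eq_residual = eq_res,
                lambda = lambda, iterations = iter))
  }
}

#' Solve an equality-constrained QP directly through its KKT system
#'
#' Independent oracle for [qp_active_set()] when no bound is active:
#' assembles `[Q A'; A 0] [x; l] = [-c; b]` and solves it with a single
#' dense linear solve.
#'
#' @inheritParams qp_active_set
#' @return numeric solution vector `x`.
#' @keywords internal
qp_kkt_solve <- function(Q, cvec = NULL, Aeq, beq) {
  n <- nrow(Q)
  if (is.null(cvec)) cvec <- numeric(n)
  Aeq <- as.matrix(Aeq)
  qra <- qr(t(Aeq))
  keep <- qra$pivot[seq_len(qra$rank)]
  A <- Aeq[keep, , drop = FALSE]
  b <- beq[keep]
  m <- nrow(A)
  K <- rbind(cbind(Q, t(A)), cbind(A, matrix(0, m, m)))
  sol <- solve(K, c(-cvec, b))
  sol[seq_len(n)]
}
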