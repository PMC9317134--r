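# Dense bounded-variable two-phase primal simplex.
#
# Solves   min c'x  s.t.  Aeq x = beq,  Aub x <= bub,  lb <= x <= ub
# with +/-Inf bounds allowed.  Bland's smallest-index rule is used for both
# the entering and the leaving choice, which guarantees finite termination
# on the degenerate problems that routinely arise from flux polytopes.
# Problems here are desk-scale (tens of variables), so the basis system is
# re-solved densely at every iteration for numerical robustness.
#
# Returns list(status, x, objective, infeasibility) where status is one of
# "optimal", "infeasible", "unbounded"; `infeasibility` is the phase-1
# residual (0 when feasible).  `feas_tol` sets the phase-1 acceptance
# threshold, allowing deliberately relaxed feasibility checks.

lp_solve <- function(c_obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                     lb = NULL, ub = NULL, maximize = FALSE,
                     feas_tol = 1e-9, opt_tol = 1e-9, max_iter = NULL) {
  nx <- length(c_obj)
  c_obj <- as.numeric(c_obj)
  if (maximize) c_obj <- -c_obj
  if (is.null(lb)) lb <- rep(-Inf, nx)
  if (is.null(ub)) ub <- rep(Inf, nx)
  stopifnot(length(lb) == nx, length(ub) == nx)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, nx),
                objective = NA_real_, infeasibility = Inf))
  }
  Aeq <- if (is.null(Aeq)) matrix(0, 0L, nx) else as.matrix(Aeq)
  Aub <- if (is.null(Aub)) matrix(0, 0L, nx) else as.matrix(Aub)
  beq <- as.numeric(if (is.null(beq)) numeric(0) else beq)
  bub <- as.numeric(if (is.null(bub)) numeric(0) else bub)
  stopifnot(ncol(Aeq) == nx, ncol(Aub) == nx,
            nrow(Aeq) == length(beq), nrow(Aub) == length(bub))

  m1 <- nrow(Aeq); m2 <- nrow(Aub); m <- m1 + m2

  # No constraints beyond bounds: solve separably.
  if (m == 0L) {
    x <- numeric(nx)
    for (j in seq_len(nx)) {
      if (c_obj[j] > opt_tol) {
        if (!is.finite(lb[j]))
          return(list(status = "unbounded", x = rep(NA_real_, nx),
                      objective = -Inf, infeasibility = 0))
        x[j] <- lb[j]
      } else if (c_obj[j] < -opt_tol) {
        if (!is.finite(ub[j]))
          return(list(status = "unbounded", x = rep(NA_real_, nx),
                      objective = -Inf, infeasibility = 0))
        x[j] <- ub[j]
      } else {
        x[j] <- if (is.finite(lb[j])) max(lb[j], min(0, ub[j]))
                else if (is.finite(ub[j])) min(ub[j], 0) else 0
      }
    }
    obj <- sum(c_obj * x)
    return(list(status = "optimal", x = x,
                objective = if (maximize) -obj else obj, infeasibility = 0))
  }

  # Computational form: A X = b with slacks on <= rows, then artificials.
  A <- rbind(cbind(Aeq, matrix(0, m1, m2)),
             cbind(Aub, diag(1, m2)))
  b <- c(beq, bub)
  L <- c(lb, rep(0, m2))
  U <- c(ub, rep(Inf, m2))
  cc <- c(c_obj, rep(0, m2))
  ns <- nx + m2                       # structural + slack count

  # Initial nonbasic values at a finite bound (0 for free variables).
  x <- ifelse(is.finite(L), L, ifelse(is.finite(U), U, 0))
  resid <- b - drop(A %*% x)
  art_sign <- ifelse(resid >= 0, 1, -1)
  A <- cbind(A, diag(art_sign, m))
  L <- c(L, rep(0, m))
  U <- c(U, rep(Inf, m))
  x <- c(x, abs(resid))
  ntot <- ns + m
  basis <- seq.int(ns + 1L, ntot)
  # status: 1 at lower, 2 at upper, 0 free-at-zero, 3 basic
  vstat <- ifelse(is.finite(L[seq_len(ns)]), 1L,
                  ifelse(is.finite(U[seq_len(ns)]), 2L, 0L))
  vstat <- c(vstat, rep(3L, m))

  if (is.null(max_iter)) max_iter <- 200L * (ntot + m) + 2000L
  piv_tol <- 1e-10

  run_phase <- function(cost, allow, x, basis, vstat) {
    # `allow`: logical, variables allowed to enter the basis
    for (iter in seq_len(max_iter)) {
      B <- A[, basis, drop = FALSE]
      nb <- setdiff(seq_len(ntot), basis)
      xN <- x[nb]
      xB <- tryCatch(solve(B, b - drop(A[, nb, drop = FALSE] %*% xN)),
                     error = function(e) NULL)
      if (is.null(xB)) return(NULL)
      x[basis] <- xB
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return(NULL)
      d <- cost[nb] - drop(y %*% A[, nb, drop = FALSE])
      st <- vstat[nb]
      elig_up <- (st == 1L | st == 0L) & d < -opt_tol & allow[nb]
      elig_dn <- (st == 2L | st == 0L) & d > opt_tol & allow[nb]
      cand <- nb[elig_up | elig_dn]
      if (length(cand) == 0L)
        return(list(x = x, basis = basis, vstat = vstat, optimal = TRUE))
      j <- min(cand)                              # Bland
      sigma <- if (vstat[j] == 2L || (vstat[j] == 0L &&
                   d[match(j, nb)] > opt_tol)) -1 else 1
      alpha <- tryCatch(solve(B, A[, j]), error = function(e) NULL)
      if (is.null(alpha)) return(NULL)
      # Ratio test
      step_own <- U[j] - L[j]                     # Inf when a bound is Inf
      best <- step_own; leave_row <- 0L
      w <- sigma * alpha
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (w[i] > piv_tol) {
          if (is.finite(L[bi])) {
            t_i <- (x[bi] - L[bi]) / w[i]
            if (t_i < best - 1e-12 ||
                (t_i < best + 1e-12 && (leave_row == 0L || bi < basis[leave_row]))) {
              best <- t_i; leave_row <- i
            }
          }
        } else if (w[i] < -piv_tol) {
          if (is.finite(U[bi])) {
            t_i <- (U[bi] - x[bi]) / (-w[i])
            if (t_i < best - 1e-12 ||
                (t_i < best + 1e-12 && (leave_row == 0L || bi < basis[leave_row]))) {
              best <- t_i; leave_row <- i
            }
          }
        }
      }
      if (!is.finite(best))
        return(list(x = x, basis = basis, vstat = vstat, optimal = FALSE,
                    unbounded = TRUE))
      best <- max(best, 0)
      if (leave_row == 0L) {
        # Bound flip: entering variable runs to its opposite bound.
        x[j] <- x[j] + sigma * best
        vstat[j] <- if (sigma > 0) 2L else 1L
      } else {
        bi <- basis[leave_row]
        x[j] <- x[j] + sigma * best
        x[basis] <- x[basis] - w * best
        vstat[bi] <- if (w[leave_row] > 0) {
          if (is.finite(L[bi])) 1L else 0L
        } else {
          if (is.finite(U[bi])) 2L else 0L
        }
        x[bi] <- if (vstat[bi] == 1L) L[bi] else if (vstat[bi] == 2L) U[bi] else 0
        basis[leave_row] <- j
        vstat[j] <- 3L
      }
    }
    NULL                                          # iteration limit
  }

  # Phase 1: minimise the artificial sum.
  cost1 <- c(rep(0, ns), rep(1, m))
  ph1 <- run_phase(cost1, allow = c(rep(TRUE, ns), rep(FALSE, m)),
                   x = x, basis = basis, vstat = vstat)
  if (is.null(ph1))
    return(list(status = "infeasible", x = rep(NA_real_, nx),
                objective = NA_real_, infeasibility = Inf))
  infeas <- sum(ph1$x[seq.int(ns + 1L, ntot)])
  scale_b <- max(1, abs(b))
  if (infeas > feas_tol * scale_b)
    return(list(status = "infeasible", x = ph1$x[seq_len(nx)],
                objective = NA_real_, infeasibility = infeas))

  # Phase 2: artificials pinned to zero, original objective.
  x <- ph1$x; basis <- ph1$basis; vstat <- ph1$vstat
  U[seq.int(ns + 1L, ntot)] <- 0
  x[seq.int(ns + 1L, ntot)][vstat[seq.int(ns + 1L, ntot)] != 3L] <- 0
  vstat[seq.int(ns + 1L, ntot)][vstat[seq.int(ns + 1L, ntot)] == 2L] <- 1L
  cost2 <- c(cc, rep(0, m))
  ph2 <- run_phase(cost2, allow = c(rep(TRUE, ns), rep(FALSE, m)),
                   x = x, basis = basis, vstat = vstat)
  if (is.null(ph2))
    return(list(status = "infeasible", x = rep(NA_real_, nx),
                objective = NA_real_, infeasibility = infeas))
  if (isTRUE(ph2$unbounded))
    return(list(status = "unbounded", x = ph2$x[seq_len(nx)],
                objective = if (maximize) Inf else -Inf,
                infeasibility = infeas))
  xs <- ph2$x[seq_len(nx)]
  obj <- sum(c_obj * xs)
  list(status = "optimal", x = xs,
       objective = if (maximize) -obj else obj, infeasibility = infeas)
}
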