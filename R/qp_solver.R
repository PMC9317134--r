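# Weighted-least-squares QP layer on top of quadprog::solve.QP.
#
# Solves  min sum_i w_i (x_i - t_i)^2  over the penalised index set,
# subject to  Aeq x = beq,  Aub x <= bub,  lb <= x <= ub.
#
# quadprog requires a strictly positive-definite Hessian, so variables
# without quadratic cost receive a tiny ridge; afterwards the active set
# is read off and the reduced equality-constrained problem is re-solved
# exactly (nullspace method), removing the ridge bias.  The polished
# point is kept only if it is feasible and not worse.

qp_weighted_lsq <- function(nvar, pen_idx, w, tgt,
                            Aeq = NULL, beq = NULL,
                            Aub = NULL, bub = NULL,
                            lb = rep(-Inf, nvar), ub = rep(Inf, nvar),
                            ridge_frac = 1e-8) {
  stopifnot(length(pen_idx) == length(w), length(w) == length(tgt),
            all(w > 0), all(is.finite(w)))
  Aeq <- if (is.null(Aeq)) matrix(0, 0L, nvar) else as.matrix(Aeq)
  beq <- as.numeric(if (is.null(beq)) numeric(0) else beq)
  Aub <- if (is.null(Aub)) matrix(0, 0L, nvar) else as.matrix(Aub)
  bub <- as.numeric(if (is.null(bub)) numeric(0) else bub)

  wfull <- rep(0, nvar); wfull[pen_idx] <- w
  tfull <- rep(0, nvar); tfull[pen_idx] <- tgt
  wmin <- if (length(w)) min(w) else 1

  # assemble quadprog inequality block: lb rows, ub rows, general rows
  lb_rows <- which(is.finite(lb)); ub_rows <- which(is.finite(ub))
  Alb <- if (length(lb_rows)) {
    M <- matrix(0, length(lb_rows), nvar)
    M[cbind(seq_along(lb_rows), lb_rows)] <- 1
    M
  } else matrix(0, 0L, nvar)
  Aub2 <- if (length(ub_rows)) {
    M <- matrix(0, length(ub_rows), nvar)
    M[cbind(seq_along(ub_rows), ub_rows)] <- -1
    M
  } else matrix(0, 0L, nvar)
  Amat <- rbind(Aeq, Alb, Aub2, -Aub)            # quadprog wants A'x >= b
  bvec <- c(beq, lb[lb_rows], -ub[ub_rows], -bub)
  meq <- nrow(Aeq)

  sol <- NULL
  ridge <- ridge_frac * wmin
  for (attempt in 1:4) {
    D <- diag(2 * pmax(wfull, ridge), nvar)
    d <- 2 * wfull * tfull
    sol <- tryCatch(
      quadprog::solve.QP(D, d, t(Amat), bvec, meq = meq),
      error = function(e) e)
    if (!inherits(sol, "error")) break
    # "inconsistent constraints" can be a conditioning artefact of the
    # ridge, so both error classes get retried with a stronger ridge
    ridge <- ridge * 100
  }
  if (inherits(sol, "error")) {
    msg <- conditionMessage(sol)
    status <- if (grepl("inconsistent|no solution", msg, ignore.case = TRUE))
      "infeasible" else "solver_failure"
    return(list(status = status, x = rep(NA_real_, nvar),
                objective = NA_real_, message = msg))
  }
  x <- sol$solution
  objective <- sum(wfull * (x - tfull)^2)

  # Exact polish on the detected active set
  scale_x <- max(1, abs(x), abs(tfull))
  act_tol <- 1e-6 * scale_x
  resid <- drop(Amat %*% x) - bvec
  act <- which(seq_len(nrow(Amat)) <= meq | abs(resid) <= act_tol)
  C <- Amat[act, , drop = FALSE]; dact <- bvec[act]
  xp <- tryCatch(drop(pinv(C) %*% dact), error = function(e) NULL)
  if (!is.null(xp)) {
    Z <- nullspace_basis(C)
    sw <- sqrt(wfull[pen_idx])
    G <- matrix(0, length(pen_idx), nvar)
    G[cbind(seq_along(pen_idx), pen_idx)] <- sw
    h <- sw * tgt
    y <- if (ncol(Z)) drop(pinv(G %*% Z) %*% (h - drop(G %*% xp))) else numeric(0)
    xpol <- xp + if (ncol(Z)) drop(Z %*% y) else 0
    feas_tol <- 1e-7 * scale_x
    ok <- all(drop(Amat %*% xpol) - bvec >= -feas_tol) &&
      (meq == 0L || all(abs(drop(Aeq %*% xpol) - beq) <= feas_tol))
    obj_pol <- sum(wfull * (xpol - tfull)^2)
    if (ok && obj_pol <= objective + 1e-9 * max(1, objective)) {
      x <- xpol; objective <- obj_pol
    }
  }
  list(status = "optimal", x = x, objective = objective, message = NULL)
}
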