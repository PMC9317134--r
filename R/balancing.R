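# Optimisation-based correction of infeasible scenarios: QP (squared
# corrections), LP (paired non-negative slacks), and generalized slack
# corrections of steady-state rows, bounds and general constraints.

new_correction_result <- function(method, delta, corrected, objective,
                                  unique = NA, status = "optimal",
                                  given = NULL, slacks = NULL,
                                  lp_slacks = NULL, message = NULL) {
  structure(list(method = method,
                 deltas = delta,
                 lp_slacks = lp_slacks,
                 corrected_values = corrected,
                 given_values = given %||% (corrected + delta),
                 constraint_slacks = slacks,
                 objective_value = objective,
                 unique = unique,
                 status = status,
                 message = message),
            class = "correction_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Changes applied by a correction, as corrected minus given
#'
#' @param result a `correction_result`.
#' @return Named numeric vector `corrected - given` over the fixed rates.
#' @export
correction_changes <- function(result) {
  stopifnot(inherits(result, "correction_result"))
  result$corrected_values - result$given_values
}

#' @export
print.correction_result <- function(x, ...) {
  cat("Correction result (", x$method, "), status: ", x$status, "\n",
      sep = "")
  if (!is.null(x$message)) cat("  ", x$message, "\n")
  if (x$status == "optimal") {
    cat("  objective value:", format(x$objective_value), "\n")
    ch <- correction_changes(x)
    if (length(ch) == 0L || all(abs(ch) <= 1e-12)) {
      cat("  scenario already feasible: no corrections needed\n")
    } else {
      ord <- order(abs(ch), decreasing = TRUE)
      df <- data.frame(reaction = names(ch)[ord],
                       given = unname(x$given_values[ord]),
                       corrected = unname(x$corrected_values[ord]),
                       change = unname(ch[ord]))
      print(df, row.names = FALSE)
    }
    if (!is.null(x$constraint_slacks)) {
      nz <- vapply(x$constraint_slacks,
                   function(s) any(abs(unlist(s)) > 1e-9), logical(1))
      if (any(nz))
        cat("  non-zero constraint slacks in:",
            paste(names(x$constraint_slacks)[nz], collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Correction weights for a scenario
#'
#' Resolves a [weight_spec()] into per-reaction weights `w_i`: `W1` uses
#' `1/sigma_i^2`, `W2` uses `1/|f_i|`, `W3` uses 1. Rates fixed at zero
#' get `zero_flux_weight` under W1 (where a zero variance is disallowed
#' anyway) and W2, or weight `Inf` when `pin_zero_rates` is set (the rate
#' is then excluded from correction).
#'
#' @param scenario a [flux_scenario()].
#' @param spec a [weight_spec()].
#' @return Named numeric vector of weights, `Inf` marking pinned rates.
#' @export
compute_weights <- function(scenario, spec = weight_spec("W3")) {
  stopifnot(inherits(scenario, "flux_scenario"),
            inherits(spec, "weight_spec"))
  f <- scenario$fixed
  if (length(f) == 0L) return(stats::setNames(numeric(0), character(0)))
  w <- switch(spec$scheme,
    W1 = {
      if (is.null(scenario$variances) ||
          !all(names(f) %in% names(scenario$variances)))
        stop("weighting scheme W1 requires variances for every fixed rate")
      1 / scenario$variances[names(f)]
    },
    W2 = ifelse(f == 0, NA_real_, 1 / abs(f)),
    W3 = rep(1, length(f)))
  w <- stats::setNames(as.numeric(w), names(f))
  zero <- f == 0
  if (any(zero) && spec$scheme %in% c("W1", "W2")) {
    w[zero] <- if (spec$pin_zero_rates) Inf else spec$zero_flux_weight
  } else if (any(zero) && spec$pin_zero_rates) {
    w[zero] <- Inf
  }
  if (any(!is.finite(w) & !is.infinite(w)))
    stop("could not compute finite weights")
  if (any(w <= 0)) stop("weights must be strictly positive")
  w
}

# Accept either a weight_spec or a ready-made named weight vector.
resolve_weights <- function(scenario, weights) {
  if (inherits(weights, "weight_spec"))
    return(compute_weights(scenario, weights))
  w <- stats::setNames(as.numeric(unlist(weights)), names(unlist(weights)))
  if (!all(names(scenario$fixed) %in% names(w)))
    stop("weights must cover every fixed rate")
  if (any(w <= 0)) stop("weights must be strictly positive")
  w[names(scenario$fixed)]
}

# ---- feasibility helpers -------------------------------------------------

# Feasibility of the base constraint set N r = 0, lb <= r <= ub, A r <= b.
base_feasible <- function(model, feas_tol = 1e-9) {
  n <- length(model$reaction_ids)
  r <- lp_solve(rep(0, n), Aeq = model$N, beq = rep(0, nrow(model$N)),
                Aub = model$A, bub = model$b,
                lb = model$lb, ub = model$ub, feas_tol = feas_tol)
  r$status == "optimal"
}

#' Check feasibility of a scenario by an independent LP solve
#'
#' Solves the pure feasibility LP of the steady-state, bound, general and
#' fixed-rate constraints. `feas_tol` sets the accepted phase-1 residual,
#' allowing the deliberately relaxed re-checks recommended after applying
#' floating-point corrections.
#'
#' @param model a [metabolic_model()].
#' @param scenario a [flux_scenario()].
#' @param feas_tol feasibility tolerance (relative to `max(1,|b|)`).
#' @return `list(feasible, infeasibility, fluxes)`.
#' @export
scenario_feasible <- function(model, scenario, feas_tol = 1e-9) {
  validate_scenario(scenario, model)
  n <- length(model$reaction_ids)
  Fidx <- fixed_indices(model, scenario)
  Afix <- matrix(0, length(Fidx), n)
  if (length(Fidx)) Afix[cbind(seq_along(Fidx), Fidx)] <- 1
  r <- lp_solve(rep(0, n),
                Aeq = rbind(model$N, Afix),
                beq = c(rep(0, nrow(model$N)), unname(scenario$fixed)),
                Aub = model$A, bub = model$b,
                lb = model$lb, ub = model$ub, feas_tol = feas_tol)
  list(feasible = r$status == "optimal",
       infeasibility = r$infeasibility,
       fluxes = if (r$status == "optimal")
         stats::setNames(r$x, model$reaction_ids) else NULL)
}

# ---- QP balancing --------------------------------------------------------

#' Minimal quadratic correction of fixed rates
#'
#' Finds corrections `delta` minimising `sum_i w_i delta_i^2` such that
#' the corrected rates `r_i = f_i - delta_i` admit a flux vector
#' satisfying steady state, bounds and general constraints. The
#' corrections are unique at the optimum. When bounds and general
#' constraints are slack at the optimum the result coincides with the
#' analytical [wls_correction()].
#'
#' @param model a [metabolic_model()].
#' @param scenario a [flux_scenario()].
#' @param weights a [weight_spec()] or named weight vector.
#' @param feas_tol_relax tolerance for the post-correction feasibility
#'   re-check.
#' @return A `correction_result` with method `"qp"`. Status is
#'   `"infeasible_base"` when already the constraints without fixed rates
#'   admit no flux vector (use [generalized_balance()] then).
#' @export
qp_balance <- function(model, scenario, weights = weight_spec("W3"),
                       feas_tol_relax = 1e-6) {
  validate_scenario(scenario, model)
  f <- scenario$fixed
  k <- length(f)
  if (k == 0L)
    return(new_correction_result("qp", delta = stats::setNames(numeric(0), character(0)),
                                 corrected = stats::setNames(numeric(0), character(0)),
                                 objective = 0, unique = TRUE))
  if (!base_feasible(model))
    return(new_correction_result(
      "qp", delta = stats::setNames(rep(NA_real_, k), names(f)),
      corrected = stats::setNames(rep(NA_real_, k), names(f)),
      given = f, objective = NA_real_, status = "infeasible_base",
      message = paste("the base constraint system (steady state, bounds,",
                      "general constraints) is itself infeasible;",
                      "use generalized_balance() to correct it")))
  # already feasible: zero corrections, no QP needed
  if (scenario_feasible(model, scenario)$feasible) {
    zero <- stats::setNames(rep(0, k), names(f))
    return(new_correction_result("qp", delta = zero, corrected = f,
                                 given = f, objective = 0, unique = TRUE))
  }
  w <- resolve_weights(scenario, weights)
  n <- length(model$reaction_ids)
  Fidx <- fixed_indices(model, scenario)
  pinned <- is.infinite(w)
  pen <- Fidx[!pinned]
  Aeq <- model$N; beq <- rep(0, nrow(model$N))
  if (any(pinned)) {
    Apin <- matrix(0, sum(pinned), n)
    Apin[cbind(seq_len(sum(pinned)), Fidx[pinned])] <- 1
    Aeq <- rbind(Aeq, Apin); beq <- c(beq, unname(f[pinned]))
  }
  sol <- qp_weighted_lsq(n, pen, unname(w[!pinned]), unname(f[!pinned]),
                         Aeq = Aeq, beq = beq,
                         Aub = model$A, bub = model$b,
                         lb = model$lb, ub = model$ub)
  if (sol$status != "optimal")
    return(new_correction_result(
      "qp", delta = stats::setNames(rep(NA_real_, k), names(f)),
      corrected = stats::setNames(rep(NA_real_, k), names(f)),
      given = f, objective = NA_real_, status = "solver_failure",
      message = sol$message))
  corrected <- stats::setNames(sol$x[Fidx], names(f))
  corrected[pinned] <- f[pinned]
  delta <- f - corrected
  res <- new_correction_result("qp", delta = delta, corrected = corrected,
                               given = f, objective = sol$objective,
                               unique = TRUE)
  chk <- scenario_feasible(model, apply_corrections(scenario, res),
                           feas_tol = feas_tol_relax)
  if (!chk$feasible) {
    res$status <- "solver_failure"
    res$message <- "corrected scenario failed the LP feasibility re-check"
  }
  res
}

# ---- LP balancing --------------------------------------------------------

#' Minimal weighted absolute correction of fixed rates
#'
#' Introduces paired non-negative slacks `delta_i^+`, `delta_i^-` with
#' `r_i = f_i + delta_i^+ - delta_i^-` and minimises
#' `sum_i w_i (delta_i^+ + delta_i^-)` subject to the full constraint
#' set. The optimal objective value is unique, the corrected values may
#' not be; `check_unique = TRUE` bounds each corrected rate over the
#' optimal face to decide this.
#'
#' @param model a [metabolic_model()].
#' @param scenario a [flux_scenario()].
#' @param weights a [weight_spec()] or named weight vector.
#' @param check_unique logical; probe uniqueness of the corrected values
#'   (2k extra LP solves).
#' @param feas_tol_relax tolerance for the post-correction re-check.
#' @return A `correction_result` with method `"lp"`; `lp_slacks` holds
#'   the `(plus, minus)` pair per fixed rate.
#' @export
lp_balance <- function(model, scenario, weights = weight_spec("W3"),
                       check_unique = FALSE, feas_tol_relax = 1e-6) {
  validate_scenario(scenario, model)
  f <- scenario$fixed
  k <- length(f)
  if (k == 0L)
    return(new_correction_result("lp", delta = stats::setNames(numeric(0), character(0)),
                                 corrected = stats::setNames(numeric(0), character(0)),
                                 objective = 0, unique = TRUE))
  if (!base_feasible(model))
    return(new_correction_result(
      "lp", delta = stats::setNames(rep(NA_real_, k), names(f)),
      corrected = stats::setNames(rep(NA_real_, k), names(f)),
      given = f, objective = NA_real_, status = "infeasible_base",
      message = paste("the base constraint system (steady state, bounds,",
                      "general constraints) is itself infeasible;",
                      "use generalized_balance() to correct it")))
  w <- resolve_weights(scenario, weights)
  n <- length(model$reaction_ids)
  Fidx <- fixed_indices(model, scenario)
  pinned <- is.infinite(w)
  free_k <- which(!pinned)                      # slack pair per these
  ns <- length(free_k)
  nv <- n + 2L * ns                             # r, then d+ then d- pairs
  # r_Fi + (-1) d+_i + (+1) d-_i = f_i  for corrected rates
  # r_Fi = f_i for pinned rates
  Afix <- matrix(0, k, nv)
  Afix[cbind(seq_len(k), Fidx)] <- 1
  for (jj in seq_along(free_k)) {
    Afix[free_k[jj], n + jj] <- -1
    Afix[free_k[jj], n + ns + jj] <- 1
  }
  Aeq <- rbind(cbind(model$N, matrix(0, nrow(model$N), 2L * ns)), Afix)
  beq <- c(rep(0, nrow(model$N)), unname(f))
  Aub <- if (!is.null(model$A))
    cbind(model$A, matrix(0, nrow(model$A), 2L * ns)) else NULL
  cvec <- c(rep(0, n), rep(unname(w[free_k]), 2L))
  sol <- lp_solve(cvec, Aeq = Aeq, beq = beq, Aub = Aub, bub = model$b,
                  lb = c(model$lb, rep(0, 2L * ns)),
                  ub = c(model$ub, rep(Inf, 2L * ns)))
  if (sol$status != "optimal")
    return(new_correction_result(
      "lp", delta = stats::setNames(rep(NA_real_, k), names(f)),
      corrected = stats::setNames(rep(NA_real_, k), names(f)),
      given = f, objective = NA_real_, status = "solver_failure",
      message = paste("LP solver status:", sol$status)))
  dplus <- stats::setNames(rep(0, k), names(f))
  dminus <- stats::setNames(rep(0, k), names(f))
  dplus[free_k] <- pmax(sol$x[n + seq_len(ns)], 0)
  dminus[free_k] <- pmax(sol$x[n + ns + seq_len(ns)], 0)
  corrected <- f + dplus - dminus
  res <- new_correction_result(
    "lp", delta = dminus - dplus,               # Eq.(16)-style delta
    corrected = corrected, given = f, objective = sol$objective,
    unique = NA, lp_slacks = list(plus = dplus, minus = dminus))
  if (check_unique && ns > 0L) {
    # fix the optimal objective and range each corrected rate
    Aub2 <- rbind(Aub, cvec)
    bub2 <- c(model$b, sol$objective + 1e-9 * max(1, abs(sol$objective)))
    rng <- vapply(Fidx[free_k], function(j) {
      e <- rep(0, nv); e[j] <- 1
      lo <- lp_solve(e, Aeq, beq, Aub2, bub2,
                     lb = c(model$lb, rep(0, 2L * ns)),
                     ub = c(model$ub, rep(Inf, 2L * ns)))
      hi <- lp_solve(e, Aeq, beq, Aub2, bub2,
                     lb = c(model$lb, rep(0, 2L * ns)),
                     ub = c(model$ub, rep(Inf, 2L * ns)), maximize = TRUE)
      if (lo$status == "optimal" && hi$status == "optimal")
        hi$objective - lo$objective else NA_real_
    }, numeric(1))
    res$unique <- all(!is.na(rng)) && all(rng <= 1e-7 * max(1, max(abs(f))))
  }
  chk <- scenario_feasible(model, apply_corrections(scenario, res),
                           feas_tol = feas_tol_relax)
  if (!chk$feasible) {
    res$status <- "solver_failure"
    res$message <- "corrected scenario failed the LP feasibility re-check"
  }
  res
}

# ---- generalized slack balancing ----------------------------------------

#' Generalized slack correction of constraints
#'
#' Extends balancing beyond fixed rates: any combination of the fixed
#' rates, the steady-state rows, the flux bounds and the general
#' inequality rows can be declared correctable. Equality rows get a
#' signed slack (QP engine) or a pair of non-negative slacks (LP
#' engine); each inequality row gets one non-negative slack. The
#' engine's objective (squared or absolute, weighted) is minimised over
#' all slack variables. With `targets = "steady_state"`, equal weights
#' and a purely algebraic inconsistency, the QP steady-state slacks
#' reproduce the steady-state residual of [pseudoinverse_solution()].
#'
#' @param model a [metabolic_model()].
#' @param scenario a [flux_scenario()].
#' @param targets character subset of
#'   `c("fixed_rates", "steady_state", "bounds", "general")`.
#' @param weights a [weight_spec()] or named weight vector for the
#'   fixed-rate slacks (used only when `"fixed_rates"` is targeted).
#' @param slack_weight positive scalar weight applied to the
#'   steady-state, bound and general-constraint slacks.
#' @param engine `"qp"` or `"lp"`.
#' @return A `correction_result` with `constraint_slacks` holding the
#'   per-class slack values.
#' @export
generalized_balance <- function(model, scenario,
                                targets = "steady_state",
                                weights = weight_spec("W3"),
                                slack_weight = 1,
                                engine = c("qp", "lp")) {
  engine <- match.arg(engine)
  validate_scenario(scenario, model)
  targets <- match.arg(targets,
                       c("fixed_rates", "steady_state", "bounds", "general"),
                       several.ok = TRUE)
  if (!length(targets)) stop("at least one target class must be selected")
  if ("general" %in% targets && is.null(model$A))
    targets <- setdiff(targets, "general")
  stopifnot(slack_weight > 0)
  f <- scenario$fixed
  k <- length(f)
  # a feasible scenario needs no slacks whatever the target set
  if (scenario_feasible(model, scenario)$feasible) {
    zero_slacks <- list()
    if ("steady_state" %in% targets)
      zero_slacks$steady_state <- stats::setNames(
        rep(0, nrow(model$N)), model$metabolite_ids)
    if ("bounds" %in% targets)
      zero_slacks$bounds <- list(
        lb = stats::setNames(rep(0, sum(is.finite(model$lb))),
                             model$reaction_ids[is.finite(model$lb)]),
        ub = stats::setNames(rep(0, sum(is.finite(model$ub))),
                             model$reaction_ids[is.finite(model$ub)]))
    if ("general" %in% targets)
      zero_slacks$general <- rep(0, nrow(model$A))
    return(new_correction_result(
      if (engine == "qp") "generalized-qp" else "generalized-lp",
      delta = stats::setNames(rep(0, k), names(f)), corrected = f,
      given = f, objective = 0, slacks = zero_slacks, unique = NA))
  }
  n <- length(model$reaction_ids)
  m <- nrow(model$N)
  Fidx <- fixed_indices(model, scenario)
  w_fix <- if (k) resolve_weights(scenario, weights) else numeric(0)
  fix_target <- "fixed_rates" %in% targets
  ss_target <- "steady_state" %in% targets
  bd_target <- "bounds" %in% targets
  gn_target <- "general" %in% targets

  # variable layout: r (n) | s_ss (m, signed or pair) | d_lb | d_ub | d_gen
  lb_rows <- if (bd_target) which(is.finite(model$lb)) else integer(0)
  ub_rows <- if (bd_target) which(is.finite(model$ub)) else integer(0)
  ng <- if (gn_target) nrow(model$A) else 0L
  n_ss <- if (ss_target) m else 0L
  pairs <- engine == "lp"

  idx_r <- seq_len(n)
  off <- n
  idx_ss <- if (n_ss) off + seq_len(n_ss * (1L + pairs)) else integer(0)
  off <- off + length(idx_ss)
  idx_lb <- if (length(lb_rows)) off + seq_along(lb_rows) else integer(0)
  off <- off + length(idx_lb)
  idx_ub <- if (length(ub_rows)) off + seq_along(ub_rows) else integer(0)
  off <- off + length(idx_ub)
  idx_gn <- if (ng) off + seq_len(ng) else integer(0)
  off <- off + length(idx_gn)
  # fixed-rate pair slacks for the LP engine
  free_k <- if (fix_target) which(!is.infinite(w_fix)) else integer(0)
  idx_fx <- if (pairs && length(free_k)) off + seq_len(2L * length(free_k)) else integer(0)
  nv <- off + length(idx_fx)

  zero_block <- function(nr) matrix(0, nr, nv)
  # steady state: N r - s = 0 (or N r - s+ + s- = 0)
  Ass <- zero_block(m)
  Ass[, idx_r] <- model$N
  if (ss_target) {
    if (pairs) {
      Ass[cbind(seq_len(m), idx_ss[seq_len(m)])] <- -1
      Ass[cbind(seq_len(m), idx_ss[m + seq_len(m)])] <- 1
    } else {
      Ass[cbind(seq_len(m), idx_ss)] <- -1
    }
  }
  # fixed rates
  Afix <- zero_block(k)
  if (k) Afix[cbind(seq_len(k), Fidx)] <- 1
  if (fix_target && pairs && length(free_k)) {
    nf <- length(free_k)
    Afix[cbind(free_k, idx_fx[seq_len(nf)])] <- -1
    Afix[cbind(free_k, idx_fx[nf + seq_len(nf)])] <- 1
  }
  Aeq <- rbind(Ass, if (k) Afix)
  beq <- c(rep(0, m), unname(f))
  if (fix_target && engine == "qp") {
    # drop the equality for corrected rates; penalise r_F toward f instead
    keep <- c(rep(TRUE, m), is.infinite(w_fix))
    Aeq <- Aeq[keep, , drop = FALSE]; beq <- beq[keep]
  }

  # bounds on r: slacked rows move into inequalities
  lbv <- rep(-Inf, nv); ubv <- rep(Inf, nv)
  lbv[idx_r] <- model$lb; ubv[idx_r] <- model$ub
  if (bd_target) {
    lbv[idx_r][lb_rows] <- -Inf
    ubv[idx_r][ub_rows] <- Inf
  }
  lbv[c(idx_lb, idx_ub, idx_gn, idx_fx)] <- 0
  if (ss_target && pairs) lbv[idx_ss] <- 0

  Aub <- NULL; bub <- NULL
  add_ub <- function(rows, rhs) {
    Aub <<- rbind(Aub, rows); bub <<- c(bub, rhs)
  }
  if (bd_target && length(lb_rows)) {
    M <- zero_block(length(lb_rows))
    M[cbind(seq_along(lb_rows), lb_rows)] <- -1      # -r - d_lb <= -lb
    M[cbind(seq_along(lb_rows), idx_lb)] <- -1
    add_ub(M, -model$lb[lb_rows])
  }
  if (bd_target && length(ub_rows)) {
    M <- zero_block(length(ub_rows))
    M[cbind(seq_along(ub_rows), ub_rows)] <- 1       # r - d_ub <= ub
    M[cbind(seq_along(ub_rows), idx_ub)] <- -1
    add_ub(M, model$ub[ub_rows])
  }
  if (!is.null(model$A)) {
    M <- zero_block(nrow(model$A))
    M[, idx_r] <- model$A
    if (gn_target) M[cbind(seq_len(ng), idx_gn)] <- -1
    add_ub(M, model$b)
  }

  slack_of <- function(x) {
    out <- list()
    if (ss_target) {
      s <- if (pairs) x[idx_ss[seq_len(m)]] - x[idx_ss[m + seq_len(m)]]
           else x[idx_ss]
      out$steady_state <- stats::setNames(s, model$metabolite_ids)
    }
    if (bd_target)
      out$bounds <- list(
        lb = stats::setNames(pmax(x[idx_lb], 0),
                             model$reaction_ids[lb_rows]),
        ub = stats::setNames(pmax(x[idx_ub], 0),
                             model$reaction_ids[ub_rows]))
    if (gn_target)
      out$general <- pmax(x[idx_gn], 0)
    out
  }

  if (engine == "qp") {
    pen <- c(if (fix_target) Fidx[free_k],
             idx_ss, idx_lb, idx_ub, idx_gn)
    wpen <- c(if (fix_target) unname(w_fix[free_k]),
              rep(slack_weight, length(idx_ss) + length(idx_lb) +
                    length(idx_ub) + length(idx_gn)))
    tgt <- c(if (fix_target) unname(f[free_k]),
             rep(0, length(pen) - (if (fix_target) length(free_k) else 0L)))
    if (!length(pen)) stop("nothing to correct: no slack variables")
    sol <- qp_weighted_lsq(nv, pen, wpen, tgt, Aeq = Aeq, beq = beq,
                           Aub = Aub, bub = bub, lb = lbv, ub = ubv)
    if (sol$status != "optimal")
      stop("generalized balancing failed even with slacks (",
           sol$status, "): the model is malformed for the selected ",
           "targets {", paste(targets, collapse = ", "), "}",
           if (!is.null(sol$message)) paste0("; solver: ", sol$message))
    x <- sol$x; objective <- sol$objective
    method <- "generalized-qp"
  } else {
    cvec <- rep(0, nv)
    cvec[c(idx_ss, idx_lb, idx_ub, idx_gn)] <- slack_weight
    if (length(idx_fx)) {
      nf <- length(free_k)
      cvec[idx_fx] <- rep(unname(w_fix[free_k]), 2L)
    }
    sol <- lp_solve(cvec, Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                    lb = lbv, ub = ubv)
    if (sol$status != "optimal")
      stop("generalized balancing failed even with slacks (",
           sol$status, "): the model is malformed for the selected ",
           "targets {", paste(targets, collapse = ", "), "}")
    x <- sol$x; objective <- sol$objective
    method <- "generalized-lp"
  }
  corrected <- if (k) stats::setNames(x[Fidx], names(f)) else f
  if (k && !fix_target) corrected <- f
  delta <- if (k) f - corrected else f
  new_correction_result(method, delta = delta, corrected = corrected,
                        given = f, objective = objective,
                        slacks = slack_of(x), unique = NA)
}

#' Apply a correction to a scenario
#'
#' @param scenario a [flux_scenario()].
#' @param result an optimal `correction_result`.
#' @return A new [flux_scenario()] with the corrected fixed values; the
#'   input scenario is unchanged.
#' @export
apply_corrections <- function(scenario, result) {
  stopifnot(inherits(scenario, "flux_scenario"),
            inherits(result, "correction_result"))
  if (result$status != "optimal")
    stop("cannot apply corrections: result status is ", result$status)
  fixed <- scenario$fixed
  fixed[names(result$corrected_values)] <- result$corrected_values
  flux_scenario(fixed, scenario$variances)
}
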