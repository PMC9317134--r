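# Classical metabolic flux analysis: partitioning into known/unknown
# rates, rank diagnostics, the redundancy matrix, pseudoinverse solutions
# and the analytical weighted least-squares correction.

#' Partition a model by known and unknown rates
#'
#' Splits the steady-state system `N r = 0` into `NU rU = -NF rF = z`,
#' where F indexes the reactions fixed by the scenario and U the
#' remaining (unknown) ones.
#'
#' @param model a [metabolic_model()].
#' @param scenario a [flux_scenario()].
#' @return An object of class `mfa_partition` with elements `U`, `F`
#'   (column indices into `model$N`), `ids_U`, `ids_F`, `NU`, `NF`,
#'   `rF`, `z`, and the originating `model`/`scenario`.
#' @export
partition <- function(model, scenario) {
  validate_scenario(scenario, model)
  Fidx <- fixed_indices(model, scenario)
  Uidx <- setdiff(seq_along(model$reaction_ids), Fidx)
  NF <- model$N[, Fidx, drop = FALSE]
  NU <- model$N[, Uidx, drop = FALSE]
  rF <- unname(scenario$fixed)
  z <- -drop(NF %*% rF)
  if (length(z) == 0L) z <- numeric(nrow(model$N))
  structure(list(U = Uidx, F = Fidx,
                 ids_U = model$reaction_ids[Uidx],
                 ids_F = model$reaction_ids[Fidx],
                 NU = NU, NF = NF, rF = rF, z = z,
                 model = model, scenario = scenario),
            class = "mfa_partition")
}

#' Redundancy matrix of a partitioned scenario
#'
#' Computes `R = NF - NU NU^+ NF` (`^+` the Moore-Penrose pseudoinverse).
#' `R rF = 0` is the steady-state consistency condition; fixed reactions
#' with a non-zero column in `R` are the redundant rates. In a
#' non-redundant system `R = 0`.
#'
#' @param part an `mfa_partition`.
#' @param rank_tol optional numerical rank tolerance.
#' @return An m x k numeric matrix (k = number of fixed rates).
#' @export
redundancy_matrix <- function(part, rank_tol = NULL) {
  stopifnot(inherits(part, "mfa_partition"))
  if (ncol(part$NF) == 0L) return(part$NF)
  if (ncol(part$NU) == 0L) return(part$NF)
  R <- part$NF - part$NU %*% (pinv(part$NU, rank_tol) %*% part$NF)
  dimnames(R) <- list(part$model$metabolite_ids, part$ids_F)
  R
}

#' Minimal-norm least-squares rates for the unknown reactions
#'
#' Solves `NU rU = z` in the least-squares sense via the Moore-Penrose
#' pseudoinverse, `rU = NU^+ z`. Among all least-squares solutions the
#' returned vector has minimal Euclidean norm; only the entries flagged
#' in `determined_unknowns` of [diagnose()] are unique. In an
#' inconsistent scenario the result minimises the steady-state violation
#' rather than satisfying it.
#'
#' @param part an `mfa_partition`.
#' @param rank_tol optional numerical rank tolerance.
#' @return Named numeric vector of unknown-reaction rates (possibly
#'   length zero when every reaction is fixed).
#' @export
pseudoinverse_solution <- function(part, rank_tol = NULL) {
  stopifnot(inherits(part, "mfa_partition"))
  if (ncol(part$NU) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  rU <- drop(pinv(part$NU, rank_tol) %*% part$z)
  stats::setNames(rU, part$ids_U)
}

#' Diagnose determinacy, redundancy and consistency of a flux scenario
#'
#' Classifies a scenario by the rank arithmetic of the steady-state
#' system: degrees of freedom `dof = x - rank(NU)` (determined when 0),
#' degrees of redundancy `degR = rank(N) - rank(NU)` (redundant when
#' > 0, a count unaffected by conservation relations), and steady-state
#' consistency `R rF = 0` checked in the max norm. Unknown rates whose
#' row in a nullspace basis of `NU` vanishes are uniquely determined.
#'
#' @param model a [metabolic_model()].
#' @param scenario a [flux_scenario()].
#' @param rank_tol optional numerical rank tolerance (default:
#'   `max(dim) * eps * max singular value`).
#' @param consistency_tol absolute tolerance on `max|R rF|`, scaled by
#'   `max(1, max|f|)`.
#' @return An object of class `scenario_diagnosis`.
#' @export
diagnose <- function(model, scenario, rank_tol = NULL,
                     consistency_tol = 1e-9) {
  part <- partition(model, scenario)
  m <- nrow(model$N)
  x <- length(part$U); k <- length(part$F)
  rank_N <- mat_rank(model$N, rank_tol)
  rank_NU <- mat_rank(part$NU, rank_tol)
  cons <- m - rank_N
  dof <- x - rank_NU
  degR <- rank_N - rank_NU
  R <- redundancy_matrix(part, rank_tol)
  residual <- if (k) drop(R %*% part$rF) else numeric(m)
  # redundant rates: non-zero columns of R, thresholded relative to the
  # magnitude of the corresponding NF column (floating-point zeros).
  col_tol <- 1e-9
  red_cols <- if (k) {
    vapply(seq_len(k), function(j) {
      max(abs(R[, j])) > col_tol * max(1, max(abs(part$NF[, j])))
    }, logical(1))
  } else logical(0)
  # reduced redundancy matrix: degR independent rows of R
  if (degR > 0L) {
    rows <- independent_rows(R, rank_tol)
    rows <- rows[seq_len(min(degR, length(rows)))]
    Rr <- R[rows, , drop = FALSE]
  } else {
    rows <- integer(0)
    Rr <- R[integer(0), , drop = FALSE]
  }
  # determined unknowns: all-zero rows of a nullspace basis of NU
  KU <- nullspace_basis(part$NU, rank_tol)
  det_unknown <- if (x) {
    if (ncol(KU) == 0L) rep(TRUE, x)
    else apply(abs(KU), 1L, max) <= 1e-9
  } else logical(0)
  scale_f <- max(1, if (k) max(abs(part$rF)) else 0)
  consistent <- degR == 0L ||
    max(abs(residual)) <= consistency_tol * scale_f
  structure(list(
    rank_N = rank_N, rank_NU = rank_NU, c = cons,
    dof = dof, degR = degR,
    determinacy = if (dof == 0L) "determined" else "underdetermined",
    redundancy = if (degR > 0L) "redundant" else "non-redundant",
    consistency = if (consistent) "consistent" else "inconsistent",
    redundancy_matrix = R,
    reduced_redundancy_matrix = Rr,
    reduced_rows = rows,
    redundant_rate_ids = part$ids_F[red_cols],
    residual = residual,
    determined_unknowns = part$ids_U[det_unknown],
    partition = part),
    class = "scenario_diagnosis")
}

#' @export
print.scenario_diagnosis <- function(x, ...) {
  cat("Scenario diagnosis\n")
  cat("  classification:", x$determinacy, "/", x$redundancy, "/",
      x$consistency, "\n")
  cat("  rank(N) =", x$rank_N, " rank(NU) =", x$rank_NU,
      " conservation relations =", x$c, "\n")
  cat("  degrees of freedom =", x$dof, " degrees of redundancy =",
      x$degR, "\n")
  if (length(x$redundant_rate_ids))
    cat("  redundant rates:", paste(x$redundant_rate_ids, collapse = ", "),
        "\n")
  if (x$degR > 0L)
    cat("  max |R rF| =", format(max(abs(x$residual))), "\n")
  if (length(x$determined_unknowns))
    cat("  uniquely determined unknowns:",
        paste(x$determined_unknowns, collapse = ", "), "\n")
  invisible(x)
}

#' Analytical weighted least-squares correction of fixed rates
#'
#' Computes the closed-form correction
#' `delta = W Rr' (Rr W Rr')^-1 Rr rF`, where `Rr` is the reduced
#' redundancy matrix and `W` is diagonal with the reciprocals `1/w_i` of
#' the correction weights. Corrected rates `f - delta` satisfy
#' `Rr (f - delta) = 0`; non-redundant fixed rates receive no
#' correction. This is the purely algebraic counterpart of
#' [qp_balance()]: bounds and general constraints are ignored.
#'
#' @param part an `mfa_partition`.
#' @param diagnosis the matching `scenario_diagnosis`.
#' @param weights a [weight_spec()] (or a named numeric vector of
#'   per-reaction weights `w_i`).
#' @return A `correction_result` with method `"wls"`.
#' @export
wls_correction <- function(part, diagnosis, weights = weight_spec("W3")) {
  stopifnot(inherits(part, "mfa_partition"),
            inherits(diagnosis, "scenario_diagnosis"))
  k <- length(part$F)
  f <- stats::setNames(part$rF, part$ids_F)
  if (diagnosis$degR == 0L || k == 0L) {
    delta <- stats::setNames(rep(0, k), part$ids_F)
    return(new_correction_result("wls", delta = delta,
                                 corrected = f - delta,
                                 objective = 0, unique = TRUE))
  }
  w <- resolve_weights(part$scenario, weights)
  Rr <- diagnosis$reduced_redundancy_matrix
  Winv <- ifelse(is.finite(w), 1 / w, 0)      # pinned rates: zero variance
  M <- Rr %*% (Winv * t(Rr))
  if (rcond(M) < 1e-12)
    stop("Rr W Rr' is numerically singular; offending redundancy row(s): ",
         paste(diagnosis$reduced_rows, collapse = ", "),
         " (weights may be degenerate for the pinned/zero rates involved)")
  delta <- drop(Winv * t(Rr) %*% solve(M, drop(Rr %*% part$rF)))
  delta <- stats::setNames(delta, part$ids_F)
  objective <- sum(ifelse(is.finite(w), w, 0) * delta^2)
  new_correction_result("wls", delta = delta, corrected = f - delta,
                        objective = objective, unique = TRUE)
}
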