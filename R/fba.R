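# FBA optimisation and flux variability analysis on (corrected) scenarios.

.scenario_lp_parts <- function(model, scenario) {
  n <- length(model$reaction_ids)
  Aeq <- model$N; beq <- rep(0, nrow(model$N))
  if (!is.null(scenario) && length(scenario$fixed)) {
    Fidx <- fixed_indices(model, scenario)
    Afix <- matrix(0, length(Fidx), n)
    Afix[cbind(seq_along(Fidx), Fidx)] <- 1
    Aeq <- rbind(Aeq, Afix); beq <- c(beq, unname(scenario$fixed))
  }
  list(Aeq = Aeq, beq = beq, Aub = model$A, bub = model$b,
       lb = model$lb, ub = model$ub)
}

#' Flux balance analysis
#'
#' Optimises a linear objective over the flux polyhedron defined by
#' steady state, bounds, general constraints and any fixed rates of the
#' scenario.
#'
#' @param model a [metabolic_model()] (its `objective_c` is used unless
#'   `objective` is supplied).
#' @param scenario optional [flux_scenario()].
#' @param objective optional numeric objective coefficients (length n)
#'   or a named vector over reaction ids.
#' @param sense `"max"` or `"min"`.
#' @param feas_tol LP feasibility tolerance.
#' @return An object of class `fba_result` with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value` and the optimal
#'   flux vector `fluxes`.
#' @export
fba <- function(model, scenario = NULL, objective = NULL,
                sense = c("max", "min"), feas_tol = 1e-9) {
  sense <- match.arg(sense)
  if (!is.null(scenario)) validate_scenario(scenario, model)
  n <- length(model$reaction_ids)
  cvec <- objective %||% model$objective_c
  if (is.null(cvec))
    stop("no objective: the model carries none and none was supplied")
  if (!is.null(names(cvec)) && length(cvec) != n) {
    cc <- rep(0, n)
    bad <- setdiff(names(cvec), model$reaction_ids)
    if (length(bad)) stop("objective names unknown reaction(s): ",
                          paste(bad, collapse = ", "))
    cc[match(names(cvec), model$reaction_ids)] <- as.numeric(cvec)
    cvec <- cc
  }
  stopifnot(length(cvec) == n)
  p <- .scenario_lp_parts(model, scenario)
  r <- lp_solve(as.numeric(cvec), p$Aeq, p$beq, p$Aub, p$bub, p$lb, p$ub,
                maximize = sense == "max", feas_tol = feas_tol)
  structure(list(status = r$status,
                 objective_value = r$objective,
                 fluxes = if (r$status == "optimal")
                   stats::setNames(r$x, model$reaction_ids) else NULL,
                 sense = sense),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("FBA result:", x$status, "\n")
  if (x$status == "optimal")
    cat("  objective (", x$sense, "): ", format(x$objective_value), "\n",
        sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' Minimises and maximises each reaction flux over the feasible
#' polyhedron of the (corrected) scenario. A reaction whose range
#' collapses below `det_tol` is flagged as uniquely determined; because
#' FVA sees the bounds and general constraints, it can determine rates
#' that pure kernel analysis of the steady-state system cannot.
#'
#' @param model a [metabolic_model()].
#' @param scenario optional [flux_scenario()]; must be feasible
#'   (balance first if not).
#' @param reactions optional character subset of reaction ids.
#' @param det_tol determinacy tolerance, scaled by `max(1, |value|)`.
#' @param fix_objective_fraction optional gamma in (0, 1]; adds
#'   `c'r >= gamma * optimum` using the model objective before ranging.
#' @param feas_tol LP feasibility tolerance (relax after applying
#'   floating-point corrections).
#' @return An object of class `fva_result`.
#' @export
fva <- function(model, scenario = NULL, reactions = NULL,
                det_tol = 1e-7, fix_objective_fraction = NULL,
                feas_tol = 1e-9) {
  if (!is.null(scenario)) validate_scenario(scenario, model)
  if (is.null(reactions)) reactions <- model$reaction_ids
  bad <- setdiff(reactions, model$reaction_ids)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  p <- .scenario_lp_parts(model, scenario)
  if (!is.null(fix_objective_fraction)) {
    if (is.null(model$objective_c)) stop("fix_objective_fraction needs a model objective")
    opt <- fba(model, scenario, feas_tol = feas_tol)
    if (opt$status != "optimal")
      stop("cannot fix objective: FBA status ", opt$status)
    p$Aub <- rbind(p$Aub, -model$objective_c)
    p$bub <- c(p$bub, -fix_objective_fraction * opt$objective_value)
  }
  feas <- lp_solve(rep(0, length(model$lb)), p$Aeq, p$beq, p$Aub, p$bub,
                   p$lb, p$ub, feas_tol = feas_tol)
  if (feas$status != "optimal")
    stop("scenario is infeasible (phase-1 residual ",
         format(feas$infeasibility),
         "): balance it first, e.g. with qp_balance() or lp_balance()")
  idx <- match(reactions, model$reaction_ids)
  lo <- numeric(length(idx)); hi <- numeric(length(idx))
  for (jj in seq_along(idx)) {
    e <- rep(0, length(model$lb)); e[idx[jj]] <- 1
    rmin <- lp_solve(e, p$Aeq, p$beq, p$Aub, p$bub, p$lb, p$ub,
                     feas_tol = feas_tol)
    rmax <- lp_solve(e, p$Aeq, p$beq, p$Aub, p$bub, p$lb, p$ub,
                     maximize = TRUE, feas_tol = feas_tol)
    lo[jj] <- if (rmin$status == "unbounded") -Inf else rmin$objective
    hi[jj] <- if (rmax$status == "unbounded") Inf else rmax$objective
  }
  # guard against LP roundoff inverting degenerate ranges
  swap <- is.finite(lo) & is.finite(hi) & lo > hi
  if (any(swap)) { tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp }
  det <- is.finite(lo) & is.finite(hi) &
    (hi - lo) <= det_tol * pmax(1, pmax(abs(lo), abs(hi)))
  structure(list(reaction_ids = reactions,
                 min_flux = stats::setNames(lo, reactions),
                 max_flux = stats::setNames(hi, reactions),
                 determined = stats::setNames(det, reactions),
                 det_tol = det_tol),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat("FVA over", length(x$reaction_ids), "reaction(s);",
      sum(x$determined), "determined\n")
  df <- data.frame(reaction = x$reaction_ids,
                   min = unname(x$min_flux), max = unname(x$max_flux),
                   determined = unname(x$determined))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Reactions with a degenerate FVA range
#'
#' @param fva_result an `fva_result`.
#' @return Character vector of reaction ids whose flux is uniquely
#'   determined (`max - min <= det_tol`).
#' @export
determined_rates <- function(fva_result) {
  stopifnot(inherits(fva_result, "fva_result"))
  fva_result$reaction_ids[fva_result$determined]
}
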