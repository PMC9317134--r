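# Bundled example networks and a seeded synthetic-scenario generator.

#' Ten-reaction example network
#'
#' A canonical reconstruction of a small metabolic network with six
#' internal metabolites (A-F) and ten reactions: two inflow exchanges
#' (R1 to A, reversible R2 to B), two outflow exchanges (R3 from E, R4
#' from F), and internal conversions R5: A->C, R6: A->E, R7: A->D,
#' R8: C->E (reversible), R9: B->E, R10: D->F. Only R2 and R8 are
#' reversible. The stoichiometric matrix has full rank 6, the exchange
#' rates satisfy `r1 + r2 = r3 + r4` at steady state, R7 and R10 are
#' strictly coupled to R4 through metabolites D and F, and with the
#' irreversibilities in force the rate of R4 can never exceed the flux
#' through R1.
#'
#' The exact wiring of the internal part is a reconstruction chosen to
#' satisfy those structural facts; it is the smallest network on which
#' all four determinacy/redundancy scenario classes can be produced by
#' fixing different rate subsets.
#'
#' @return A [metabolic_model()] with 6 metabolites and 10 reactions.
#' @examples
#' mod <- example_network()
#' diagnose(mod, flux_scenario(c(R1 = 5, R4 = 5)))
#' @export
example_network <- function() {
  mets <- c("A", "B", "C", "D", "E", "F")
  rxns <- paste0("R", 1:10)
  N <- matrix(0, 6, 10, dimnames = list(mets, rxns))
  N["A", "R1"] <- 1
  N["B", "R2"] <- 1
  N["E", "R3"] <- -1
  N["F", "R4"] <- -1
  N["A", "R5"] <- -1; N["C", "R5"] <- 1
  N["A", "R6"] <- -1; N["E", "R6"] <- 1
  N["A", "R7"] <- -1; N["D", "R7"] <- 1
  N["C", "R8"] <- -1; N["E", "R8"] <- 1
  N["B", "R9"] <- -1; N["E", "R9"] <- 1
  N["D", "R10"] <- -1; N["F", "R10"] <- 1
  lb <- rep(0, 10)
  lb[rxns %in% c("R2", "R8")] <- -Inf
  metabolic_model(N, rxns, mets, lb = lb, ub = rep(Inf, 10))
}

#' Minimal strictly coupled reaction pair
#'
#' The smallest network in which two reactions are forced to carry the
#' same rate: R4 produces metabolite D and R10 consumes it, both
#' irreversible. Fixing the two rates at different values gives the
#' canonical one-degree-of-redundancy inconsistent scenario.
#'
#' @return A [metabolic_model()] with `N = [[1, -1]]`.
#' @examples
#' mod <- coupled_pair()
#' qp_balance(mod, flux_scenario(c(R4 = 2, R10 = 4)), weight_spec("W2"))
#' @export
coupled_pair <- function() {
  N <- matrix(c(1, -1), 1, 2, dimnames = list("D", c("R4", "R10")))
  metabolic_model(N, c("R4", "R10"), "D", lb = c(0, 0), ub = c(Inf, Inf))
}

#' Single-branch network
#'
#' One influx R1 into metabolite A, two irreversible effluxes R2 and R3.
#' Fixing R1 leaves one degree of freedom split between the branches:
#' useful for illustrating FVA ranges and how bound constraints (e.g.
#' `ub(R2) = 0`) can determine rates that kernel analysis cannot.
#'
#' @return A [metabolic_model()] with 1 metabolite and 3 reactions.
#' @export
branch_network <- function() {
  N <- matrix(c(1, -1, -1), 1, 3,
              dimnames = list("A", c("R1", "R2", "R3")))
  metabolic_model(N, c("R1", "R2", "R3"), "A",
                  lb = c(0, 0, 0), ub = rep(Inf, 3))
}

#' Seeded synthetic flux scenario
#'
#' Generates a random sparse stoichiometric network, a ground-truth flux
#' vector `r_star` inside its flux polytope, and a scenario fixing a
#' random subset of the true rates with additive Gaussian noise.
#' `r_star` is built by averaging the optima of a few random-objective
#' LPs (interior averaging), so it satisfies steady state and all bounds;
#' with `sigma = 0` the generated scenario is therefore consistent.
#'
#' @param seed integer seed; the result is reproducible per seed.
#' @param m,n metabolite and reaction counts (`n > m >= 1`).
#' @param k number of fixed rates (`k <= n`).
#' @param sigma measurement noise standard deviation (flux units);
#'   recorded as variance `sigma^2` on the scenario when positive.
#' @param reversible_fraction fraction of reactions with `lb = -flux_cap`.
#' @param flux_cap magnitude of the finite flux bounds.
#' @param require_redundant if `TRUE`, resample (growing the fixed set if
#'   needed) until the scenario has `degR >= 1`.
#' @param max_tries internal resampling budget.
#' @return An object of class `synthetic_scenario`: a list with `model`,
#'   `r_star`, `scenario`, `sigma`, `seed` and the `diagnosis` of the
#'   generated scenario.
#' @export
random_scenario <- function(seed, m = 4, n = 10, k = 5, sigma = 0.1,
                            reversible_fraction = 0.3, flux_cap = 10,
                            require_redundant = FALSE, max_tries = 200L) {
  stopifnot(n > m, m >= 1, k <= n, sigma >= 0)
  set.seed(as.integer(seed))
  for (try in seq_len(max_tries)) {
    N <- matrix(0, m, n)
    for (j in seq_len(n)) {
      nz <- sample(seq_len(m), size = min(m, sample(1:3, 1)))
      N[nz, j] <- sample(c(-2, -1, 1, 2), length(nz), replace = TRUE)
    }
    # every metabolite needs a producer and a consumer for a live polytope;
    # patch missing ones instead of rejecting the draw
    for (i in seq_len(m)) {
      if (all(N[i, ] <= 0)) N[i, sample(which(N[i, ] == 0), 1)] <- 1
      if (all(N[i, ] >= 0)) N[i, sample(which(N[i, ] == 0), 1)] <- -1
    }
    rev <- stats::runif(n) < reversible_fraction
    lb <- ifelse(rev, -flux_cap, 0)
    ub <- rep(flux_cap, n)
    model <- metabolic_model(N, paste0("R", seq_len(n)),
                             paste0("M", seq_len(m)), lb, ub)
    # interior-averaged ground truth
    pts <- list()
    for (t in 1:4) {
      r <- lp_solve(stats::rnorm(n), Aeq = N, beq = rep(0, m),
                    lb = lb, ub = ub)
      if (r$status == "optimal") pts[[length(pts) + 1L]] <- r$x
    }
    if (length(pts) < 2L) next
    r_star <- Reduce(`+`, pts) / length(pts)
    if (max(abs(r_star)) < 0.1) next            # essentially blocked network
    k_use <- k
    found <- FALSE
    for (grow in 0:(n - k)) {
      k_use <- k + grow
      Fids <- sample(model$reaction_ids, k_use)
      f <- stats::setNames(r_star[match(Fids, model$reaction_ids)], Fids)
      noise <- stats::rnorm(k_use, 0, sigma)
      sc <- flux_scenario(
        f + noise,
        variances = if (sigma > 0)
          stats::setNames(rep(sigma^2, k_use), Fids) else NULL,
        model = model)
      dg <- diagnose(model, sc)
      if (!require_redundant || dg$degR >= 1L) { found <- TRUE; break }
    }
    if (!found) next
    return(structure(list(model = model, r_star = stats::setNames(
      r_star, model$reaction_ids),
      scenario = sc, diagnosis = dg, sigma = sigma, seed = seed,
      noise = stats::setNames(noise, Fids)),
      class = "synthetic_scenario"))
  }
  stop("could not generate a suitable scenario in ", max_tries, " tries")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic scenario (seed ", x$seed, "): ",
      length(x$model$metabolite_ids), " metabolites x ",
      length(x$model$reaction_ids), " reactions, ",
      length(x$scenario$fixed), " fixed rate(s), sigma = ", x$sigma,
      "\n", sep = "")
  cat("  diagnosis:", x$diagnosis$determinacy, "/", x$diagnosis$redundancy,
      "/", x$diagnosis$consistency, "\n")
  invisible(x)
}
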