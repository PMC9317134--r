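#' Construct a metabolic model
#'
#' A metabolic model holds the stoichiometric matrix `N` (m metabolites x
#' n reactions), per-reaction flux bounds, optional general linear
#' inequality constraints `A r <= b`, and an optional linear objective.
#' Steady state requires `N r = 0`; together with `lb <= r <= ub` and
#' `A r <= b` the feasible flux vectors form a polyhedron.
#'
#' @param N numeric matrix (m x n) of stoichiometric coefficients; rows are
#'   metabolites, columns reactions. Dimnames, when present, seed the
#'   identifier vectors.
#' @param reaction_ids character vector of n unique reaction identifiers.
#' @param metabolite_ids character vector of m unique metabolite identifiers.
#' @param lb,ub numeric flux bounds per reaction; `-Inf`/`Inf` allowed.
#'   Default is an unbounded reversible reaction.
#' @param A,b optional general constraint matrix (p x n) and right-hand
#'   side (length p), encoding `A r <= b`.
#' @param objective_c optional numeric objective coefficients (length n).
#' @return An object of class `metabolic_model`.
#' @examples
#' m <- metabolic_model(matrix(c(1, -1), 1), c("R4", "R10"), "D",
#'                      lb = c(0, 0))
#' m
#' @export
metabolic_model <- function(N, reaction_ids = colnames(N),
                            metabolite_ids = rownames(N),
                            lb = NULL, ub = NULL,
                            A = NULL, b = NULL, objective_c = NULL) {
  N <- as.matrix(N)
  storage.mode(N) <- "double"
  m <- nrow(N); n <- ncol(N)
  if (n == 0L) stop("empty model: no reactions")
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(n))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(m))
  reaction_ids <- as.character(reaction_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (length(reaction_ids) != n)
    stop("dimension mismatch: ", length(reaction_ids),
         " reaction ids for ", n, " columns of N")
  if (length(metabolite_ids) != m)
    stop("dimension mismatch: ", length(metabolite_ids),
         " metabolite ids for ", m, " rows of N")
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction identifiers: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "))
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite identifiers: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != n || length(ub) != n)
    stop("dimension mismatch: bounds must have one entry per reaction")
  if (any(is.na(lb)) || any(is.na(ub))) stop("NA in flux bounds")
  bad <- which(lb > ub)
  if (length(bad))
    stop("lb > ub for reaction(s): ", paste(reaction_ids[bad], collapse = ", "))
  if (!is.null(A)) {
    A <- as.matrix(A); storage.mode(A) <- "double"
    b <- as.numeric(b)
    if (ncol(A) != n) stop("dimension mismatch: A must have n columns")
    if (nrow(A) != length(b)) stop("dimension mismatch: length(b) != nrow(A)")
  } else if (!is.null(b) && length(b)) {
    stop("b given without A")
  } else {
    A <- NULL; b <- NULL
  }
  if (!is.null(objective_c)) {
    objective_c <- as.numeric(objective_c)
    if (length(objective_c) != n)
      stop("dimension mismatch: objective_c must have length n")
  }
  dimnames(N) <- list(metabolite_ids, reaction_ids)
  structure(list(reaction_ids = reaction_ids,
                 metabolite_ids = metabolite_ids,
                 N = N, lb = lb, ub = ub, A = A, b = b,
                 objective_c = objective_c),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", length(x$metabolite_ids), "metabolites x",
      length(x$reaction_ids), "reactions\n")
  nrev <- sum(x$lb < 0)
  cat("  reversible (lb < 0):", nrev, " irreversible:",
      length(x$reaction_ids) - nrev, "\n")
  if (!is.null(x$A)) cat("  general constraints:", nrow(x$A), "\n")
  if (!is.null(x$objective_c) && any(x$objective_c != 0))
    cat("  objective on:",
        paste(x$reaction_ids[x$objective_c != 0], collapse = ", "), "\n")
  invisible(x)
}

#' Construct a flux scenario
#'
#' A flux scenario fixes a subset F of reaction rates to known (typically
#' measured) values `f_i`, optionally with measurement variances
#' `sigma_i^2` used by the W1 weighting scheme.
#'
#' @param fixed named numeric vector: reaction id -> fixed rate value.
#'   May be empty.
#' @param variances optional named numeric vector of positive measurement
#'   variances; names must be a subset of `names(fixed)`.
#' @param model optional `metabolic_model`; when given, every fixed id is
#'   checked against the model and conflicts with `lb = ub` clamps are
#'   rejected.
#' @return An object of class `flux_scenario`.
#' @export
flux_scenario <- function(fixed = numeric(0), variances = NULL, model = NULL) {
  fixed <- unlist(fixed)
  if (length(fixed) && is.null(names(fixed)))
    stop("fixed rates must be named by reaction id")
  fixed <- stats::setNames(as.numeric(fixed), names(fixed))
  if (anyDuplicated(names(fixed)))
    stop("duplicate fixed reaction id")
  if (!is.null(variances)) {
    variances <- stats::setNames(as.numeric(unlist(variances)),
                                 names(unlist(variances)))
    unknown <- setdiff(names(variances), names(fixed))
    if (length(unknown))
      stop("variance given for non-fixed reaction(s): ",
           paste(unknown, collapse = ", "))
    if (any(variances <= 0))
      stop("non-positive variance for: ",
           paste(names(variances)[variances <= 0], collapse = ", "))
  }
  sc <- structure(list(fixed = fixed, variances = variances),
                  class = "flux_scenario")
  if (!is.null(model)) validate_scenario(sc, model)
  sc
}

# Check a scenario against a model; returns the scenario invisibly.
validate_scenario <- function(scenario, model) {
  stopifnot(inherits(scenario, "flux_scenario"),
            inherits(model, "metabolic_model"))
  unknown <- setdiff(names(scenario$fixed), model$reaction_ids)
  if (length(unknown))
    stop("unknown reaction id(s) in scenario: ",
         paste(unknown, collapse = ", "))
  if (length(scenario$fixed) > length(model$reaction_ids))
    stop("more fixed rates than reactions")
  clamped <- model$reaction_ids[model$lb == model$ub]
  for (id in intersect(clamped, names(scenario$fixed))) {
    v <- model$lb[match(id, model$reaction_ids)]
    if (abs(v - scenario$fixed[[id]]) > 1e-12 * max(1, abs(v)))
      stop("conflict for ", id, ": model clamps lb = ub = ", v,
           " but scenario fixes ", scenario$fixed[[id]])
  }
  invisible(scenario)
}

#' @export
print.flux_scenario <- function(x, ...) {
  k <- length(x$fixed)
  cat("Flux scenario:", k, "fixed rate(s)\n")
  if (k) {
    df <- data.frame(reaction = names(x$fixed), value = unname(x$fixed))
    if (!is.null(x$variances))
      df$variance <- unname(x$variances[df$reaction])
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Specify correction weights
#'
#' Chooses how corrections to fixed rates are penalised: `W1` uses
#' reciprocal measurement variances (`w_i = 1/sigma_i^2`), `W2` uses
#' reciprocal magnitudes (`w_i = 1/|f_i|`), and `W3` uses unit weights.
#' Rates fixed at zero get the large penalty `zero_flux_weight` under
#' W1/W2, or are excluded from correction entirely when `pin_zero_rates`
#' is set.
#'
#' @param scheme `"W1"`, `"W2"` or `"W3"` (case-insensitive).
#' @param zero_flux_weight positive weight (>= 1000) used for rates fixed
#'   at zero under W1/W2.
#' @param pin_zero_rates logical; if `TRUE`, rates fixed at 0 receive no
#'   correction variable at all.
#' @return An object of class `weight_spec`.
#' @export
weight_spec <- function(scheme = c("W3", "W1", "W2"),
                        zero_flux_weight = 1e6, pin_zero_rates = FALSE) {
  scheme <- toupper(scheme[1])
  if (!scheme %in% c("W1", "W2", "W3"))
    stop("unknown weighting scheme: ", scheme)
  zero_flux_weight <- as.numeric(zero_flux_weight)
  if (!is.finite(zero_flux_weight) || zero_flux_weight < 1e3)
    stop("zero_flux_weight must be finite and >= 1000")
  structure(list(scheme = scheme, zero_flux_weight = zero_flux_weight,
                 pin_zero_rates = isTRUE(pin_zero_rates)),
            class = "weight_spec")
}

# index positions of fixed reactions within the model ordering
fixed_indices <- function(model, scenario) {
  match(names(scenario$fixed), model$reaction_ids)
}
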