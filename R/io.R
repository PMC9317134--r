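# Readers and writers: SBML L3/FBC-v2 (read-only), a native JSON dialect,
# and TSV tables.  In files, infinity is encoded as +/-1e30 (the usual LP
# solver convention); internally true +/-Inf is used.

FILE_INF <- 1e30

.from_file_num <- function(x) {
  x <- as.numeric(x)
  x[x >= FILE_INF] <- Inf
  x[x <= -FILE_INF] <- -Inf
  x
}

.to_file_num <- function(x) {
  x <- as.numeric(x)
  x[x == Inf] <- FILE_INF
  x[x == -Inf] <- -FILE_INF
  x
}

#' Load a metabolic model from file
#'
#' Supported formats: `"sbml"` (SBML level 3 with the FBC v2 package for
#' bounds and objective), `"json"` (the native dialect written by
#' [write_model_json()]), and `"tsv"` (stoichiometric matrix with header
#' row of reaction ids and first column of metabolite ids, plus an
#' optional bounds table). Missing bounds default to `(-Inf, Inf)` for
#' reversible and `(0, Inf)` for irreversible reactions as declared by
#' the format.
#'
#' @param path file path.
#' @param format one of `"sbml"`, `"json"`, `"tsv"`; default guessed from
#'   the file extension.
#' @param bounds optional path to a TSV bounds table
#'   (`reaction_id  lb  ub  [objective]`), used by the `"tsv"` format.
#' @return A [metabolic_model()].
#' @export
load_model <- function(path, format = NULL, bounds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml", json = "json",
                     tsv = , txt = "tsv",
                     stop("cannot guess model format from extension: ", path))
  }
  format <- match.arg(tolower(format), c("sbml", "json", "tsv"))
  switch(format,
         sbml = read_model_sbml(path),
         json = read_model_json(path),
         tsv  = read_model_tsv(path, bounds))
}

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || length(doc$reactions) == 0L)
    stop("empty model: no reactions in ", path)
  mets <- as.character(unlist(doc$metabolites))
  rxns <- vapply(doc$reactions, function(r) as.character(r$id), "")
  N <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  obj <- numeric(length(rxns)); has_obj <- FALSE
  for (j in seq_along(doc$reactions)) {
    r <- doc$reactions[[j]]
    st <- r$stoichiometry
    if (length(st)) {
      bad <- setdiff(names(st), mets)
      if (length(bad))
        stop("reaction ", r$id, " references unknown metabolite(s): ",
             paste(bad, collapse = ", "))
      N[names(st), j] <- as.numeric(unlist(st))
    }
    lb[j] <- if (is.null(r$lb)) -Inf else .from_file_num(r$lb)
    ub[j] <- if (is.null(r$ub)) Inf else .from_file_num(r$ub)
    if (!is.null(r$objective)) { obj[j] <- as.numeric(r$objective); has_obj <- TRUE }
  }
  A <- NULL; b <- NULL
  if (!is.null(doc$constraints) && length(doc$constraints$rows)) {
    rows <- doc$constraints$rows
    A <- matrix(0, length(rows), length(rxns),
                dimnames = list(NULL, rxns))
    for (i in seq_along(rows)) {
      cf <- rows[[i]]
      bad <- setdiff(names(cf), rxns)
      if (length(bad))
        stop("constraint row ", i, " references unknown reaction(s): ",
             paste(bad, collapse = ", "))
      A[i, names(cf)] <- as.numeric(unlist(cf))
    }
    b <- .from_file_num(unlist(doc$constraints$b))
    if (length(b) != nrow(A))
      stop("dimension mismatch: constraints b has length ", length(b),
           " for ", nrow(A), " rows")
  }
  metabolic_model(N, rxns, mets, lb, ub, A, b,
                  objective_c = if (has_obj) obj else NULL)
}

#' Write a metabolic model in the native JSON dialect
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    nz <- which(model$N[, j] != 0)
    st <- as.list(model$N[nz, j])
    names(st) <- model$metabolite_ids[nz]
    r <- list(id = model$reaction_ids[j],
              stoichiometry = st,
              lb = .to_file_num(model$lb[j]),
              ub = .to_file_num(model$ub[j]))
    if (!is.null(model$objective_c)) r$objective <- model$objective_c[j]
    r
  })
  doc <- list(metabolites = model$metabolite_ids, reactions = rxns)
  if (!is.null(model$A)) {
    rows <- lapply(seq_len(nrow(model$A)), function(i) {
      nz <- which(model$A[i, ] != 0)
      cf <- as.list(model$A[i, nz])
      names(cf) <- model$reaction_ids[nz]
      cf
    })
    doc$constraints <- list(rows = rows, b = .to_file_num(model$b))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# SBML L3 + FBC v2 subset.  Namespace-robust via local-name() XPaths.
# Species with boundaryCondition="true" are external and excluded from N.
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  sp_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  rx_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("empty model: no reactions in ", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  boundary <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  mets <- sp_id[!boundary]
  # fbc parameters for bound lookup
  par_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))
  rxns <- xml2::xml_attr(rx_nodes, "id")
  N <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  for (j in seq_along(rx_nodes)) {
    node <- rx_nodes[[j]]
    add_side <- function(list_name, sign) {
      refs <- xml2::xml_find_all(
        node, paste0("./*[local-name()='", list_name,
                     "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        if (sp %in% mets) N[sp, j] <<- N[sp, j] + sign * coef
      }
    }
    add_side("listOfReactants", -1)
    add_side("listOfProducts", +1)
    rev <- !(tolower(xml2::xml_attr(node, "reversible")) %in% "false")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb[j] <- if (!is.na(lb_ref) && lb_ref %in% names(par_val))
      .from_file_num(par_val[[lb_ref]]) else if (rev) -Inf else 0
    ub[j] <- if (!is.na(ub_ref) && ub_ref %in% names(par_val))
      .from_file_num(par_val[[ub_ref]]) else Inf
  }
  # active fbc objective, if any
  obj <- NULL
  fo <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
  if (length(fo)) {
    obj <- numeric(length(rxns))
    for (node in fo) {
      rid <- xml2::xml_attr(node, "reaction")
      coef <- as.numeric(xml2::xml_attr(node, "coefficient"))
      if (rid %in% rxns) obj[match(rid, rxns)] <- coef
    }
  }
  metabolic_model(N, rxns, mets, lb, ub, objective_c = obj)
}

read_model_tsv <- function(path, bounds = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  if (ncol(tab) == 0L) stop("empty model: no reactions in ", path)
  N <- as.matrix(tab)
  rxns <- colnames(N); mets <- rownames(N)
  lb <- rep(-Inf, length(rxns)); ub <- rep(Inf, length(rxns)); obj <- NULL
  if (!is.null(bounds)) {
    bt <- utils::read.delim(bounds, check.names = FALSE)
    names(bt)[1] <- "reaction_id"
    bad <- setdiff(bt$reaction_id, rxns)
    if (length(bad))
      stop("dimension mismatch: bounds table names reaction(s) not in the ",
           "stoichiometry header: ", paste(bad, collapse = ", "))
    idx <- match(bt$reaction_id, rxns)
    lb[idx] <- .from_file_num(bt$lb)
    ub[idx] <- .from_file_num(bt$ub)
    if ("objective" %in% names(bt)) {
      obj <- numeric(length(rxns)); obj[idx] <- as.numeric(bt$objective)
    }
  }
  metabolic_model(N, rxns, mets, lb, ub, objective_c = obj)
}

#' Load a flux scenario from a TSV table
#'
#' Reads a two- or three-column table `reaction_id  value  [variance]`
#' (with or without a header line). Any model reaction clamped by
#' `lb = ub` is additionally imported into the fixed set; a clash between
#' such a clamp and a scenario row with a different value is an error.
#'
#' @param path file path; may be missing/empty to build a scenario purely
#'   from `lb = ub` clamps.
#' @param model a [metabolic_model()].
#' @return A [flux_scenario()].
#' @export
load_scenario <- function(path = NULL, model) {
  fixed <- numeric(0); variances <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    first <- readLines(path, n = 1L)
    has_header <- length(first) == 1L &&
      is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
    tab <- utils::read.delim(path, header = has_header,
                             check.names = FALSE, colClasses = "character")
    if (length(first) && nrow(tab)) {
      ids <- as.character(tab[[1]])
      fixed <- stats::setNames(as.numeric(tab[[2]]), ids)
      if (ncol(tab) >= 3L && !all(is.na(tab[[3]])))
        variances <- stats::setNames(as.numeric(tab[[3]]), ids)
    }
  }
  # auto-import lb = ub clamps
  clamped <- which(model$lb == model$ub)
  for (j in clamped) {
    id <- model$reaction_ids[j]
    if (!id %in% names(fixed))
      fixed[id] <- model$lb[j]
  }
  flux_scenario(fixed, variances, model = model)
}

#' Write a flux scenario as TSV
#'
#' @param scenario a [flux_scenario()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_tsv <- function(scenario, path) {
  df <- data.frame(reaction_id = names(scenario$fixed),
                   value = unname(scenario$fixed))
  if (!is.null(scenario$variances))
    df$variance <- unname(scenario$variances[df$reaction_id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a combined analysis report
#'
#' Serializes any combination of a diagnosis, a correction result and an
#' FVA result to JSON (round-trippable via [read_report()]) or to a flat
#' TSV. Corrections are always reported as `corrected - given`, whatever
#' the internal sign convention of the method.
#'
#' @param diagnosis optional `scenario_diagnosis`.
#' @param corrections optional `correction_result`.
#' @param ranges optional `fva_result`.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(diagnosis = NULL, corrections = NULL, ranges = NULL,
                         path, format = c("json", "tsv")) {
  format <- match.arg(format)
  rep <- list()
  if (!is.null(diagnosis)) {
    rep$diagnosis <- list(
      determinacy = diagnosis$determinacy,
      redundancy = diagnosis$redundancy,
      consistency = diagnosis$consistency,
      rank_N = diagnosis$rank_N, rank_NU = diagnosis$rank_NU,
      conservation_relations = diagnosis$c,
      dof = diagnosis$dof, degR = diagnosis$degR,
      redundant_rate_ids = as.list(diagnosis$redundant_rate_ids),
      determined_unknowns = as.list(diagnosis$determined_unknowns),
      residual = diagnosis$residual)
  }
  if (!is.null(corrections)) {
    ch <- correction_changes(corrections)
    rep$corrections <- list(
      method = corrections$method,
      status = corrections$status,
      objective_value = corrections$objective_value,
      already_feasible = !is.na(corrections$objective_value) &&
        corrections$objective_value <= 1e-12,
      change = as.list(ch),
      corrected_values = as.list(corrections$corrected_values))
    if (!is.null(corrections$constraint_slacks))
      rep$corrections$constraint_slacks <-
        lapply(corrections$constraint_slacks, as.list)
  }
  if (!is.null(ranges)) {
    rep$fva <- list(reaction = as.list(ranges$reaction_ids),
                    min = as.list(.to_file_num(ranges$min_flux)),
                    max = as.list(.to_file_num(ranges$max_flux)),
                    determined = as.list(ranges$determined))
  }
  if (format == "json") {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(rep$diagnosis)) {
      d <- rep$diagnosis
      writeLines(c("# diagnosis",
                   paste("determinacy", d$determinacy, sep = "\t"),
                   paste("redundancy", d$redundancy, sep = "\t"),
                   paste("consistency", d$consistency, sep = "\t"),
                   paste("degR", d$degR, sep = "\t"),
                   paste("dof", d$dof, sep = "\t"),
                   paste("redundant_rates",
                         paste(unlist(d$redundant_rate_ids), collapse = ","),
                         sep = "\t")), con)
    }
    if (!is.null(rep$corrections)) {
      cr <- rep$corrections
      writeLines(c("# corrections",
                   paste("method", cr$method, sep = "\t"),
                   paste("status", cr$status, sep = "\t"),
                   paste("objective", cr$objective_value, sep = "\t")), con)
      if (isTRUE(cr$already_feasible))
        writeLines("note\talready feasible: no corrections needed", con)
      writeLines("reaction_id\tchange\tcorrected", con)
      for (id in names(cr$change))
        writeLines(paste(id, cr$change[[id]], cr$corrected_values[[id]],
                         sep = "\t"), con)
    }
    if (!is.null(rep$fva)) {
      writeLines(c("# fva", "reaction_id\tmin\tmax\tdetermined"), con)
      for (i in seq_along(rep$fva$reaction))
        writeLines(paste(rep$fva$reaction[[i]], rep$fva$min[[i]],
                         rep$fva$max[[i]], rep$fva$determined[[i]],
                         sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Re-read a JSON report written by [write_report()]
#'
#' @param path file path.
#' @return A list with any of the components `diagnosis`, `corrections`,
#'   `fva`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
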