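# Small builders shared across the test files.

# Linear chain ->A->B->: R1 produces A, R2 converts A to B, R3 drains B.
chain3 <- function(lb = c(0, 0, 0), ub = rep(Inf, 3)) {
  N <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("R1", "R2", "R3")))
  metabolic_model(N, lb = lb, ub = ub)
}

# Serialize a model to a minimal SBML L3 + FBC v2 document (tests only;
# the package itself deliberately does not write SBML).
sbml_string <- function(model) {
  num <- function(x) {
    x[x == Inf] <- 1e30; x[x == -Inf] <- -1e30
    format(x, scientific = FALSE)
  }
  sp <- paste(sprintf(
    '      <species id="%s" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
    model$metabolite_ids), collapse = "\n")
  pars <- character(0)
  rx <- vapply(seq_along(model$reaction_ids), function(j) {
    id <- model$reaction_ids[j]
    pars <<- c(pars,
               sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>',
                       id, num(model$lb[j])),
               sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>',
                       id, num(model$ub[j])))
    subs <- which(model$N[, j] < 0); prods <- which(model$N[, j] > 0)
    side <- function(idx, tag) {
      if (!length(idx)) return("")
      refs <- paste(sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        model$metabolite_ids[idx], num(abs(model$N[idx, j]))), collapse = "\n")
      sprintf("        <%s>\n%s\n        </%s>", tag, refs, tag)
    }
    sprintf(paste0(
      '      <reaction id="%s" reversible="%s" fast="false" ',
      'fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">\n%s\n%s\n      </reaction>'),
      id, tolower(model$lb[j] < 0), id, id,
      side(subs, "listOfReactants"), side(prods, "listOfProducts"))
  }, "")
  obj <- ""
  if (!is.null(model$objective_c) && any(model$objective_c != 0)) {
    nz <- which(model$objective_c != 0)
    fo <- paste(sprintf(
      '          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
      model$reaction_ids[nz], num(model$objective_c[nz])), collapse = "\n")
    obj <- sprintf(paste0(
      '    <fbc:listOfObjectives fbc:activeObjective="obj">\n',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">\n',
      '        <fbc:listOfFluxObjectives>\n%s\n',
      '        </fbc:listOfFluxObjectives>\n      </fbc:objective>\n',
      '    </fbc:listOfObjectives>\n'), fo)
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">\n',
    '  <model id="test" fbc:strict="true">\n',
    '    <listOfCompartments>\n      <compartment id="c" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', sp, '\n    </listOfSpecies>\n',
    '    <listOfParameters>\n', paste(pars, collapse = "\n"),
    '\n    </listOfParameters>\n',
    '    <listOfReactions>\n', paste(rx, collapse = "\n"),
    '\n    </listOfReactions>\n', obj,
    '  </model>\n</sbml>\n')
}

write_sbml_tmp <- function(model) {
  path <- tempfile(fileext = ".xml")
  writeLines(sbml_string(model), path)
  path
}

# Full flux vector of a scenario completed by the pseudoinverse solution.
pinv_full_flux <- function(model, scenario) {
  part <- partition(model, scenario)
  r <- stats::setNames(numeric(length(model$reaction_ids)),
                       model$reaction_ids)
  rU <- pseudoinverse_solution(part)
  r[names(rU)] <- rU
  r[names(scenario$fixed)] <- scenario$fixed
  r
}

# Model with bounds replaced by a wide box, dropping bound effects.
widen_bounds <- function(model, cap = 1e6) {
  metabolic_model(model$N, model$reaction_ids, model$metabolite_ids,
                  lb = rep(-cap, length(model$lb)),
                  ub = rep(cap, length(model$ub)),
                  A = model$A, b = model$b,
                  objective_c = model$objective_c)
}
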