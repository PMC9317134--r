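Package: fluxbalancer
Title: Diagnosing and Resolving Infeasible Flux Balance Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based metabolic modelling scenarios in
    which fixed (measured) reaction rates render a flux balance analysis
    (FBA) problem infeasible. Classifies scenarios by determinacy,
    redundancy and consistency using stoichiometric rank analysis and the
    redundancy matrix, identifies the fixed rates responsible for
    inconsistencies, and computes minimal corrections by analytical
    weighted least squares, by quadratic programming, or by linear
    programming with paired slack variables. Corrections can also be
    applied to steady-state rows, flux bounds and general linear
    constraints. Includes FBA and flux variability analysis (FVA) on the
    corrected system, readers for SBML L3/FBC-v2 and a native JSON/TSV
    model dialect, bundled worked-example networks and a seeded synthetic
    scenario generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
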