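Package: chassiscraft
Title: Model-Guided Design of Growth-Coupled Chassis Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Constraint-based design of microbial chassis strains. Provides a
    compact data model for genome-scale metabolic networks (stoichiometry, flux
    bounds, gene-protein-reaction rules, carbon counts) with SBML Level 3 (fbc)
    and JSON input/output, phenotype prediction by flux balance analysis (FBA),
    parsimonious FBA, linear minimization of metabolic adjustment (lMOMA) and
    flux variability analysis (FVA), a knockout-target filtering pipeline
    (essentiality, gene association, drains/transporters, blocked and fully
    coupled reactions), a SPEA2 multi-objective search for gene-knockout sets
    that couple growth to product secretion, a chassis-analysis stage that
    scores gene sets shared across multiple target products (gene and chassis
    scores, frequency clustering), and an omics-constrained flux-fitting stage
    that integrates transcript, protein and exometabolite fold changes into
    flux balance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
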