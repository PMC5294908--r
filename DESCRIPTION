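Package: oncolattice
Title: Derivative Diagnosis Lattices for Integrating ICD-10 and ICD-O-3
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a machine-readable "derivative" integration model that
    bridges ICD-10 diagnosis codes and ICD-O-3 topography-morphology code
    pairs through a diagnosis lattice derived from an NCIt-style oncology
    ontology. Constructs a reflexive-part (S-node) topography lattice over
    the anatomy axis, a behavior-stratified morphology axis from ICD-O-3
    annotations, and retains the cross-product diagnosis classes that
    structurally subsume at least one source concept. Terminology codes are
    bound to the model through CUI crosswalks, audited for multi-class
    instantiation (is_a overloading, behavior conflicts), and evaluated
    against SEER-style conversion gold standards by minimum hierarchical
    edge distance. Includes deterministic fixture generators, a planted
    gold-standard simulator, and an independent rule-saturation oracle for
    testing structural subsumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    igraph,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
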