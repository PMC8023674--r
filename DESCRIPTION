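Package: mi2castr
Title: Validation and Interchange of Causal Molecular Interaction Statements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating causal molecular interaction statements
    against the MI2CAST minimum-information checklist. Provides a typed
    data model for causal statements (source and target entities, causal
    relation, evidence and biological context), a compact-identifier
    (CURIE) registry with per-namespace accession syntax, an OBO-subset
    loader with ontology branch-membership queries, a rule engine that
    grades each statement against the four MI2CAST rules with
    ERROR/WARNING/INFO findings, lossless canonical JSON and PSI-MITAB 2.8
    serialization, signed SIF export, a seeded generator of valid and
    deliberately violated statements for validator benchmarking, and a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
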