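Package: baomini
Title: Layered Bioassay-Ontology Modularization and Description-Logic Reasoning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for engineering modular OWL ontologies of
    high-throughput screening bioassays and reasoning over them. Provides a
    layered modularization framework (vocabularies, modules, axiom files,
    combinators and perspectives connected by an acyclic import graph, with
    per-layer purity validation), a tableau reasoner for the ALC description
    logic with atomic role hierarchies (satisfiability, subsumption,
    classification, instance retrieval and minimal justifications, backed by
    a direct-semantics model checker), a deterministic generator for a
    compact bioassay ontology fixture ("BAO-mini") covering luciferase assay
    classification, measure-group inference and kinase panel construction,
    and utilities to turn spreadsheet-style assay annotation tables into RDF
    triples for reasoning-backed retrieval.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
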