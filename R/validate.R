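# Layer-purity validation. Each file kind in the layered architecture obeys
# rules: vocabularies carry terms and subsumption only; axiom files carry
# logic over imported terms but declare no classes or properties;
# combinators carry only atomic cross-namespace bridges; modules and
# perspectives are unrestricted here and are checked for self-containedness
# over their import closure instead.

is_atomic_pair <- function(ax)
  ax$sub$kind == "atomic" && ax$sup$kind == "atomic"

#' Validate a file against its layer's purity rules
#'
#' * `vocabulary` (and, by this package's convention, property
#'   vocabularies): only declarations, annotations, atomic-to-atomic
#'   `SubClassOf`, and atomic `SubObjectPropertyOf` are allowed.
#' * `axiomfile`: logical axioms and annotations only; no declarations of
#'   classes or properties (individuals may be declared for ABox files).
#' * `combinator`: only `EquivalentClasses`/`SubClassOf` bridges between two
#'   atomic terms of different namespaces.
#' * `module`, `perspective`, `external_stub`: no purity restriction
#'   (self-containedness is [check_self_contained()]'s job).
#'
#' @param file a `bao_ontology_file` (from a catalog) or a list with
#'   `iri`, `kind` and `ontology`.
#' @return a `bao_validation_report`.
#' @export
validate_artifact <- function(file) {
  onto <- file$ontology
  v <- list()
  bad <- function(rule, subject, message)
    v[[length(v) + 1L]] <<- violation(rule, subject, message)
  if (file$kind == "vocabulary") {
    for (ax in onto$axioms) {
      s <- axiom_str(ax)
      if (ax$kind %in% c("declaration", "annotation")) next
      if (ax$kind == "subclass") {
        if (!is_atomic_pair(ax))
          bad("vocabulary-subsumption-only", s,
              "vocabularies may only relate named terms by plain subsumption")
        next
      }
      if (ax$kind == "subrole") next
      bad("vocabulary-subsumption-only", s,
          sprintf("axiom kind '%s' is not allowed in a vocabulary", ax$kind))
    }
  } else if (file$kind == "axiomfile") {
    for (ax in onto$axioms) {
      s <- axiom_str(ax)
      if (ax$kind == "declaration" &&
          ax$entity_kind %in% c("Class", "ObjectProperty", "DataProperty"))
        bad("axiomfile-no-declarations", s,
            "axiom files must not declare classes or properties")
    }
  } else if (file$kind == "combinator") {
    for (ax in onto$axioms) {
      s <- axiom_str(ax)
      if (ax$kind == "annotation") next
      if (ax$kind == "subclass" && is_atomic_pair(ax)) {
        if (curie_prefix(ax$sub$name) == curie_prefix(ax$sup$name))
          bad("combinator-cross-namespace", s,
              "combinator bridges must connect different namespaces")
        next
      }
      if (ax$kind == "subrole") {
        if (curie_prefix(ax$sub) == curie_prefix(ax$sup))
          bad("combinator-cross-namespace", s,
              "combinator bridges must connect different namespaces")
        next
      }
      if (ax$kind == "equivalent" &&
          all(vapply(ax$exprs, function(e) e$kind == "atomic", NA))) {
        if (length(unique(curie_prefix(vapply(ax$exprs, `[[`, "", "name")))) < 2L)
          bad("combinator-cross-namespace", s,
              "combinator bridges must connect different namespaces")
        next
      }
      bad("combinator-bridges-only", s,
          "combinators may only contain atomic equivalence/subsumption bridges")
    }
  }
  validation_report(file$iri, v)
}

#' Check self-containedness of a file over its import closure
#'
#' A file is self-contained when every IRI occurring in the axioms of the
#' file and its import closure is declared somewhere within that same
#' closure: no outside term or relationship.
#'
#' @param file a `bao_ontology_file`.
#' @param graph a `bao_import_graph` containing the file.
#' @return a `bao_validation_report` (rule `self-contained`, one violation
#'   per undeclared IRI).
#' @export
check_self_contained <- function(file, graph) {
  closure <- import_closure(graph, file$iri)
  axioms <- do.call(c, c(lapply(closure, function(i)
    graph$files[[i]]$ontology$axioms), list(list())))
  sig <- signature_of(axioms)
  declared <- signature_of(Filter(function(a) a$kind == "declaration", axioms))
  v <- list()
  for (kind in names(declared)) {
    undeclared <- setdiff(sig[[kind]], declared[[kind]])
    for (u in undeclared)
      v[[length(v) + 1L]] <- violation(
        "self-contained", u,
        sprintf("%s used but not declared in the import closure of %s",
                sub("_", " ", kind), file$iri))
  }
  validation_report(file$iri, v)
}

#' Validate every file of a catalog
#'
#' Runs [assert_acyclic()] on the import graph, [validate_artifact()] on
#' every file and [check_self_contained()] on every module and perspective.
#'
#' @param catalog a `bao_catalog`.
#' @return named list of `bao_validation_report`s (the acyclicity report
#'   under `"<import graph>"`).
#' @export
validate_catalog <- function(catalog) {
  graph <- build_import_graph(catalog)
  reports <- list("<import graph>" = assert_acyclic(graph))
  for (iri in graph$nodes) {
    reports[[iri]] <- validate_artifact(graph$files[[iri]])
    if (graph$files[[iri]]$kind %in% c("module", "perspective") &&
        reports[["<import graph>"]]$passed) {
      sc <- check_self_contained(graph$files[[iri]], graph)
      if (!sc$passed)
        reports[[iri]] <- validation_report(
          iri, c(reports[[iri]]$violations, sc$violations))
    }
  }
  reports
}
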