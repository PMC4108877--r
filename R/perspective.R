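# Perspectives (views on the knowledge base), module extraction from
# external taxonomies, and combinator generation.

#' Build a perspective: the merged ontology of an import closure
#'
#' Validates the catalog (acyclic imports, all layer rules), then merges the
#' deduplicated union of all axioms over the import closure of `root` under
#' canonical structural equality. The result carries no imports and is
#' independent of catalog entry order.
#'
#' @param root the perspective's root file IRI.
#' @param catalog a `bao_catalog`.
#' @return a `bao_ontology`.
#' @export
build_perspective <- function(root, catalog) {
  graph <- build_import_graph(catalog)
  acyc <- assert_acyclic(graph)
  if (!acyc$passed)
    stop(paste(c("cannot build perspective: import graph has cycles",
                 vapply(acyc$violations, `[[`, "", "message")),
               collapse = "\n"), call. = FALSE)
  closure <- import_closure(graph, root)
  for (iri in closure) {
    rep <- validate_artifact(graph$files[[iri]])
    if (!rep$passed)
      stop(paste(c(sprintf("cannot build perspective: %s fails validation",
                           iri),
                   vapply(rep$violations, `[[`, "", "message")),
               collapse = "\n"), call. = FALSE)
  }
  merged <- merge_ontologies(lapply(closure, function(i)
    graph$files[[i]]$ontology), iri = root)
  merged$axioms <- order_axioms(merged$axioms)
  merged
}

#' Extract a module from an external taxonomy by upward closure
#'
#' Starting from the seed terms, follows asserted atomic subsumptions up to
#' the external ontology's roots and returns the seeds, all their ancestors,
#' the connecting `SubClassOf` axioms, their declarations and (optionally)
#' their label annotations — nothing else. Monotone in the seed set.
#'
#' @param external a `bao_ontology` (typically a taxonomy).
#' @param seeds character vector of class IRIs; must be in the external
#'   signature.
#' @param annotations copy `rdfs:label` annotations of kept terms.
#' @param iri IRI for the extracted module.
#' @return a `bao_ontology`.
#' @export
extract_module <- function(external, seeds, annotations = TRUE,
                           iri = paste0(external$iri, "_module")) {
  sig <- signature_of(external)
  unknown <- setdiff(seeds, c(sig$classes, sig$roles, sig$individuals,
                              sig$data_properties))
  if (length(unknown))
    stop(sprintf("unknown seed IRI(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  atomic_subs <- Filter(function(a) a$kind == "subclass" && is_atomic_pair(a),
                        external$axioms)
  parent_of <- lapply(atomic_subs, function(a) c(a$sub$name, a$sup$name))
  kept <- character()
  frontier <- seeds
  while (length(frontier)) {
    kept <- c(kept, frontier)
    ups <- unlist(lapply(parent_of, function(p)
      if (p[[1L]] %in% frontier) p[[2L]] else NULL))
    frontier <- setdiff(unique(ups), kept)
  }
  kept <- sort(unique(kept))
  axioms <- c(
    Filter(function(a) a$kind == "declaration" && a$iri %in% kept,
           external$axioms),
    Filter(function(a) a$kind == "subclass" && is_atomic_pair(a) &&
             a$sub$name %in% kept && a$sup$name %in% kept,
           external$axioms),
    if (annotations)
      Filter(function(a) a$kind == "annotation" &&
               a$property == "rdfs:label" && a$subject %in% kept,
             external$axioms))
  ontology(iri, axioms)
}

#' Generate a combinator module from term mappings
#'
#' Emits one bridging axiom per mapping between an internal and an external
#' term: `equivalent` becomes `EquivalentClasses`, `subclass` asserts the
#' internal term under the external one, `superclass` the converse. The
#' result passes [validate_artifact()] with kind `combinator`.
#'
#' @param mappings list of mappings, each a list/vector with `internal`,
#'   `external` and `relation` (one of equivalent, subclass, superclass).
#' @param iri IRI for the combinator ontology.
#' @return a `bao_ontology`.
#' @export
make_combinator <- function(mappings, iri = "bao:combinator") {
  seen <- character()
  axioms <- list()
  for (m in mappings) {
    m <- as.list(m)
    stopifnot(m$relation %in% c("equivalent", "subclass", "superclass"))
    key <- paste(m$internal, m$external)
    if (key %in% names(seen) && seen[[key]] != m$relation)
      stop(sprintf("conflicting mappings for pair (%s, %s): %s vs %s",
                   m$internal, m$external, seen[[key]], m$relation),
           call. = FALSE)
    seen[[key]] <- m$relation
    axioms[[length(axioms) + 1L]] <- switch(m$relation,
      equivalent = ax_equivalent(list(ce_atomic(m$internal),
                                      ce_atomic(m$external))),
      subclass = ax_subclass(ce_atomic(m$internal), ce_atomic(m$external)),
      superclass = ax_subclass(ce_atomic(m$external), ce_atomic(m$internal)))
  }
  ontology(iri, axioms)
}
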