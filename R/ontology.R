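# An Ontology is a duplicate-free set of axioms (TBox + RBox + ABox +
# declarations + annotations) with an IRI and a list of direct imports.

#' Construct an ontology
#'
#' @param iri the ontology IRI (CURIE or full IRI string).
#' @param axioms a list of `bao_axiom` objects; duplicates under canonical
#'   structural equality are dropped.
#' @param imports character vector of directly imported ontology IRIs.
#' @return a `bao_ontology`.
#' @export
ontology <- function(iri = "bao:anonymous", axioms = list(),
                     imports = character()) {
  strs <- vapply(axioms, axiom_str, "")
  axioms <- axioms[!duplicated(strs)]
  structure(list(iri = iri, axioms = axioms,
                 imports = unique(as.character(imports))),
            class = "bao_ontology")
}

#' @export
print.bao_ontology <- function(x, ...) {
  kinds <- vapply(x$axioms, `[[`, "", "kind")
  cat("<ontology> ", x$iri, "\n", sep = "")
  if (length(x$imports))
    cat("  imports: ", paste(x$imports, collapse = ", "), "\n", sep = "")
  cat("  axioms: ", length(x$axioms),
      " (tbox ", sum(kinds %in% TBOX_KINDS),
      ", rbox ", sum(kinds %in% RBOX_KINDS),
      ", abox ", sum(kinds %in% ABOX_KINDS),
      ", declarations ", sum(kinds == "declaration"),
      ", annotations ", sum(kinds == "annotation"), ")\n", sep = "")
  invisible(x)
}

axioms_of_kind <- function(onto, kinds) {
  onto$axioms[vapply(onto$axioms, `[[`, "", "kind") %in% kinds]
}

#' Axiom-group accessors
#'
#' Extract the TBox (class axioms), RBox (role axioms), ABox (assertions),
#' declarations or annotations of an ontology.
#'
#' @param onto a `bao_ontology`.
#' @return a list of `bao_axiom` objects.
#' @name axiom-groups
NULL

#' @rdname axiom-groups
#' @export
tbox <- function(onto) axioms_of_kind(onto, TBOX_KINDS)

#' @rdname axiom-groups
#' @export
rbox <- function(onto) axioms_of_kind(onto, RBOX_KINDS)

#' @rdname axiom-groups
#' @export
abox <- function(onto) axioms_of_kind(onto, ABOX_KINDS)

#' @rdname axiom-groups
#' @export
declarations <- function(onto) axioms_of_kind(onto, "declaration")

#' @rdname axiom-groups
#' @export
annotations <- function(onto) axioms_of_kind(onto, "annotation")

#' Merge ontologies into one axiom set
#'
#' Deduplicated union of the axioms of several ontologies under canonical
#' structural equality; the result carries no imports. Merging is commutative
#' and associative at the axiom-set level.
#'
#' @param ontos list of `bao_ontology` objects.
#' @param iri IRI of the merged ontology.
#' @return a `bao_ontology` without imports.
#' @export
merge_ontologies <- function(ontos, iri = "bao:merged") {
  ontology(iri, do.call(c, c(lapply(ontos, `[[`, "axioms"), list(list()))))
}

concept_signature <- function(expr, sig) {
  walk <- function(e) {
    switch(e$kind,
      atomic = sig$classes <<- c(sig$classes, e$name),
      top = NULL, bottom = NULL,
      not = walk(e$arg),
      and = , or = lapply(e$args, walk),
      some = , only = { sig$roles <<- c(sig$roles, e$role); walk(e$filler) },
      min = , max = { sig$roles <<- c(sig$roles, e$role); walk(e$filler) },
      nominal = sig$individuals <<- c(sig$individuals, e$individual),
      self = sig$roles <<- c(sig$roles, e$role))
    invisible(NULL)
  }
  walk(expr)
  sig
}

#' Signature of an axiom set
#'
#' Collects the exact set of IRIs occurring in the given axioms, partitioned
#' into classes, roles (object properties), individuals and data properties.
#' The built-ins `owl:Thing` / `owl:Nothing` are not part of any signature.
#' Declarations contribute their declared IRI; annotation assertions are
#' non-logical and contribute nothing.
#'
#' @param x a `bao_ontology` or a list of `bao_axiom` objects.
#' @return a list with sorted character vectors `classes`, `roles`,
#'   `individuals`, `data_properties`.
#' @export
signature_of <- function(x) {
  axioms <- if (inherits(x, "bao_ontology")) x$axioms else x
  sig <- list(classes = character(), roles = character(),
              individuals = character(), data_properties = character())
  env <- environment()
  add_expr <- function(e) assign("sig", concept_signature(e, sig), envir = env)
  for (ax in axioms) {
    switch(ax$kind,
      subclass = { add_expr(ax$sub); add_expr(ax$sup) },
      equivalent = , disjoint = for (e in ax$exprs) add_expr(e),
      subrole = sig$roles <- c(sig$roles, ax$sub, ax$sup),
      role_characteristic = sig$roles <- c(sig$roles, ax$role),
      class_assertion = {
        add_expr(ax$expr)
        sig$individuals <- c(sig$individuals, ax$individual)
      },
      property_assertion = {
        sig$roles <- c(sig$roles, ax$role)
        sig$individuals <- c(sig$individuals, ax$subject, ax$object)
      },
      data_assertion = {
        sig$data_properties <- c(sig$data_properties, ax$property)
        sig$individuals <- c(sig$individuals, ax$subject)
      },
      declaration = switch(ax$entity_kind,
        Class = sig$classes <- c(sig$classes, ax$iri),
        ObjectProperty = sig$roles <- c(sig$roles, ax$iri),
        DataProperty = sig$data_properties <- c(sig$data_properties, ax$iri),
        NamedIndividual = sig$individuals <- c(sig$individuals, ax$iri),
        AnnotationProperty = NULL),
      annotation = NULL)
  }
  lapply(sig, function(v) sort(unique(v)))
}

#' Named classes of an ontology's signature
#' @param onto a `bao_ontology`.
#' @return sorted character vector of class IRIs.
#' @export
named_classes <- function(onto) signature_of(onto)$classes
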