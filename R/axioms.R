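# Axiom variants of the knowledge base: TBox (SubClassOf, EquivalentClasses,
# DisjointClasses), RBox (SubObjectPropertyOf, role characteristics), ABox
# (class/property/data assertions), plus Declarations and annotations.
# Like concepts, every axiom caches a canonical string used for set
# semantics, deduplication and deterministic file output.

new_axiom <- function(kind, fields, cstr) {
  x <- c(list(kind = kind), fields)
  attr(x, "cstr") <- cstr
  class(x) <- "bao_axiom"
  x
}

#' Canonical serialization of an axiom
#' @param x a `bao_axiom`.
#' @return a character scalar; identical strings mean structurally equal
#'   axioms (argument order of equivalence/disjointness is canonicalized).
#' @export
axiom_str <- function(x) {
  if (!inherits(x, "bao_axiom")) stop("not an axiom")
  attr(x, "cstr")
}

#' Axiom constructors
#'
#' Build the axiom variants of a knowledge base. `exprs` lists of
#' [ax_equivalent()] and [ax_disjoint()] must have length at least two and are
#' canonically sorted. [ax_data_assertion()] carries an inert literal value
#' with a unit tag; it is queryable but ignored by the reasoner.
#'
#' @param sub,sup class expressions (or role IRIs for [ax_subrole()]).
#' @param exprs a list of at least two class expressions.
#' @param expr a class expression.
#' @param individual,subject,object individual IRIs.
#' @param role,property an object/data/annotation property IRI.
#' @param value a numeric or character literal.
#' @param unit a unit IRI tag.
#' @param entity_kind one of `"Class"`, `"ObjectProperty"`, `"DataProperty"`,
#'   `"NamedIndividual"`, `"AnnotationProperty"`.
#' @param iri the declared IRI.
#' @param text annotation text.
#' @param characteristic a role characteristic name (e.g. `"transitive"`);
#'   stored as parsed metadata, rejected by the reasoner.
#' @return a `bao_axiom`.
#' @name axiom-constructors
NULL

#' @rdname axiom-constructors
#' @export
ax_subclass <- function(sub, sup) {
  new_axiom("subclass", list(sub = sub, sup = sup),
            paste0("SubClassOf(", ce_str(sub), " ", ce_str(sup), ")"))
}

sort_exprs <- function(exprs) {
  strs <- vapply(exprs, ce_str, "")
  keep <- !duplicated(strs)
  exprs <- exprs[keep]
  exprs[order(strs[keep], method = "radix")]
}

#' @rdname axiom-constructors
#' @export
ax_equivalent <- function(exprs) {
  exprs <- sort_exprs(exprs)
  stopifnot(length(exprs) >= 2L)
  new_axiom("equivalent", list(exprs = exprs),
            paste0("EquivalentClasses(",
                   paste(vapply(exprs, ce_str, ""), collapse = " "), ")"))
}

#' @rdname axiom-constructors
#' @export
ax_disjoint <- function(exprs) {
  exprs <- sort_exprs(exprs)
  stopifnot(length(exprs) >= 2L)
  new_axiom("disjoint", list(exprs = exprs),
            paste0("DisjointClasses(",
                   paste(vapply(exprs, ce_str, ""), collapse = " "), ")"))
}

#' @rdname axiom-constructors
#' @export
ax_subrole <- function(sub, sup) {
  stopifnot(is.character(sub), is.character(sup))
  new_axiom("subrole", list(sub = sub, sup = sup),
            paste0("SubObjectPropertyOf(", sub, " ", sup, ")"))
}

#' @rdname axiom-constructors
#' @export
ax_role_characteristic <- function(characteristic, role) {
  ok <- c("transitive", "symmetric", "asymmetric", "reflexive",
          "irreflexive", "functional", "inverse-functional")
  stopifnot(characteristic %in% ok)
  new_axiom("role_characteristic",
            list(characteristic = characteristic, role = role),
            paste0("RoleCharacteristic(", characteristic, " ", role, ")"))
}

#' @rdname axiom-constructors
#' @export
ax_class_assertion <- function(expr, individual) {
  new_axiom("class_assertion", list(expr = expr, individual = individual),
            paste0("ClassAssertion(", ce_str(expr), " ", individual, ")"))
}

#' @rdname axiom-constructors
#' @export
ax_property_assertion <- function(role, subject, object) {
  new_axiom("property_assertion",
            list(role = role, subject = subject, object = object),
            paste0("ObjectPropertyAssertion(", role, " ", subject, " ",
                   object, ")"))
}

#' @rdname axiom-constructors
#' @export
ax_data_assertion <- function(property, subject, value, unit = "uo:dimensionless") {
  new_axiom("data_assertion",
            list(property = property, subject = subject, value = value,
                 unit = unit),
            paste0("DataPropertyAssertion(", property, " ", subject, " \"",
                   format(value, scientific = FALSE, trim = TRUE),
                   "\"^^", unit, ")"))
}

DECL_KINDS <- c("Class", "ObjectProperty", "DataProperty", "NamedIndividual",
                "AnnotationProperty")

#' @rdname axiom-constructors
#' @export
ax_declaration <- function(entity_kind, iri) {
  stopifnot(entity_kind %in% DECL_KINDS)
  new_axiom("declaration", list(entity_kind = entity_kind, iri = iri),
            paste0("Declaration(", entity_kind, "(", iri, "))"))
}

#' @rdname axiom-constructors
#' @export
ax_annotation <- function(subject, property, text) {
  new_axiom("annotation", list(subject = subject, property = property,
                               text = text),
            paste0("AnnotationAssertion(", property, " ", subject, " \"",
                   gsub("\"", "\\\\\"", text), "\")"))
}

#' @export
print.bao_axiom <- function(x, ...) {
  cat("<axiom> ", axiom_str(x), "\n", sep = "")
  invisible(x)
}

TBOX_KINDS <- c("subclass", "equivalent", "disjoint")
RBOX_KINDS <- c("subrole", "role_characteristic")
ABOX_KINDS <- c("class_assertion", "property_assertion", "data_assertion")

# Deterministic ordering of axioms inside a serialized file.
AXIOM_KIND_ORDER <- c("declaration", "annotation", "subrole",
                      "role_characteristic", "subclass", "equivalent",
                      "disjoint", "class_assertion", "property_assertion",
                      "data_assertion")

order_axioms <- function(axioms) {
  kinds <- vapply(axioms, `[[`, "", "kind")
  strs <- vapply(axioms, axiom_str, "")
  axioms[order(match(kinds, AXIOM_KIND_ORDER), strs, method = "radix")]
}
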