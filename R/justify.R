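# Minimal justifications for entailments, by deletion-based shrinking: walk
# the logical axioms once and drop every axiom whose removal preserves the
# entailment. The result entails, and removing any single member breaks the
# entailment, so it is minimal in the single-deletion sense.

#' Does a knowledge base entail an axiom?
#'
#' Supported entailment forms: `SubClassOf` (via [check_subsumption()]),
#' `EquivalentClasses` (mutual subsumption), `ClassAssertion` (via
#' [check_instance()]).
#'
#' @param kb a `bao_ontology`.
#' @param entailment a `bao_axiom`.
#' @param node_cap see [is_satisfiable()].
#' @return logical.
#' @export
entails <- function(kb, entailment, node_cap = 50000L) {
  switch(entailment$kind,
    subclass = check_subsumption(kb, entailment$sub, entailment$sup, node_cap),
    equivalent = {
      es <- entailment$exprs
      all(vapply(seq_along(es)[-1L], function(i)
        check_subsumption(kb, es[[1L]], es[[i]], node_cap) &&
        check_subsumption(kb, es[[i]], es[[1L]], node_cap), NA))
    },
    class_assertion = check_instance(kb, entailment$individual,
                                     entailment$expr, node_cap),
    stop(sprintf("entailment checking not supported for axiom kind '%s'",
                 entailment$kind), call. = FALSE))
}

#' Minimal justification for an entailment
#'
#' Returns a minimal subset J of the knowledge base's logical axioms such
#' that J entails the given axiom while removing any single member of J
#' breaks the entailment. Computed by deletion-based shrinking over the
#' axioms in canonical order, so the result is deterministic. Tautologies
#' justify themselves with the empty set; a non-entailed input is an error.
#'
#' @param kb a `bao_ontology`.
#' @param entailment a `bao_axiom` entailed by `kb`.
#' @param node_cap see [is_satisfiable()].
#' @return list of `bao_axiom` objects.
#' @export
justify <- function(kb, entailment, node_cap = 50000L) {
  logical_kinds <- c(TBOX_KINDS, "subrole", ABOX_KINDS)
  keep_fixed <- Filter(function(a) !(a$kind %in% logical_kinds), kb$axioms)
  candidates <- order_axioms(Filter(function(a) a$kind %in% logical_kinds,
                                    kb$axioms))
  as_kb <- function(axs) ontology(kb$iri, c(keep_fixed, axs))
  if (!entails(as_kb(candidates), entailment, node_cap))
    stop("not entailed: the knowledge base does not entail the given axiom",
         call. = FALSE)
  current <- candidates
  for (ax in candidates) {
    trial <- Filter(function(a) axiom_str(a) != axiom_str(ax), current)
    if (entails(as_kb(trial), entailment, node_cap)) current <- trial
  }
  current
}
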