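# Negation normal form and TBox internalization: standard preprocessing for
# the tableau, restricted to the ALC fragment the reasoner supports.

#' Negation normal form
#'
#' Pushes negation inward (De Morgan, quantifier duality, double negation)
#' until it stands only directly above atomic names. Logically equivalent to
#' the input and idempotent. Cardinality, nominal and self restrictions are
#' outside the supported fragment and raise an error naming the construct.
#'
#' @param expr a `bao_concept`.
#' @return a `bao_concept` in NNF.
#' @export
to_nnf <- function(expr) {
  nnf <- function(e, neg) {
    if (e$kind %in% UNSUPPORTED_KINDS) stop_unsupported(e$kind)
    switch(e$kind,
      atomic = if (neg) ce_not(e) else e,
      top = if (neg) ce_bottom() else ce_top(),
      bottom = if (neg) ce_top() else ce_bottom(),
      not = nnf(e$arg, !neg),
      and = {
        args <- lapply(e$args, nnf, neg = neg)
        if (neg) ce_or_list(args) else ce_and_list(args)
      },
      or = {
        args <- lapply(e$args, nnf, neg = neg)
        if (neg) ce_and_list(args) else ce_or_list(args)
      },
      some = if (neg) ce_only(e$role, nnf(e$filler, TRUE))
             else ce_some(e$role, nnf(e$filler, FALSE)),
      only = if (neg) ce_some(e$role, nnf(e$filler, TRUE))
             else ce_only(e$role, nnf(e$filler, FALSE)))
  }
  nnf(expr, FALSE)
}

# Expand an equivalence/disjointness into its constituent GCIs.
tbox_to_gcis <- function(axioms) {
  gcis <- list()
  add <- function(sub, sup) gcis[[length(gcis) + 1L]] <<- list(sub = sub, sup = sup)
  for (ax in axioms) {
    switch(ax$kind,
      subclass = add(ax$sub, ax$sup),
      equivalent = {
        es <- ax$exprs
        for (i in seq_along(es)[-1L]) {
          add(es[[1L]], es[[i]])
          add(es[[i]], es[[1L]])
        }
      },
      disjoint = {
        es <- ax$exprs
        for (i in seq_len(length(es) - 1L))
          for (j in seq(i + 1L, length(es)))
            add(ce_and(es[[i]], es[[j]]), ce_bottom())
      },
      stop(sprintf("internalize: not a class axiom: %s", ax$kind),
           call. = FALSE))
  }
  gcis
}

#' Internalize a TBox into one global concept
#'
#' Turns every general class inclusion C subClassOf D of the given class
#' axioms into the disjunction (not C or D) and returns the NNF of their
#' conjunction: a concept every element of every model must satisfy.
#' Equivalences expand into two inclusions, disjointness into pairwise
#' inclusions with bottom on the right. The empty TBox internalizes to Top.
#'
#' @param tbox_axioms list of class axioms (subclass / equivalent / disjoint).
#' @return a `bao_concept` in NNF.
#' @export
internalize <- function(tbox_axioms) {
  gcis <- tbox_to_gcis(tbox_axioms)
  if (length(gcis) == 0L) return(ce_top())
  to_nnf(ce_and_list(lapply(gcis, function(g)
    ce_or(ce_not(g$sub), g$sup))))
}
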