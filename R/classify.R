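# Classification: the full entailed subsumption preorder over named classes,
# reduced to a direct (transitively reduced) hierarchy with equivalence
# groups and satisfiability flags. Classes are processed in lexicographic
# IRI order; told subsumers are seeded first and transitivity prunes tableau
# calls, so results are reproducible and reasonably cheap.

told_subsumption_closure <- function(kb, classes) {
  n <- length(classes)
  idx <- stats::setNames(seq_len(n), classes)
  m <- diag(TRUE, n)
  add <- function(sub, sup) {
    if (sub$kind == "atomic" && sup$kind == "atomic" &&
        sub$name %in% classes && sup$name %in% classes)
      m[idx[[sub$name]], idx[[sup$name]]] <<- TRUE
  }
  for (ax in tbox(kb)) {
    if (ax$kind == "subclass") add(ax$sub, ax$sup)
    if (ax$kind == "equivalent")
      for (i in seq_along(ax$exprs))
        for (j in seq_along(ax$exprs))
          if (i != j) add(ax$exprs[[i]], ax$exprs[[j]])
  }
  # Warshall closure
  for (k in seq_len(n)) m <- m | (m[, k] %o% m[k, ])
  m
}

#' Compute the inferred class hierarchy
#'
#' Checks global consistency, tests satisfiability of every named class,
#' computes all pairwise entailed subsumptions (told subsumptions and
#' transitivity prune tableau calls), groups mutually subsuming classes into
#' equivalence groups (unsatisfiable classes join `owl:Nothing`) and returns
#' the transitive reduction as direct superclass links under `owl:Thing`.
#'
#' @param kb a `bao_ontology`.
#' @param node_cap see [is_satisfiable()].
#' @return a `bao_hierarchy`: list with `classes`, `direct_supers` (named
#'   list), `equivalents` (list of groups), `satisfiable` (named logical)
#'   and the full `subsumes` matrix (`subsumes[i, j]`: class i is subsumed
#'   by class j).
#' @export
classify <- function(kb, node_cap = 50000L) {
  ctx <- compile_kb(kb)
  if (!sat_ctx(ctx, NULL, node_cap)$satisfiable)
    stop("knowledge base is inconsistent: every class would be entailed ",
         "under owl:Nothing", call. = FALSE)
  classes <- sort(named_classes(kb), method = "radix")
  n <- length(classes)
  sat <- vapply(classes, function(cl)
    sat_ctx(ctx, ce_atomic(cl), node_cap)$satisfiable, NA)

  m <- matrix(NA, n, n, dimnames = list(classes, classes))
  diag(m) <- TRUE
  told <- if (n) told_subsumption_closure(kb, classes) else m
  m[told] <- TRUE
  for (i in seq_len(n)) if (!sat[[i]]) m[i, ] <- TRUE

  propagate <- function(m) {
    # positive transitivity to fixed point over the known entries
    repeat {
      changed <- FALSE
      known <- which(m == TRUE, arr.ind = TRUE)
      for (r in seq_len(nrow(known))) {
        i <- known[r, 1L]; j <- known[r, 2L]
        upd <- which(m[j, ] == TRUE & is.na(m[i, ]))
        if (length(upd)) { m[i, upd] <- TRUE; changed <- TRUE }
      }
      if (!changed) return(m)
    }
  }
  m <- propagate(m)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!is.na(m[i, j])) next
      m[i, j] <- subsumed_ctx(ctx, ce_atomic(classes[[i]]),
                              ce_atomic(classes[[j]]), node_cap)
      if (m[i, j]) m <- propagate(m)
    }
  }
  mode(m) <- "logical"

  # equivalence groups
  group_id <- integer(n)
  groups <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      rep <- groups[[g]][[1L]]
      ri <- match(rep, classes)
      if (m[i, ri] && m[ri, i]) {
        groups[[g]] <- c(groups[[g]], classes[[i]])
        group_id[[i]] <- g
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- classes[[i]]
      group_id[[i]] <- length(groups)
    }
  }
  unsat_groups <- unique(group_id[!sat])

  # group-level strict order and transitive reduction
  ng <- length(groups)
  gsub <- matrix(FALSE, ng, ng)
  for (a in seq_len(ng))
    for (b in seq_len(ng))
      if (a != b) {
        ia <- match(groups[[a]][[1L]], classes)
        ib <- match(groups[[b]][[1L]], classes)
        gsub[a, b] <- m[ia, ib] && !m[ib, ia]
      }
  direct <- gsub
  for (a in seq_len(ng))
    for (b in seq_len(ng))
      if (direct[a, b])
        for (k in seq_len(ng))
          if (k != a && k != b && gsub[a, k] && gsub[k, b])
            direct[a, b] <- FALSE

  direct_supers <- stats::setNames(vector("list", n), classes)
  for (i in seq_len(n)) {
    g <- group_id[[i]]
    if (g %in% unsat_groups) {
      sups <- BOTTOM_IRI
    } else {
      sups <- sort(unlist(groups[which(direct[g, ])])) %||% character()
      sups <- setdiff(sups, classes[!sat])
      if (!length(sups)) sups <- TOP_IRI
    }
    direct_supers[[classes[[i]]]] <- sups
  }

  equivalents <- lapply(groups, function(g) sort(unique(unlist(g))))
  if (length(unsat_groups)) {
    bottom_members <- sort(unique(c(BOTTOM_IRI,
                                    unlist(groups[unsat_groups]))))
    equivalents <- c(equivalents[-unsat_groups], list(bottom_members))
  }

  structure(list(classes = classes, direct_supers = direct_supers,
                 equivalents = equivalents,
                 satisfiable = stats::setNames(sat, classes),
                 subsumes = m),
            class = "bao_hierarchy")
}

#' @export
print.bao_hierarchy <- function(x, ...) {
  cat("<inferred hierarchy>", length(x$classes), "named classes,",
      length(x$equivalents), "equivalence groups,",
      sum(!x$satisfiable), "unsatisfiable\n")
  invisible(x)
}

#' Direct subclasses of a class in an inferred hierarchy
#'
#' @param hierarchy a `bao_hierarchy` from [classify()].
#' @param iri a class IRI (`owl:Thing` lists the hierarchy roots).
#' @return sorted character vector of class IRIs whose direct superclasses
#'   include `iri`.
#' @export
direct_subclasses <- function(hierarchy, iri) {
  sort(names(Filter(function(s) iri %in% s, hierarchy$direct_supers)))
}

#' Is a subsumption entailed according to a computed hierarchy?
#' @param hierarchy a `bao_hierarchy`.
#' @param sub,sup class IRIs present in the hierarchy.
#' @return logical.
#' @export
is_subsumed <- function(hierarchy, sub, sup) {
  if (sup == TOP_IRI) return(TRUE)
  if (sub == BOTTOM_IRI) return(TRUE)
  hierarchy$subsumes[sub, sup]
}
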