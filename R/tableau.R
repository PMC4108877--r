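# Tableau decision procedure for ALC with atomic role hierarchies.
#
# Preprocessing: axioms with an atomic left-hand side are absorbed (lazy
# unfolding) — SubClassOf(A, C) fires when A enters a node label; a single
# acyclic EquivalentClasses(A, C) definition fires in both polarities and is
# repaired into the exported model by re-evaluating A's extension from its
# definition. All remaining general inclusions are internalized into one
# global NNF concept added to every node label.
#
# The procedure itself works on label sets. Named individuals (and the query
# root) form a small graph over the asserted role edges, expanded by
# saturation, boolean constraint propagation and binary semantic branching.
# Existential successors are never materialized during the decision: each
# one reduces to an independent label-set satisfiability problem (sound
# because the fragment has no inverse roles or nominals), decided by a
# recursive DFS with ancestor subset blocking for termination and a
# per-knowledge-base memo of label-set verdicts — unsatisfiable verdicts are
# absolute and always cached, satisfiable verdicts are cached once every
# blocking loop they relied on is discharged. Witness models are
# reconstructed afterwards from the memoized decisions, so every
# satisfiable verdict still exports a finite model that verify_model
# accepts.

compile_kb <- function(kb) {
  for (ax in kb$axioms)
    if (ax$kind == "role_characteristic")
      stop_unsupported(paste0("role characteristic '", ax$characteristic, "'"))

  sig <- signature_of(kb)

  # reflexive-transitive closure of the told role hierarchy
  sub_edges <- axioms_of_kind(kb, "subrole")
  roles <- sort(unique(c(sig$roles,
                         vapply(sub_edges, `[[`, "", "sub"),
                         vapply(sub_edges, `[[`, "", "sup"))))
  supers <- stats::setNames(lapply(roles, function(r) r), roles)
  repeat {
    changed <- FALSE
    for (e in sub_edges) {
      new <- union(supers[[e$sub]], supers[[e$sup]])
      if (length(new) > length(supers[[e$sub]])) {
        supers[[e$sub]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # absorption split
  class_axioms <- tbox(kb)
  unfold_pos <- new.env(parent = emptyenv())
  unfold_neg <- new.env(parent = emptyenv())
  general <- list()
  add_unfold <- function(envir, name, concept) {
    cur <- envir[[name]]
    if (is.null(cur)) cur <- list()
    strs <- vapply(cur, ce_str, "")
    if (!(ce_str(concept) %in% strs))
      assign(name, c(cur, list(concept)), envir = envir)
  }

  lhs_count <- table(unlist(lapply(class_axioms, function(ax) {
    if (ax$kind == "subclass" && ax$sub$kind == "atomic") return(ax$sub$name)
    if (ax$kind == "equivalent")
      return(vapply(Filter(function(e) e$kind == "atomic", ax$exprs),
                    `[[`, "", "name"))
    character()
  })))

  candidate_defs <- list()
  for (ax in class_axioms) {
    if (ax$kind == "subclass" && ax$sub$kind == "atomic" &&
        !(ax$sub$name %in% c(TOP_IRI, BOTTOM_IRI))) {
      add_unfold(unfold_pos, ax$sub$name, to_nnf(ax$sup))
    } else if (ax$kind == "equivalent" && length(ax$exprs) == 2L &&
               any(vapply(ax$exprs, function(e) e$kind == "atomic", NA))) {
      atom_idx <- which(vapply(ax$exprs, function(e) e$kind == "atomic",
                               NA))[1L]
      a <- ax$exprs[[atom_idx]]$name
      def <- ax$exprs[[if (atom_idx == 1L) 2L else 1L]]
      add_unfold(unfold_pos, a, to_nnf(def))
      if (lhs_count[[a]] == 1L && !(a %in% names(candidate_defs))) {
        candidate_defs[[a]] <- def
      } else {
        general[[length(general) + 1L]] <- ax_subclass(def, ce_atomic(a))
      }
    } else {
      general[[length(general) + 1L]] <- ax
    }
  }

  # keep only acyclic definitions; cyclic ones fall back to internalization
  dep_names <- function(def) intersect(signature_of(list(
    ax_subclass(def, ce_top())))$classes, names(candidate_defs))
  ordered <- character()
  remaining <- names(candidate_defs)
  repeat {
    ready <- remaining[vapply(remaining, function(a)
      all(dep_names(candidate_defs[[a]]) %in% ordered), NA)]
    if (!length(ready)) break
    ordered <- c(ordered, sort(ready))
    remaining <- setdiff(remaining, ready)
  }
  for (a in remaining) {
    general[[length(general) + 1L]] <-
      ax_subclass(candidate_defs[[a]], ce_atomic(a))
    candidate_defs[[a]] <- NULL
  }
  for (a in names(candidate_defs))
    add_unfold(unfold_neg, a, to_nnf(ce_not(candidate_defs[[a]])))

  g <- internalize(general)
  base <- if (g$kind == "top") list()
          else if (g$kind == "and") g$args else list(g)

  class_asserts <- axioms_of_kind(kb, "class_assertion")
  prop_asserts <- axioms_of_kind(kb, "property_assertion")
  individuals <- sort(unique(c(sig$individuals,
    unlist(lapply(class_asserts, `[[`, "individual")),
    unlist(lapply(prop_asserts, function(a) c(a$subject, a$object))))))

  exprs <- new.env(parent = emptyenv())
  reg <- function(e) { assign(ce_str(e), e, envir = exprs); ce_str(e) }
  base_strs <- vapply(base, reg, "")

  list(sig = sig, role_supers = supers, unfold_pos = unfold_pos,
       unfold_neg = unfold_neg, defined = candidate_defs,
       defined_order = intersect(ordered, names(candidate_defs)),
       base = base_strs, exprs = exprs, reg = reg,
       class_asserts = class_asserts, prop_asserts = prop_asserts,
       individuals = individuals,
       memo = new.env(parent = emptyenv()),
       work = new.env(parent = emptyenv()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

neg_str <- function(atom) paste0("(not ", atom, ")")

label_has_clash <- function(label) {
  if (BOTTOM_IRI %in% label) return(TRUE)
  atoms <- label[!startsWith(label, "(")]
  length(atoms) && any(neg_str(atoms) %in% label)
}

# propositional saturation of one label: conjunctions and lazy unfolding
prop_saturate <- function(ctx, label) {
  i <- 1L
  while (i <= length(label)) {
    e <- ctx$exprs[[label[[i]]]]
    adds <- NULL
    if (e$kind == "and") {
      adds <- vapply(e$args, ctx$reg, "")
    } else if (e$kind == "atomic") {
      u <- ctx$unfold_pos[[e$name]]
      if (!is.null(u)) adds <- vapply(u, ctx$reg, "")
    } else if (e$kind == "not" && e$arg$kind == "atomic") {
      u <- ctx$unfold_neg[[e$arg$name]]
      if (!is.null(u)) adds <- vapply(u, ctx$reg, "")
    }
    if (!is.null(adds)) {
      new <- setdiff(adds, label)
      if (length(new)) label <- c(label, new)
    }
    i <- i + 1L
  }
  label
}

# successor seed for (some role filler) under a node label
succ_seed <- function(ctx, label, role, filler_str) {
  seed <- c(filler_str, ctx$base)
  for (s in label) {
    e <- ctx$exprs[[s]]
    if (e$kind == "only" && e$role %in% ctx$role_supers[[role]])
      seed <- c(seed, ctx$reg(e$filler))
  }
  unique(seed)
}

tick_work <- function(ctx, node_cap) {
  n <- (ctx$work$n %||% 0L) + 1L
  ctx$work$n <- n
  if (n > node_cap)
    stop("resource-limit: tableau node cap exceeded", call. = FALSE)
}

# Decide satisfiability of a label set w.r.t. the compiled KB.
# path: list of closed ancestor labels (for subset blocking).
# Returns list(sat, mindep): mindep is the shallowest path index a blocking
# hit relied on (Inf if none undischarged); unsat verdicts are absolute and
# memoized, sat verdicts are memoized once loop-free.
sat_label <- function(ctx, label, path, node_cap) {
  tick_work(ctx, node_cap)
  label <- prop_saturate(ctx, sort(unique(label)))
  if (label_has_clash(label)) return(list(sat = FALSE, mindep = Inf))

  # disjunctions: BCP, then binary semantic branching on the first open one
  repeat {
    progressed <- FALSE
    for (s in label) {
      e <- ctx$exprs[[s]]
      if (e$kind != "or") next
      strs <- vapply(e$args, ce_str, "")
      if (any(strs %in% label)) next
      open <- e$args[!vapply(e$args, function(a)
        ce_str(to_nnf(ce_not(a))) %in% label, NA)]
      if (length(open) == 0L) return(list(sat = FALSE, mindep = Inf))
      if (length(open) == 1L) {
        label <- prop_saturate(ctx, c(label, ctx$reg(open[[1L]])))
        if (label_has_clash(label)) return(list(sat = FALSE, mindep = Inf))
        progressed <- TRUE
        break
      }
      d <- open[[1L]]
      r1 <- sat_label(ctx, c(label, ctx$reg(d)), path, node_cap)
      if (r1$sat) return(r1)
      return(sat_label(ctx, c(label, ctx$reg(to_nnf(ce_not(d)))), path,
                       node_cap))
    }
    if (!progressed) break
  }

  label <- sort(label)
  key <- paste(label, collapse = "\x1f")
  hit <- ctx$memo[[key]]
  if (!is.null(hit)) return(list(sat = hit, mindep = Inf))

  # ancestor subset blocking
  for (i in seq_along(path))
    if (all(label %in% path[[i]]))
      return(list(sat = TRUE, mindep = i))

  depth <- length(path) + 1L
  path2 <- c(path, list(label))
  mindep <- Inf
  for (s in label) {
    e <- ctx$exprs[[s]]
    if (e$kind != "some") next
    seed <- succ_seed(ctx, label, e$role, ctx$reg(e$filler))
    res <- sat_label(ctx, seed, path2, node_cap)
    if (!res$sat) {
      ctx$memo[[key]] <- FALSE
      return(list(sat = FALSE, mindep = Inf))
    }
    mindep <- min(mindep, res$mindep)
  }
  if (mindep >= depth) {       # all blocking loops closed within this subtree
    ctx$memo[[key]] <- TRUE
    mindep <- Inf
  }
  list(sat = TRUE, mindep = mindep)
}

# ---- named-individual graph ---------------------------------------------

init_named <- function(ctx, query_expr = NULL, extra_asserts = list(),
                       restrict_to = NULL) {
  individuals <- if (is.null(restrict_to)) ctx$individuals
                 else intersect(ctx$individuals, restrict_to)
  class_asserts <- ctx$class_asserts
  prop_asserts <- ctx$prop_asserts
  if (!is.null(restrict_to)) {
    class_asserts <- Filter(function(a) a$individual %in% individuals,
                            class_asserts)
    prop_asserts <- Filter(function(a)
      a$subject %in% individuals && a$object %in% individuals, prop_asserts)
  }
  labels <- list()
  node_of <- integer()
  names(node_of) <- character()
  for (ind in individuals) {
    labels[[length(labels) + 1L]] <- ctx$base
    node_of[[ind]] <- length(labels)
  }
  edges <- list(from = integer(), to = integer(), role = character())
  for (ax in prop_asserts) {
    edges$from <- c(edges$from, node_of[[ax$subject]])
    edges$to <- c(edges$to, node_of[[ax$object]])
    edges$role <- c(edges$role, ax$role)
  }
  anon_root <- NA_integer_
  if (!is.null(query_expr)) {
    labels[[length(labels) + 1L]] <- unique(c(ctx$reg(to_nnf(query_expr)),
                                              ctx$base))
    anon_root <- length(labels)
  }
  if (length(labels) == 0L) {
    labels[[1L]] <- ctx$base
    anon_root <- 1L
  }
  for (ax in c(class_asserts, extra_asserts)) {
    n <- node_of[[ax$individual]]
    labels[[n]] <- unique(c(labels[[n]], ctx$reg(to_nnf(ax$expr))))
  }
  list(labels = labels, edges = edges, node_of = node_of,
       anon_root = anon_root)
}

named_saturate <- function(ctx, state) {
  repeat {
    changed <- FALSE
    for (i in seq_along(state$labels)) {
      new <- prop_saturate(ctx, state$labels[[i]])
      if (length(new) > length(state$labels[[i]])) {
        state$labels[[i]] <- new
        changed <- TRUE
      }
      for (s in state$labels[[i]]) {
        e <- ctx$exprs[[s]]
        if (e$kind != "only") next
        sel <- which(state$edges$from == i)
        for (k in sel) {
          if (!(e$role %in% ctx$role_supers[[state$edges$role[[k]]]])) next
          tgt <- state$edges$to[[k]]
          fs <- ctx$reg(e$filler)
          if (!(fs %in% state$labels[[tgt]])) {
            state$labels[[tgt]] <- c(state$labels[[tgt]], fs)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) return(state)
  }
}

# expand the named graph; returns NULL (inconsistent) or the final state
# with a list of anonymous successor witnesses per node
expand_named <- function(ctx, state, node_cap) {
  tick_work(ctx, node_cap)
  state <- named_saturate(ctx, state)
  if (any(vapply(state$labels, label_has_clash, NA))) return(NULL)

  # BCP / binary semantic branching across all named nodes
  for (i in seq_along(state$labels)) {
    for (s in state$labels[[i]]) {
      e <- ctx$exprs[[s]]
      if (e$kind != "or") next
      strs <- vapply(e$args, ce_str, "")
      if (any(strs %in% state$labels[[i]])) next
      open <- e$args[!vapply(e$args, function(a)
        ce_str(to_nnf(ce_not(a))) %in% state$labels[[i]], NA)]
      if (length(open) == 0L) return(NULL)
      st1 <- state
      st1$labels[[i]] <- c(st1$labels[[i]], ctx$reg(open[[1L]]))
      if (length(open) == 1L) return(expand_named(ctx, st1, node_cap))
      res <- expand_named(ctx, st1, node_cap)
      if (!is.null(res)) return(res)
      st2 <- state
      st2$labels[[i]] <- c(st2$labels[[i]],
                           ctx$reg(to_nnf(ce_not(open[[1L]]))))
      return(expand_named(ctx, st2, node_cap))
    }
  }

  # modal step: every unsatisfied existential spawns an independent
  # label-set problem
  witnesses <- rep(list(list()), length(state$labels))
  for (i in seq_along(state$labels)) {
    for (s in state$labels[[i]]) {
      e <- ctx$exprs[[s]]
      if (e$kind != "some") next
      sel <- which(state$edges$from == i)
      fs <- ctx$reg(e$filler)
      satisfied <- any(vapply(sel, function(k)
        e$role %in% ctx$role_supers[[state$edges$role[[k]]]] &&
          fs %in% state$labels[[state$edges$to[[k]]]], NA))
      if (satisfied) next
      seed <- succ_seed(ctx, state$labels[[i]], e$role, fs)
      res <- sat_label(ctx, seed, list(), node_cap)
      if (!res$sat) return(NULL)
      witnesses[[i]] <- c(witnesses[[i]],
                          list(list(role = e$role, seed = seed)))
    }
  }
  state$witnesses <- witnesses
  state
}

# ---- model reconstruction ------------------------------------------------

new_model_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$labels <- list()
  env$edges <- list(from = integer(), to = integer(), role = character())
  env
}

mb_node <- function(mb, label) {
  mb$n <- mb$n + 1L
  mb$labels[[mb$n]] <- label
  mb$n
}

mb_edge <- function(mb, from, to, role) {
  mb$edges$from <- c(mb$edges$from, from)
  mb$edges$to <- c(mb$edges$to, to)
  mb$edges$role <- c(mb$edges$role, role)
}

# deterministically re-derive the closed label of a satisfiable seed
closed_label <- function(ctx, label, path, node_cap) {
  label <- prop_saturate(ctx, sort(unique(label)))
  repeat {
    progressed <- FALSE
    for (s in label) {
      e <- ctx$exprs[[s]]
      if (e$kind != "or") next
      strs <- vapply(e$args, ce_str, "")
      if (any(strs %in% label)) next
      open <- e$args[!vapply(e$args, function(a)
        ce_str(to_nnf(ce_not(a))) %in% label, NA)]
      d <- if (length(open) == 1L) open[[1L]]
      else if (sat_label(ctx, c(label, ctx$reg(open[[1L]])), path,
                         node_cap)$sat) open[[1L]]
      else to_nnf(ce_not(open[[1L]]))
      label <- prop_saturate(ctx, c(label, ctx$reg(d)))
      progressed <- TRUE
      break
    }
    if (!progressed) return(sort(label))
  }
}

build_witness <- function(ctx, mb, seed, path_labels, path_ids, node_cap) {
  label <- closed_label(ctx, seed, path_labels, node_cap)
  for (i in seq_along(path_labels))
    if (all(label %in% path_labels[[i]])) return(path_ids[[i]])
  id <- mb_node(mb, label)
  for (s in label) {
    e <- ctx$exprs[[s]]
    if (e$kind != "some") next
    child_seed <- succ_seed(ctx, label, e$role, ctx$reg(e$filler))
    child <- build_witness(ctx, mb, child_seed,
                           c(path_labels, list(label)), c(path_ids, id),
                           node_cap)
    mb_edge(mb, id, child, e$role)
  }
  id
}

export_model <- function(ctx, state, node_cap) {
  mb <- new_model_builder()
  named_ids <- integer(length(state$labels))
  for (i in seq_along(state$labels))
    named_ids[[i]] <- mb_node(mb, sort(state$labels[[i]]))
  if (length(state$edges$from))
    for (k in seq_along(state$edges$from))
      mb_edge(mb, named_ids[[state$edges$from[[k]]]],
              named_ids[[state$edges$to[[k]]]], state$edges$role[[k]])
  for (i in seq_along(state$labels))
    for (w in state$witnesses[[i]]) {
      child <- build_witness(ctx, mb, w$seed,
                             list(sort(state$labels[[i]])),
                             named_ids[[i]], node_cap)
      mb_edge(mb, named_ids[[i]], child, w$role)
    }

  class_ext <- list()
  all_atoms <- unique(unlist(lapply(mb$labels, function(l)
    l[!startsWith(l, "(")])))
  for (cl in unique(c(ctx$sig$classes,
                      setdiff(all_atoms, c(TOP_IRI, BOTTOM_IRI)))))
    class_ext[[cl]] <- which(vapply(mb$labels, function(l) cl %in% l, NA))
  role_ext <- list()
  if (length(mb$edges$from))
    for (k in seq_along(mb$edges$from))
      for (r in ctx$role_supers[[mb$edges$role[[k]]]])
        role_ext[[r]] <- rbind(role_ext[[r]],
                               c(mb$edges$from[[k]], mb$edges$to[[k]]))
  ind_map <- integer()
  if (length(state$node_of))
    ind_map <- stats::setNames(named_ids[state$node_of],
                               names(state$node_of))
  interp <- interpretation(mb$n, class_ext, role_ext, ind_map)
  # repair defined classes: extensions re-evaluated from the definitions in
  # dependency order so asserted equivalences hold in the exported model
  for (a in ctx$defined_order) {
    interp$class_ext[[a]] <-
      sort(unique(c(interp$class_ext[[a]] %||% integer(),
                    eval_concept(ctx$defined[[a]], interp))))
  }
  interp
}

# ---- public operations ---------------------------------------------------

sat_ctx <- function(ctx, expr = NULL, node_cap = 50000L,
                    extra_asserts = list(), restrict_to = NULL,
                    want_model = TRUE) {
  ctx$work$n <- 0L
  state <- init_named(ctx, expr, extra_asserts, restrict_to)
  res <- expand_named(ctx, state, node_cap)
  out <- if (is.null(res)) list(satisfiable = FALSE, model = NULL)
         else list(satisfiable = TRUE,
                   model = if (want_model) export_model(ctx, res, node_cap))
  class(out) <- "bao_sat_result"
  out
}

subsumed_ctx <- function(ctx, sub, sup, node_cap = 50000L) {
  q <- ce_and(sub, ce_not(sup))
  if (q$kind == "bottom") return(TRUE)
  !sat_ctx(ctx, to_nnf(q), node_cap, want_model = FALSE)$satisfiable
}

#' Concept satisfiability with respect to a knowledge base
#'
#' Decides whether `expr` is satisfiable w.r.t. the TBox, role hierarchy and
#' ABox of `kb` by a tableau with lazy unfolding of absorbed axioms,
#' internalization of residual general inclusions, and ancestor subset
#' blocking. Sound and complete for ALC with atomic role hierarchies; any
#' other construct raises an unsupported-construct error. On success a
#' finite model is exported that [verify_model()] accepts.
#'
#' @param kb a `bao_ontology` (already merged over its import closure).
#' @param expr a `bao_concept`, or `NULL` to test global consistency.
#' @param node_cap abort with a resource-limit error beyond this much
#'   tableau work.
#' @return a `bao_sat_result`: list with `satisfiable` and (if satisfiable)
#'   `model`.
#' @export
is_satisfiable <- function(kb, expr = NULL, node_cap = 50000L) {
  if (!is.null(expr)) check_supported(expr)
  sat_ctx(compile_kb(kb), expr, node_cap)
}

#' @export
print.bao_sat_result <- function(x, ...) {
  cat("<satisfiability result>", if (x$satisfiable) "satisfiable"
      else "unsatisfiable", "\n")
  invisible(x)
}

#' Entailed subsumption between two class expressions
#'
#' Reduces subsumption to unsatisfiability: `sub` is subsumed by `sup` iff
#' `sub and not sup` has no model w.r.t. the knowledge base.
#'
#' @param kb a `bao_ontology`.
#' @param sub,sup class expressions (or IRI strings, taken as atomic
#'   classes).
#' @param node_cap see [is_satisfiable()].
#' @return logical.
#' @export
check_subsumption <- function(kb, sub, sup, node_cap = 50000L) {
  if (is.character(sub)) sub <- ce_atomic(sub)
  if (is.character(sup)) sup <- ce_atomic(sup)
  check_supported(sub); check_supported(sup)
  subsumed_ctx(compile_kb(kb), sub, sup, node_cap)
}

#' Global consistency of a knowledge base
#' @param kb a `bao_ontology`.
#' @param node_cap see [is_satisfiable()].
#' @return logical.
#' @export
kb_is_consistent <- function(kb, node_cap = 50000L) {
  sat_ctx(compile_kb(kb), NULL, node_cap, want_model = FALSE)$satisfiable
}

declared_individuals <- function(kb) {
  sort(unique(c(signature_of(kb)$individuals,
                vapply(Filter(function(a)
                  a$kind == "declaration" &&
                    a$entity_kind == "NamedIndividual",
                  kb$axioms), `[[`, "", "iri"))))
}

#' Instance checking
#'
#' `individual` is an instance of `expr` iff adding the complement assertion
#' makes the knowledge base inconsistent.
#'
#' @param kb a `bao_ontology`.
#' @param individual a declared individual IRI.
#' @param expr a class expression (or IRI string).
#' @param node_cap see [is_satisfiable()].
#' @return logical.
#' @export
check_instance <- function(kb, individual, expr, node_cap = 50000L) {
  if (is.character(expr)) expr <- ce_atomic(expr)
  check_supported(expr)
  if (!(individual %in% declared_individuals(kb)))
    stop(sprintf("unknown individual: %s", individual), call. = FALSE)
  ctx <- compile_kb(kb)
  if (!sat_ctx(ctx, NULL, node_cap, want_model = FALSE)$satisfiable)
    return(TRUE)
  check_instance_ctx(ctx, individual, expr, node_cap)
}

# assumes the knowledge base as a whole is consistent (checked by callers);
# the check is then restricted to the individuals forward-reachable from the
# queried one, which is sound and complete without inverse roles or
# nominals
check_instance_ctx <- function(ctx, individual, expr, node_cap = 50000L) {
  reach <- individual
  repeat {
    nxt <- unique(unlist(lapply(ctx$prop_asserts, function(a)
      if (a$subject %in% reach) a$object else NULL)))
    nxt <- setdiff(nxt, reach)
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  !sat_ctx(ctx, NULL, node_cap,
           extra_asserts = list(
             ax_class_assertion(to_nnf(ce_not(expr)), individual)),
           restrict_to = reach, want_model = FALSE)$satisfiable
}

#' Instance retrieval
#'
#' All declared individuals entailed to be instances of `expr`.
#'
#' @param kb a `bao_ontology`.
#' @param expr a class expression (or IRI string).
#' @param node_cap see [is_satisfiable()].
#' @return sorted character vector of individual IRIs.
#' @export
retrieve_instances <- function(kb, expr, node_cap = 50000L) {
  if (is.character(expr)) expr <- ce_atomic(expr)
  check_supported(expr)
  ctx <- compile_kb(kb)
  inds <- declared_individuals(kb)
  if (!sat_ctx(ctx, NULL, node_cap, want_model = FALSE)$satisfiable)
    return(inds)
  inds[vapply(inds, function(i)
    check_instance_ctx(ctx, i, expr, node_cap), NA)]
}
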