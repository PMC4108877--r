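# Independent semantic oracle for the tableau: exhaustive search for finite
# models over small domains. Partial structures are kept as interval (lower
# and upper bound) bitmask extensions so the branch-and-prune DFS can discard
# assignments that already violate an axiom — the search stays exhaustive:
# pruned branches provably contain no model. Class and role extensions are
# integer bitmasks over the (at most 3-element) domain, which keeps the inner
# loop allocation-free. Plus a small random-ontology generator used to
# exercise the reasoner property-style.

# eval over a partial structure; returns c(lo, hi) bitmasks
eval_interval <- function(e, st) {
  d <- st$d
  full <- st$full
  switch(e$kind,
    atomic = {
      k <- match(e$name, st$class_names)
      if (is.na(k)) c(0L, full) else c(st$lo_c[[k]], st$hi_c[[k]])
    },
    top = c(full, full),
    bottom = c(0L, 0L),
    not = {
      v <- eval_interval(e$arg, st)
      c(bitwAnd(full, bitwNot(v[[2L]])), bitwAnd(full, bitwNot(v[[1L]])))
    },
    and = {
      lo <- full; hi <- full
      for (a in e$args) {
        v <- eval_interval(a, st)
        lo <- bitwAnd(lo, v[[1L]]); hi <- bitwAnd(hi, v[[2L]])
      }
      c(lo, hi)
    },
    or = {
      lo <- 0L; hi <- 0L
      for (a in e$args) {
        v <- eval_interval(a, st)
        lo <- bitwOr(lo, v[[1L]]); hi <- bitwOr(hi, v[[2L]])
      }
      c(lo, hi)
    },
    some = {
      v <- eval_interval(e$filler, st)
      k <- match(e$role, st$role_names)
      lo <- 0L; hi <- 0L
      for (el in seq_len(d)) {
        rlo <- if (is.na(k)) 0L else st$lo_r[[k]][[el]]
        rhi <- if (is.na(k)) full else st$hi_r[[k]][[el]]
        if (bitwAnd(rlo, v[[1L]]) != 0L) lo <- bitwOr(lo, bitwShiftL(1L, el - 1L))
        if (bitwAnd(rhi, v[[2L]]) != 0L) hi <- bitwOr(hi, bitwShiftL(1L, el - 1L))
      }
      c(lo, hi)
    },
    only = {
      v <- eval_interval(e$filler, st)
      k <- match(e$role, st$role_names)
      nlo <- bitwAnd(full, bitwNot(v[[1L]]))
      nhi <- bitwAnd(full, bitwNot(v[[2L]]))
      lo <- 0L; hi <- 0L
      for (el in seq_len(d)) {
        rlo <- if (is.na(k)) 0L else st$lo_r[[k]][[el]]
        rhi <- if (is.na(k)) full else st$hi_r[[k]][[el]]
        if (bitwAnd(rhi, nlo) == 0L) lo <- bitwOr(lo, bitwShiftL(1L, el - 1L))
        if (bitwAnd(rlo, nhi) == 0L) hi <- bitwOr(hi, bitwShiftL(1L, el - 1L))
      }
      c(lo, hi)
    },
    stop_unsupported(e$kind))
}

axiom_violated_interval <- function(ax, st) {
  switch(ax$kind,
    subclass = {
      s <- eval_interval(ax$sub, st)
      p <- eval_interval(ax$sup, st)
      bitwAnd(s[[1L]], bitwAnd(st$full, bitwNot(p[[2L]]))) != 0L
    },
    equivalent = {
      vs <- lapply(ax$exprs, eval_interval, st = st)
      for (i in seq_along(vs))
        for (j in seq_along(vs))
          if (i != j &&
              bitwAnd(vs[[i]][[1L]],
                      bitwAnd(st$full, bitwNot(vs[[j]][[2L]]))) != 0L)
            return(TRUE)
      FALSE
    },
    disjoint = {
      vs <- lapply(ax$exprs, eval_interval, st = st)
      for (i in seq_len(length(vs) - 1L))
        for (j in seq(i + 1L, length(vs)))
          if (bitwAnd(vs[[i]][[1L]], vs[[j]][[1L]]) != 0L) return(TRUE)
      FALSE
    },
    subrole = {
      ks <- match(ax$sub, st$role_names)
      kp <- match(ax$sup, st$role_names)
      for (el in seq_len(st$d)) {
        rlo <- if (is.na(ks)) 0L else st$lo_r[[ks]][[el]]
        rhi <- if (is.na(kp)) st$full else st$hi_r[[kp]][[el]]
        if (bitwAnd(rlo, bitwAnd(st$full, bitwNot(rhi))) != 0L) return(TRUE)
      }
      FALSE
    },
    class_assertion = {
      v <- eval_interval(ax$expr, st)
      el <- st$ind_el[[ax$individual]]
      bitwAnd(v[[2L]], bitwShiftL(1L, el - 1L)) == 0L
    },
    property_assertion = {
      k <- match(ax$role, st$role_names)
      if (is.na(k)) return(FALSE)
      a <- st$ind_el[[ax$subject]]
      b <- st$ind_el[[ax$object]]
      bitwAnd(st$hi_r[[k]][[a]], bitwShiftL(1L, b - 1L)) == 0L
    },
    FALSE)
}

axiom_symbols <- function(ax) {
  sig <- signature_of(list(ax))
  c(sig$classes, sig$roles)
}

#' Exhaustive search for a small finite model
#'
#' Searches every interpretation with domain size up to `max_domain` for a
#' model of the knowledge base, using interval (three-valued) evaluation to
#' prune partial assignments that already violate an axiom; the search
#' remains exhaustive because pruned branches provably contain no model.
#' Independent of the tableau; used as the completeness oracle in the test
#' suite.
#'
#' @param kb a `bao_ontology` in the supported fragment.
#' @param max_domain largest domain size to try (small, e.g. 3).
#' @return a `bao_interpretation`, or `NULL` if no model with at most
#'   `max_domain` elements exists.
#' @export
find_model_exhaustive <- function(kb, max_domain = 3L) {
  sig <- signature_of(kb)
  axioms <- Filter(function(a)
    a$kind %in% c(TBOX_KINDS, "subrole", "class_assertion",
                  "property_assertion"), kb$axioms)
  ax_syms <- lapply(axioms, axiom_symbols)
  inds <- declared_individuals(kb)
  for (d in seq_len(max_domain)) {
    full <- bitwShiftL(1L, d) - 1L
    ind_maps <- if (length(inds) == 0L) list(integer())
      else {
        grids <- do.call(expand.grid, rep(list(seq_len(d)), length(inds)))
        lapply(seq_len(nrow(grids)), function(r)
          stats::setNames(as.integer(grids[r, ]), inds))
      }
    # variable list: one per class bit, one per role edge bit
    vars <- list()
    for (k in seq_along(sig$classes))
      for (el in seq_len(d))
        vars[[length(vars) + 1L]] <- c(1L, k, el, 0L)
    for (k in seq_along(sig$roles))
      for (el in seq_len(d))
        for (f in seq_len(d))
          vars[[length(vars) + 1L]] <- c(2L, k, el, f)
    for (ind_el in ind_maps) {
      st <- list(d = d, full = full,
                 class_names = sig$classes, role_names = sig$roles,
                 lo_c = rep(0L, length(sig$classes)),
                 hi_c = rep(full, length(sig$classes)),
                 lo_r = rep(list(rep(0L, d)), length(sig$roles)),
                 hi_r = rep(list(rep(full, d)), length(sig$roles)),
                 ind_el = ind_el)
      violated_any <- function(st, syms = NULL) {
        for (i in seq_along(axioms)) {
          if (!is.null(syms) && !any(ax_syms[[i]] %in% syms)) next
          if (axiom_violated_interval(axioms[[i]], st)) return(TRUE)
        }
        FALSE
      }
      if (violated_any(st)) next
      search <- function(v, st) {
        if (v > length(vars)) {
          class_ext <- lapply(seq_along(sig$classes), function(k)
            which(bitwAnd(st$lo_c[[k]], bitwShiftL(1L, seq_len(d) - 1L)) != 0L))
          names(class_ext) <- sig$classes
          role_ext <- lapply(seq_along(sig$roles), function(k) {
            prs <- NULL
            for (el in seq_len(d))
              for (f in seq_len(d))
                if (bitwAnd(st$lo_r[[k]][[el]], bitwShiftL(1L, f - 1L)) != 0L)
                  prs <- rbind(prs, c(el, f))
            if (is.null(prs)) matrix(integer(), ncol = 2L) else prs
          })
          names(role_ext) <- sig$roles
          return(interpretation(d, class_ext, role_ext, ind_el))
        }
        var <- vars[[v]]
        bit <- bitwShiftL(1L, (if (var[[1L]] == 1L) var[[3L]] else var[[4L]]) - 1L)
        for (val in c(FALSE, TRUE)) {
          st2 <- st
          if (var[[1L]] == 1L) {
            if (val) st2$lo_c[[var[[2L]]]] <- bitwOr(st2$lo_c[[var[[2L]]]], bit)
            else st2$hi_c[[var[[2L]]]] <-
              bitwAnd(st2$hi_c[[var[[2L]]]], bitwNot(bit))
            sym <- sig$classes[[var[[2L]]]]
          } else {
            if (val) st2$lo_r[[var[[2L]]]][[var[[3L]]]] <-
              bitwOr(st2$lo_r[[var[[2L]]]][[var[[3L]]]], bit)
            else st2$hi_r[[var[[2L]]]][[var[[3L]]]] <-
              bitwAnd(st2$hi_r[[var[[2L]]]][[var[[3L]]]], bitwNot(bit))
            sym <- sig$roles[[var[[2L]]]]
          }
          if (violated_any(st2, sym)) next
          res <- search(v + 1L, st2)
          if (!is.null(res)) return(res)
        }
        NULL
      }
      res <- search(1L, st)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

random_concept <- function(depth, classes, roles) {
  if (depth <= 0L || stats::runif(1) < 0.35)
    return(ce_atomic(sample(classes, 1L)))
  kind <- sample(c("not", "and", "or", "some", "only"), 1L,
                 prob = c(0.2, 0.25, 0.25, 0.15, 0.15))
  switch(kind,
    not = ce_not(random_concept(depth - 1L, classes, roles)),
    and = ce_and(random_concept(depth - 1L, classes, roles),
                 random_concept(depth - 1L, classes, roles)),
    or = ce_or(random_concept(depth - 1L, classes, roles),
               random_concept(depth - 1L, classes, roles)),
    some = ce_some(sample(roles, 1L),
                   random_concept(depth - 1L, classes, roles)),
    only = ce_only(sample(roles, 1L),
                   random_concept(depth - 1L, classes, roles)))
}

#' Generate a small random ontology
#'
#' Draws a random knowledge base (at most `max_axioms` logical axioms over at
#' most four atomic classes, two roles and expression depth three,
#' occasionally with a tiny ABox) from the current RNG state. Used to
#' exercise the reasoner against the exhaustive model-search oracle.
#'
#' @param max_axioms upper bound on the number of logical axioms.
#' @return a `bao_ontology`.
#' @export
random_ontology <- function(max_axioms = 6L) {
  classes <- c("t:A", "t:B", "t:C", "t:D")[seq_len(sample(2:4, 1L))]
  roles <- c("t:r", "t:s")[seq_len(sample(1:2, 1L))]
  inds <- c("t:i1", "t:i2")
  n_ax <- sample(seq_len(max_axioms), 1L)
  axioms <- lapply(seq_len(n_ax), function(k) {
    kind <- sample(c("subclass", "equivalent", "disjoint", "subrole",
                     "class_assertion", "property_assertion"), 1L,
                   prob = c(0.45, 0.15, 0.1, 0.1, 0.12, 0.08))
    switch(kind,
      subclass = ax_subclass(random_concept(3L, classes, roles),
                             random_concept(3L, classes, roles)),
      equivalent = {
        a1 <- random_concept(2L, classes, roles)
        a2 <- random_concept(2L, classes, roles)
        if (ce_equal(a1, a2)) ax_subclass(a1, a2)
        else ax_equivalent(list(a1, a2))
      },
      disjoint = ax_disjoint(lapply(sample(classes, 2L), ce_atomic)),
      subrole = ax_subrole(sample(roles, 1L), sample(roles, 1L)),
      class_assertion = ax_class_assertion(
        random_concept(2L, classes, roles), sample(inds, 1L)),
      property_assertion = ax_property_assertion(
        sample(roles, 1L), sample(inds, 1L), sample(inds, 1L)))
  })
  ontology("t:random", axioms)
}
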