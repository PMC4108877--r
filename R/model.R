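# Finite interpretations and the direct-semantics model checker. The checker
# evaluates the extended interpretation function over a finite structure and
# serves as the independent oracle for the tableau: every satisfiable verdict
# must come with a model this evaluator accepts.

#' Construct a finite interpretation
#'
#' A finite structure: a nonempty domain 1..n, a class extension map, a role
#' extension map and an individual assignment.
#'
#' @param domain_size number of domain elements (positive integer).
#' @param class_ext named list mapping class IRIs to integer vectors of
#'   domain elements.
#' @param role_ext named list mapping role IRIs to 2-column integer matrices
#'   of (subject, object) element pairs.
#' @param individual_map named integer vector mapping individual IRIs to
#'   domain elements.
#' @return a `bao_interpretation`.
#' @export
interpretation <- function(domain_size, class_ext = list(),
                           role_ext = list(), individual_map = integer()) {
  stopifnot(domain_size >= 1)
  dom <- seq_len(domain_size)
  class_ext <- lapply(class_ext, function(v) sort(unique(as.integer(v))))
  role_ext <- lapply(role_ext, function(m) {
    m <- matrix(as.integer(m), ncol = 2L)
    m[!duplicated(paste(m[, 1L], m[, 2L])), , drop = FALSE]
  })
  stopifnot(all(unlist(class_ext) %in% dom),
            all(unlist(role_ext) %in% dom),
            all(individual_map %in% dom))
  structure(list(domain = dom, class_ext = class_ext, role_ext = role_ext,
                 individual_map = individual_map),
            class = "bao_interpretation")
}

#' @export
print.bao_interpretation <- function(x, ...) {
  cat("<interpretation> |domain| =", length(x$domain),
      "| classes:", length(x$class_ext),
      "| roles:", length(x$role_ext),
      "| individuals:", length(x$individual_map), "\n")
  invisible(x)
}

role_pairs <- function(interp, role) {
  m <- interp$role_ext[[role]]
  if (is.null(m)) matrix(integer(), ncol = 2L) else m
}

#' Evaluate a class expression over a finite interpretation
#'
#' Computes the extension of a (reasoner-supported) class expression in the
#' given structure by direct application of the semantics.
#'
#' @param expr a `bao_concept` in the ALC fragment.
#' @param interp a `bao_interpretation`.
#' @return sorted integer vector of domain elements.
#' @export
eval_concept <- function(expr, interp) {
  dom <- interp$domain
  ev <- function(e) {
    switch(e$kind,
      atomic = {
        ext <- interp$class_ext[[e$name]]
        if (is.null(ext)) integer() else ext
      },
      top = dom,
      bottom = integer(),
      not = setdiff(dom, ev(e$arg)),
      and = Reduce(intersect, lapply(e$args, ev)),
      or = sort(unique(unlist(lapply(e$args, ev)))),
      some = {
        filler <- ev(e$filler)
        m <- role_pairs(interp, e$role)
        sort(unique(m[m[, 2L] %in% filler, 1L]))
      },
      only = {
        filler <- ev(e$filler)
        m <- role_pairs(interp, e$role)
        bad <- unique(m[!(m[, 2L] %in% filler), 1L])
        setdiff(dom, bad)
      },
      stop_unsupported(e$kind))
  }
  ev(expr)
}

#' Check whether a finite structure is a model of a knowledge base
#'
#' Evaluates every axiom of the knowledge base under the direct semantics:
#' inclusions as subset checks on extensions, assertions as membership
#' checks. Declarations, annotations and data assertions are non-logical and
#' always satisfied. Used in the test suite as the independent oracle for
#' the tableau's satisfiable verdicts.
#'
#' @param interp a `bao_interpretation`.
#' @param kb a `bao_ontology` in the supported fragment.
#' @return `TRUE` iff every axiom is satisfied.
#' @export
verify_model <- function(interp, kb) {
  pair_in <- function(role, a, b) {
    m <- role_pairs(interp, role)
    any(m[, 1L] == a & m[, 2L] == b)
  }
  for (ax in kb$axioms) {
    ok <- switch(ax$kind,
      subclass = {
        sub <- eval_concept(ax$sub, interp)
        all(sub %in% eval_concept(ax$sup, interp))
      },
      equivalent = {
        exts <- lapply(ax$exprs, eval_concept, interp = interp)
        all(vapply(exts[-1L], identical, NA, exts[[1L]]))
      },
      disjoint = {
        exts <- lapply(ax$exprs, eval_concept, interp = interp)
        ok2 <- TRUE
        for (i in seq_len(length(exts) - 1L))
          for (j in seq(i + 1L, length(exts)))
            if (length(intersect(exts[[i]], exts[[j]]))) ok2 <- FALSE
        ok2
      },
      subrole = {
        msub <- role_pairs(interp, ax$sub)
        msup <- role_pairs(interp, ax$sup)
        all(paste(msub[, 1L], msub[, 2L]) %in% paste(msup[, 1L], msup[, 2L]))
      },
      role_characteristic = stop_unsupported("role characteristic"),
      class_assertion = {
        el <- interp$individual_map[[ax$individual]]
        !is.null(el) && !is.na(el) && el %in% eval_concept(ax$expr, interp)
      },
      property_assertion = {
        a <- interp$individual_map[[ax$subject]]
        b <- interp$individual_map[[ax$object]]
        !is.null(a) && !is.null(b) && pair_in(ax$role, a, b)
      },
      data_assertion = TRUE,
      declaration = TRUE,
      annotation = TRUE)
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}
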