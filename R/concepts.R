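# Class-expression trees for the supported description-logic grammar:
#   C, D <- A | Top | Bottom | not C | C and D | C or D | R some C | R only C
#           | R min n C | R max n C | {a} | R Self
# Every node caches its canonical serialization (attribute "cstr"); structural
# equality is string equality on that form, which makes and/or order-free.

TOP_IRI <- "owl:Thing"
BOTTOM_IRI <- "owl:Nothing"

new_concept <- function(kind, fields, cstr) {
  x <- c(list(kind = kind), fields)
  attr(x, "cstr") <- cstr
  class(x) <- "bao_concept"
  x
}

#' Canonical serialization of a class expression
#'
#' Returns the deterministic canonical string of a class expression (or of an
#' axiom, see [axiom_str()]). Two expressions are structurally equal exactly
#' when their canonical strings are identical; `and`/`or` arguments are sorted
#' and deduplicated at construction time so argument order never matters.
#'
#' @param x a `bao_concept`.
#' @return a character scalar.
#' @export
ce_str <- function(x) {
  if (!inherits(x, "bao_concept")) stop("not a class expression")
  attr(x, "cstr")
}

ce_kind <- function(x) x$kind

#' Class-expression constructors
#'
#' Build nodes of the class-expression grammar. `ce_and()` and `ce_or()`
#' flatten nested nodes of the same kind, deduplicate structurally equal
#' arguments and sort them canonically; if a single distinct argument remains
#' it is returned unwrapped, and the empty conjunction/disjunction collapses
#' to `ce_top()`/`ce_bottom()`. Cardinality, nominal and self restrictions are
#' representable (the grammar includes them) but are rejected by the reasoner.
#'
#' @param name,individual an IRI / CURIE string.
#' @param role an object-property IRI string.
#' @param filler a `bao_concept` filler expression.
#' @param x a `bao_concept` to negate.
#' @param ... `bao_concept` arguments of a conjunction/disjunction.
#' @param n a cardinality bound (non-negative integer).
#' @return a `bao_concept`.
#' @name concept-constructors
NULL

#' @rdname concept-constructors
#' @export
ce_atomic <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (name == TOP_IRI) return(ce_top())
  if (name == BOTTOM_IRI) return(ce_bottom())
  new_concept("atomic", list(name = name), name)
}

#' @rdname concept-constructors
#' @export
ce_top <- function() new_concept("top", list(), TOP_IRI)

#' @rdname concept-constructors
#' @export
ce_bottom <- function() new_concept("bottom", list(), BOTTOM_IRI)

#' @rdname concept-constructors
#' @export
ce_not <- function(x) {
  new_concept("not", list(arg = x), paste0("(not ", ce_str(x), ")"))
}

ce_nary <- function(kind, args) {
  # flatten same-kind nesting, fold constants, drop duplicates and
  # complementary pairs, sort canonically
  absorb <- if (kind == "and") "bottom" else "top"
  neutral <- if (kind == "and") "top" else "bottom"
  flat <- list()
  for (a in args) {
    stopifnot(inherits(a, "bao_concept"))
    if (a$kind == kind) flat <- c(flat, a$args)
    else if (a$kind == neutral) next
    else if (a$kind == absorb)
      return(if (kind == "and") ce_bottom() else ce_top())
    else flat <- c(flat, list(a))
  }
  strs <- vapply(flat, ce_str, "")
  keep <- !duplicated(strs)
  flat <- flat[keep]
  strs <- strs[keep]
  negs <- vapply(flat, function(a)
    if (a$kind == "not") ce_str(a$arg) else paste0("(not ", ce_str(a), ")"), "")
  if (any(negs %in% strs))
    return(if (kind == "and") ce_bottom() else ce_top())
  ord <- order(strs, method = "radix")
  flat <- flat[ord]
  strs <- strs[ord]
  if (length(flat) == 0L) return(if (kind == "and") ce_top() else ce_bottom())
  if (length(flat) == 1L) return(flat[[1L]])
  new_concept(kind, list(args = flat),
              paste0("(", kind, " ", paste(strs, collapse = " "), ")"))
}

#' @rdname concept-constructors
#' @export
ce_and <- function(...) ce_nary("and", list(...))

#' @rdname concept-constructors
#' @export
ce_or <- function(...) ce_nary("or", list(...))

ce_and_list <- function(args) ce_nary("and", args)
ce_or_list <- function(args) ce_nary("or", args)

#' @rdname concept-constructors
#' @export
ce_some <- function(role, filler) {
  new_concept("some", list(role = role, filler = filler),
              paste0("(some ", role, " ", ce_str(filler), ")"))
}

#' @rdname concept-constructors
#' @export
ce_only <- function(role, filler) {
  new_concept("only", list(role = role, filler = filler),
              paste0("(only ", role, " ", ce_str(filler), ")"))
}

#' @rdname concept-constructors
#' @export
ce_min <- function(n, role, filler = ce_top()) {
  stopifnot(n >= 1)
  new_concept("min", list(n = as.integer(n), role = role, filler = filler),
              paste0("(min ", n, " ", role, " ", ce_str(filler), ")"))
}

#' @rdname concept-constructors
#' @export
ce_max <- function(n, role, filler = ce_top()) {
  stopifnot(n >= 0)
  new_concept("max", list(n = as.integer(n), role = role, filler = filler),
              paste0("(max ", n, " ", role, " ", ce_str(filler), ")"))
}

#' @rdname concept-constructors
#' @export
ce_nominal <- function(individual) {
  new_concept("nominal", list(individual = individual),
              paste0("({", individual, "})"))
}

#' @rdname concept-constructors
#' @export
ce_self <- function(role) {
  new_concept("self", list(role = role), paste0("(self ", role, ")"))
}

#' @export
print.bao_concept <- function(x, ...) {
  cat("<class expression> ", ce_str(x), "\n", sep = "")
  invisible(x)
}

#' Test structural equality of class expressions
#'
#' @param a,b `bao_concept` objects.
#' @return `TRUE` iff the canonical serializations coincide.
#' @export
ce_equal <- function(a, b) identical(ce_str(a), ce_str(b))

# Kinds the tableau reasoner and model checker handle (ALC).
UNSUPPORTED_KINDS <- c("min", "max", "nominal", "self")

stop_unsupported <- function(kind) {
  stop(sprintf("unsupported construct for the reasoner: %s", kind),
       call. = FALSE)
}

check_supported <- function(expr) {
  walk <- function(e) {
    if (e$kind %in% UNSUPPORTED_KINDS) stop_unsupported(e$kind)
    if (e$kind %in% c("and", "or")) lapply(e$args, walk)
    if (e$kind == "not") walk(e$arg)
    if (e$kind %in% c("some", "only")) walk(e$filler)
    invisible(NULL)
  }
  walk(expr)
  invisible(expr)
}
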