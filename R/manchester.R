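# Manchester-style surface syntax for class expressions:
#   keywords and / or / not / some / only / min / max / Self, parentheses,
#   {a} for nominals, single quotes around multi-word names.
# Precedence (loosest to tightest): or < and < not < restriction/primary.
# Names are resolved against a signature; unknown names are an error, never
# silently created.

norm_label <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Build a name-resolving signature from an ontology
#'
#' Extends [signature_of()] with a label table used by
#' [parse_class_expression()] and the annotation tools: every `rdfs:label`
#' annotation maps its (whitespace-normalized, case-folded) text to the
#' annotated IRI, and every IRI additionally gets a default label derived
#' from its local name with underscores read as spaces. A label carried by
#' two different IRIs is marked ambiguous and refuses to resolve.
#'
#' @param onto a `bao_ontology`.
#' @return a signature list with an extra `labels` environment.
#' @export
make_signature <- function(onto) {
  sig <- signature_of(onto)
  labels <- new.env(parent = emptyenv())
  put <- function(label, iri) {
    label <- norm_label(label)
    if (!nzchar(label)) return(invisible(NULL))
    old <- labels[[label]]
    if (is.null(old)) assign(label, iri, envir = labels)
    else if (!identical(old, iri)) assign(label, NA_character_, envir = labels)
  }
  for (ax in annotations(onto))
    if (ax$property == "rdfs:label") put(ax$text, ax$subject)
  for (iri in c(sig$classes, sig$roles, sig$individuals, sig$data_properties)) {
    local <- sub("^[^:]*:", "", iri)
    put(gsub("_", " ", local), iri)
  }
  sig$labels <- labels
  sig
}

resolve_name <- function(token, kind, sig) {
  pool <- sig[[kind]]
  if (token %in% pool) return(token)
  if (!is.null(sig$labels)) {
    iri <- sig$labels[[norm_label(token)]]
    if (!is.null(iri)) {
      if (is.na(iri))
        stop(sprintf("ambiguous name '%s': several IRIs carry this label",
                     token), call. = FALSE)
      if (iri %in% pool) return(iri)
    }
  }
  stop(sprintf("unknown %s name: '%s'",
               switch(kind, classes = "class", roles = "role",
                      individuals = "individual"), token), call. = FALSE)
}

KEYWORDS <- c("and", "or", "not", "some", "only", "min", "max", "Self")

tokenize_manchester <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", "{", "}")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
      next
    }
    if (ch == "'") {
      j <- regexpr("'", substr(text, i + 1L, n), fixed = TRUE)
      if (j < 0) stop(sprintf("syntax error at position %d: unterminated quote", i),
                      call. = FALSE)
      val <- substr(text, i + 1L, i + j - 1L)
      toks[[length(toks) + 1L]] <- list(type = "name", value = val, pos = i)
      i <- i + j + 1L
      next
    }
    m <- regexpr("^[A-Za-z0-9_:.\\-]+", substr(text, i, n))
    if (m > 0) {
      len <- attr(m, "match.length")
      val <- substr(text, i, i + len - 1L)
      type <- if (val %in% KEYWORDS) val else if (grepl("^[0-9]+$", val)) "int" else "name"
      toks[[length(toks) + 1L]] <- list(type = type, value = val, pos = i)
      i <- i + len
      next
    }
    stop(sprintf("syntax error at position %d: unexpected character '%s'", i, ch),
         call. = FALSE)
  }
  toks
}

#' Parse a Manchester-style class expression
#'
#' Parses strings such as
#' `"bioassay and ('has assay method' some ('assay design method' and
#' ('has participant' some 'Luciferin 4-monooxygenase')))"` into a class
#' expression tree. The parser preserves structure (no normalization beyond
#' the canonical and/or flattening of the constructors); names not present in
#' the signature raise an error.
#'
#' @param text the expression string.
#' @param sig a signature from [make_signature()] (or [signature_of()]).
#' @return a `bao_concept`.
#' @export
parse_class_expression <- function(text, sig) {
  toks <- tokenize_manchester(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      stop(sprintf("syntax error at position %d: expected '%s'",
                   if (is.null(t)) nchar(text) + 1L else t$pos, type),
           call. = FALSE)
    advance()
  }
  parse_expr <- function() {
    left <- parse_and()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      left <- ce_or(left, parse_and())
    }
    left
  }
  parse_and <- function() {
    left <- parse_unary()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      left <- ce_and(left, parse_unary())
    }
    left
  }
  parse_unary <- function() {
    t <- peek()
    if (is.null(t))
      stop(sprintf("syntax error at position %d: unexpected end of input",
                   nchar(text) + 1L), call. = FALSE)
    if (t$type == "not") { advance(); return(ce_not(parse_unary())) }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t))
      stop(sprintf("syntax error at position %d: unexpected end of input",
                   nchar(text) + 1L), call. = FALSE)
    if (t$type == "(") {
      advance()
      e <- parse_expr()
      expect(")")
      return(e)
    }
    if (t$type == "{") {
      advance()
      nm <- expect("name")
      expect("}")
      return(ce_nominal(resolve_name(nm$value, "individuals", sig)))
    }
    if (t$type != "name")
      stop(sprintf("syntax error at position %d: unexpected token '%s'",
                   t$pos, t$value), call. = FALSE)
    advance()
    nxt <- peek()
    if (!is.null(nxt) && nxt$type %in% c("some", "only", "min", "max", "Self")) {
      role <- resolve_name(t$value, "roles", sig)
      op <- advance()
      if (op$type == "Self") return(ce_self(role))
      if (op$type %in% c("min", "max")) {
        card <- expect("int")
        filler_next <- peek()
        filler <- if (!is.null(filler_next) &&
                      filler_next$type %in% c("name", "(", "{", "not"))
          parse_unary() else ce_top()
        return(if (op$type == "min") ce_min(as.integer(card$value), role, filler)
               else ce_max(as.integer(card$value), role, filler))
      }
      filler <- parse_unary()
      return(if (op$type == "some") ce_some(role, filler)
             else ce_only(role, filler))
    }
    if (t$value == TOP_IRI) return(ce_top())
    if (t$value == BOTTOM_IRI) return(ce_bottom())
    ce_atomic(resolve_name(t$value, "classes", sig))
  }
  e <- parse_expr()
  t <- peek()
  if (!is.null(t))
    stop(sprintf("syntax error at position %d: trailing token '%s'",
                 t$pos, t$value), call. = FALSE)
  e
}
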