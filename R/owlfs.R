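# Reader/writer for the package's ontology file dialect: a line-oriented
# subset of OWL 2 Functional-Style Syntax. Entities are written as CURIEs
# (prefix:local) and treated as opaque names in memory; Prefix declarations
# record the expansion. Serialization is canonical — fixed prefix order,
# axioms sorted by kind then canonical string, LF line endings — so equal
# axiom sets produce byte-identical files.

DEFAULT_PREFIXES <- c(
  owl  = "http://www.w3.org/2002/07/owl#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  bao  = "http://example.org/bao-mini/",
  t    = "http://example.org/test/",
  ex   = "http://example.org/external/",
  go   = "http://example.org/stub/go/",
  clo  = "http://example.org/stub/clo/",
  uo   = "http://example.org/stub/uo/",
  ncbitaxon = "http://example.org/stub/ncbitaxon/",
  doid = "http://example.org/stub/doid/",
  chebi = "http://example.org/stub/chebi/",
  uberon = "http://example.org/stub/uberon/",
  pato = "http://example.org/stub/pato/",
  iao  = "http://example.org/stub/iao/",
  ro   = "http://example.org/stub/ro/",
  bfo  = "http://example.org/stub/bfo/")

curie_prefix <- function(x) ifelse(grepl(":", x, fixed = TRUE),
                                   sub(":.*$", "", x), "")

CHARACTERISTIC_CONSTRUCTS <- c(
  TransitiveObjectProperty = "transitive",
  SymmetricObjectProperty = "symmetric",
  AsymmetricObjectProperty = "asymmetric",
  ReflexiveObjectProperty = "reflexive",
  IrreflexiveObjectProperty = "irreflexive",
  FunctionalObjectProperty = "functional",
  InverseFunctionalObjectProperty = "inverse-functional")

# ---- serialization -------------------------------------------------------

expr_to_ofn <- function(e) {
  switch(e$kind,
    atomic = e$name,
    top = "owl:Thing",
    bottom = "owl:Nothing",
    not = paste0("ObjectComplementOf(", expr_to_ofn(e$arg), ")"),
    and = paste0("ObjectIntersectionOf(",
                 paste(vapply(e$args, expr_to_ofn, ""), collapse = " "), ")"),
    or = paste0("ObjectUnionOf(",
                paste(vapply(e$args, expr_to_ofn, ""), collapse = " "), ")"),
    some = paste0("ObjectSomeValuesFrom(", e$role, " ",
                  expr_to_ofn(e$filler), ")"),
    only = paste0("ObjectAllValuesFrom(", e$role, " ",
                  expr_to_ofn(e$filler), ")"),
    min = paste0("ObjectMinCardinality(", e$n, " ", e$role, " ",
                 expr_to_ofn(e$filler), ")"),
    max = paste0("ObjectMaxCardinality(", e$n, " ", e$role, " ",
                 expr_to_ofn(e$filler), ")"),
    nominal = paste0("ObjectOneOf(", e$individual, ")"),
    self = paste0("ObjectHasSelf(", e$role, ")"))
}

quote_ofn <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

axiom_to_ofn <- function(ax) {
  switch(ax$kind,
    declaration = paste0("Declaration(", ax$entity_kind, "(", ax$iri, "))"),
    annotation = paste0("AnnotationAssertion(", ax$property, " ", ax$subject,
                        " ", quote_ofn(ax$text), ")"),
    subclass = paste0("SubClassOf(", expr_to_ofn(ax$sub), " ",
                      expr_to_ofn(ax$sup), ")"),
    equivalent = paste0("EquivalentClasses(",
                        paste(vapply(ax$exprs, expr_to_ofn, ""),
                              collapse = " "), ")"),
    disjoint = paste0("DisjointClasses(",
                      paste(vapply(ax$exprs, expr_to_ofn, ""),
                            collapse = " "), ")"),
    subrole = paste0("SubObjectPropertyOf(", ax$sub, " ", ax$sup, ")"),
    role_characteristic = paste0(
      names(CHARACTERISTIC_CONSTRUCTS)[
        match(ax$characteristic, CHARACTERISTIC_CONSTRUCTS)],
      "(", ax$role, ")"),
    class_assertion = paste0("ClassAssertion(", expr_to_ofn(ax$expr), " ",
                             ax$individual, ")"),
    property_assertion = paste0("ObjectPropertyAssertion(", ax$role, " ",
                                ax$subject, " ", ax$object, ")"),
    data_assertion = paste0("DataPropertyAssertion(", ax$property, " ",
                            ax$subject, " ",
                            quote_ofn(format(ax$value, scientific = FALSE,
                                             trim = TRUE)),
                            "^^", ax$unit, ")"))
}

#' Serialize an ontology to the functional-syntax dialect
#'
#' Canonical: used prefixes in fixed order, imports sorted, axioms ordered
#' by kind then canonical string; equal axiom sets give identical bytes.
#'
#' @param onto a `bao_ontology`.
#' @param prefixes named character vector of prefix expansions.
#' @return a single string (LF line endings).
#' @export
serialize_ontology <- function(onto, prefixes = DEFAULT_PREFIXES) {
  sig <- signature_of(onto)
  used <- unique(curie_prefix(c(onto$iri, onto$imports, unlist(sig),
                                unlist(lapply(annotations(onto), function(a)
                                  c(a$subject, a$property))))))
  used <- union(used, "owl")
  used <- intersect(names(prefixes), used)
  lines <- c(
    paste0("Prefix(", used, ":=<", prefixes[used], ">)"),
    "",
    paste0("Ontology(", onto$iri),
    if (length(onto$imports)) paste0("Import(", sort(onto$imports), ")"),
    vapply(order_axioms(onto$axioms), axiom_to_ofn, ""),
    ")")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write an ontology file
#'
#' @param onto a `bao_ontology`.
#' @param path output path.
#' @param prefixes prefix expansions used in the header.
#' @return `path`, invisibly.
#' @export
write_ontology_file <- function(onto, path, prefixes = DEFAULT_PREFIXES) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(serialize_ontology(onto, prefixes))), con)
  invisible(path)
}

# ---- parsing -------------------------------------------------------------

ofn_tokenize <- function(text) {
  toks <- list()
  line <- 1L
  col <- 1L
  i <- 1L
  n <- nchar(text)
  push <- function(type, value) toks[[length(toks) + 1L]] <<-
    list(type = type, value = value, line = line, col = col)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; col <- 1L; i <- i + 1L; next }
    if (grepl("^[ \t\r]$", ch)) { col <- col + 1L; i <- i + 1L; next }
    if (ch %in% c("(", ")")) { push(ch, ch); col <- col + 1L; i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L
      val <- character()
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\" && substr(text, j + 1L, j + 1L) == "\"") {
          val <- c(val, "\""); j <- j + 2L
        } else if (cj == "\"") break
        else { val <- c(val, cj); j <- j + 1L }
      }
      if (j > n) stop(sprintf("line %d, col %d: unterminated string literal",
                              line, col), call. = FALSE)
      lit <- paste(val, collapse = "")
      dt <- NA_character_
      if (substr(text, j + 1L, j + 2L) == "^^") {
        m <- regexpr("^[A-Za-z0-9_:.\\-]+", substr(text, j + 3L, n))
        dt <- substr(text, j + 3L, j + 2L + attr(m, "match.length"))
        j <- j + 2L + attr(m, "match.length")
      }
      push("string", list(value = lit, datatype = dt))
      col <- col + (j - i + 1L)
      i <- j + 1L
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0) stop(sprintf("line %d, col %d: unterminated IRI", line, col),
                      call. = FALSE)
      push("iriref", substr(text, i + 1L, i + j - 2L))
      col <- col + j
      i <- i + j
      next
    }
    if (ch == "=") { push("=", "="); col <- col + 1L; i <- i + 1L; next }
    m <- regexpr("^[A-Za-z0-9_:.\\-]+", substr(text, i, n))
    if (m > 0) {
      len <- attr(m, "match.length")
      push("name", substr(text, i, i + len - 1L))
      col <- col + len
      i <- i + len
      next
    }
    stop(sprintf("line %d, col %d: unexpected character '%s'", line, col, ch),
         call. = FALSE)
  }
  toks
}

#' Read an ontology file in the functional-syntax dialect
#'
#' Parses the documented subset (Prefix, Ontology, Import, Declaration,
#' SubClassOf, EquivalentClasses, DisjointClasses, SubObjectPropertyOf, role
#' characteristics, ClassAssertion, ObjectPropertyAssertion,
#' DataPropertyAssertion, AnnotationAssertion). Imports are recorded but not
#' resolved. Any construct outside the subset — e.g. a property chain — is an
#' unsupported-construct error naming it, never a silent drop.
#'
#' @param path path to the file.
#' @return a `bao_ontology` (with a `prefixes` attribute).
#' @export
read_ontology_file <- function(path) {
  text <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(text) <- "UTF-8"
  parse_ontology_text(text)
}

#' @rdname read_ontology_file
#' @param text ontology source text (alternative to `path`).
#' @export
parse_ontology_text <- function(text) {
  toks <- ofn_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(t, msg) stop(sprintf("line %d, col %d: %s",
                                        if (is.null(t)) -1L else t$line,
                                        if (is.null(t)) -1L else t$col, msg),
                                call. = FALSE)
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      fail(t, sprintf("expected '%s'%s", type,
                      if (is.null(t)) " at end of input"
                      else sprintf(", found '%s'",
                                   if (is.character(t$value)) t$value else t$type)))
    advance()
  }
  name_or_iri <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "iriref") return(advance()$value)
    expect("name")$value
  }

  prefixes <- character()
  while (!is.null(peek()) && peek()$type == "name" &&
         peek()$value == "Prefix") {
    advance(); expect("(")
    p <- expect("name")$value
    expect("=")
    iri <- expect("iriref")$value
    expect(")")
    prefixes[[sub(":$", "", p)]] <- iri
  }

  parse_expr <- function() {
    t <- peek()
    if (is.null(t)) fail(t, "expected class expression at end of input")
    if (t$type != "name") fail(t, "expected class expression")
    v <- advance()$value
    if (!is.null(peek()) && peek()$type == "(" &&
        grepl("^[A-Z]", sub("^.*:", "", v)) && !grepl(":", v)) {
      expect("(")
      out <- switch(v,
        ObjectComplementOf = ce_not(parse_expr()),
        ObjectIntersectionOf = {
          args <- list()
          while (!is.null(peek()) && peek()$type != ")")
            args <- c(args, list(parse_expr()))
          ce_and_list(args)
        },
        ObjectUnionOf = {
          args <- list()
          while (!is.null(peek()) && peek()$type != ")")
            args <- c(args, list(parse_expr()))
          ce_or_list(args)
        },
        ObjectSomeValuesFrom = ce_some(name_or_iri(), parse_expr()),
        ObjectAllValuesFrom = ce_only(name_or_iri(), parse_expr()),
        ObjectMinCardinality = ce_min(as.integer(expect("name")$value),
                                      name_or_iri(),
                                      if (peek()$type != ")") parse_expr()
                                      else ce_top()),
        ObjectMaxCardinality = ce_max(as.integer(expect("name")$value),
                                      name_or_iri(),
                                      if (peek()$type != ")") parse_expr()
                                      else ce_top()),
        ObjectOneOf = ce_nominal(name_or_iri()),
        ObjectHasSelf = ce_self(name_or_iri()),
        fail(t, sprintf("unsupported construct: %s", v)))
      expect(")")
      return(out)
    }
    ce_atomic(v)
  }

  expect_kw <- function(kw) {
    t <- expect("name")
    if (t$value != kw) fail(t, sprintf("expected '%s', found '%s'", kw, t$value))
    t
  }
  expect_kw("Ontology")
  expect("(")
  onto_iri <- name_or_iri()
  imports <- character()
  axioms <- list()
  repeat {
    t <- peek()
    if (is.null(t)) fail(t, "unexpected end of input inside Ontology(...)")
    if (t$type == ")") { advance(); break }
    if (t$type != "name") fail(t, "expected axiom")
    kw <- advance()$value
    expect("(")
    if (kw == "Import") {
      imports <- c(imports, name_or_iri())
      expect(")")
      next
    }
    ax <- switch(kw,
      Declaration = {
        kt <- expect("name")
        if (!(kt$value %in% DECL_KINDS))
          fail(kt, sprintf("unsupported construct: Declaration of %s", kt$value))
        expect("(")
        iri <- name_or_iri()
        expect(")")
        ax_declaration(kt$value, iri)
      },
      AnnotationAssertion = {
        prop <- name_or_iri()
        subj <- name_or_iri()
        lit <- expect("string")
        ax_annotation(subj, prop, lit$value$value)
      },
      SubClassOf = ax_subclass(parse_expr(), parse_expr()),
      EquivalentClasses = {
        es <- list()
        while (!is.null(peek()) && peek()$type != ")")
          es <- c(es, list(parse_expr()))
        ax_equivalent(es)
      },
      DisjointClasses = {
        es <- list()
        while (!is.null(peek()) && peek()$type != ")")
          es <- c(es, list(parse_expr()))
        ax_disjoint(es)
      },
      SubObjectPropertyOf = {
        t2 <- peek()
        if (!is.null(t2) && t2$type == "name" &&
            t2$value == "ObjectPropertyChain")
          fail(t2, "unsupported construct: ObjectPropertyChain")
        ax_subrole(name_or_iri(), name_or_iri())
      },
      ClassAssertion = {
        e <- parse_expr()
        ax_class_assertion(e, name_or_iri())
      },
      ObjectPropertyAssertion = ax_property_assertion(
        name_or_iri(), name_or_iri(), name_or_iri()),
      DataPropertyAssertion = {
        prop <- name_or_iri()
        subj <- name_or_iri()
        lit <- expect("string")
        val <- suppressWarnings(as.numeric(lit$value$value))
        if (is.na(val)) val <- lit$value$value
        ax_data_assertion(prop, subj, val,
                          if (is.na(lit$value$datatype)) "uo:dimensionless"
                          else lit$value$datatype)
      },
      {
        if (kw %in% names(CHARACTERISTIC_CONSTRUCTS))
          ax_role_characteristic(CHARACTERISTIC_CONSTRUCTS[[kw]], name_or_iri())
        else fail(t, sprintf("unsupported construct: %s", kw))
      })
    expect(")")
    axioms[[length(axioms) + 1L]] <- ax
  }
  t <- peek()
  if (!is.null(t)) fail(t, "trailing content after Ontology(...)")
  out <- ontology(onto_iri, axioms, imports)
  attr(out, "prefixes") <- prefixes
  out
}
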