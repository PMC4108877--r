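# Deterministic Turtle serialization of ABox assertion sets (the triple
# load path for annotation tables) and a reader for the same subset, so
# write -> parse is the identity on assertion sets.

turtle_object <- function(ax) {
  switch(ax$kind,
    class_assertion = {
      if (ax$expr$kind != "atomic")
        stop("turtle output supports atomic class assertions only",
             call. = FALSE)
      c(ax$individual, "rdf:type", ax$expr$name)
    },
    property_assertion = c(ax$subject, ax$role, ax$object),
    data_assertion = c(ax$subject, ax$property,
                       paste0("\"", format(ax$value, scientific = FALSE,
                                           trim = TRUE), "\"^^", ax$unit)),
    declaration = if (ax$entity_kind == "NamedIndividual")
      c(ax$iri, "rdf:type", "owl:NamedIndividual") else NULL,
    NULL)
}

#' Write assertions as Turtle
#'
#' Serializes an assertion set (class/property/data assertions and named
#' individual declarations) with deterministic subject, predicate and
#' object ordering and declared prefixes; two serializations of the same
#' set are byte-identical and re-parsing yields an equal assertion set.
#'
#' @param assertions list of `bao_axiom` assertions.
#' @param path output path.
#' @param prefixes named character vector of prefix expansions.
#' @return `path`, invisibly.
#' @export
write_turtle <- function(assertions, path, prefixes = DEFAULT_PREFIXES) {
  triples <- Filter(Negate(is.null), lapply(assertions, turtle_object))
  if (length(triples)) {
    m <- do.call(rbind, triples)
    m <- m[!duplicated(paste(m[, 1L], m[, 2L], m[, 3L])), , drop = FALSE]
    m <- m[order(m[, 1L], m[, 2L], m[, 3L], method = "radix"), ,
           drop = FALSE]
  } else m <- matrix(character(), ncol = 3L)
  used <- unique(curie_prefix(c(m[, 1L], m[, 2L],
                                m[, 3L][!startsWith(m[, 3L], "\"")],
                                sub("^.*\\^\\^", "", m[, 3L]))))
  used <- intersect(names(prefixes), union(used, c("rdf", "owl")))
  lines <- c(paste0("@prefix ", used, ": <", prefixes[used], "> ."),
             "",
             if (nrow(m)) paste(m[, 1L], m[, 2L], m[, 3L], "."))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"), "\n"))),
           con)
  invisible(path)
}

#' Read a Turtle file written by [write_turtle()]
#'
#' @param path the Turtle file.
#' @return a list of `bao_axiom` assertions.
#' @export
read_turtle <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "@prefix")) next
    m <- regmatches(ln, regexec(
      "^(\\S+)\\s+(\\S+)\\s+(\"[^\"]*\"\\^\\^\\S+|\\S+)\\s+\\.$", ln))[[1L]]
    if (length(m) != 4L)
      stop(sprintf("cannot parse turtle line: %s", ln), call. = FALSE)
    subj <- m[[2L]]; pred <- m[[3L]]; obj <- m[[4L]]
    ax <- if (startsWith(obj, "\"")) {
      lit <- sub("\\^\\^\\S+$", "", obj)
      lit <- substr(lit, 2L, nchar(lit) - 1L)
      val <- suppressWarnings(as.numeric(lit))
      ax_data_assertion(pred, subj, if (is.na(val)) lit else val,
                        sub("^.*\\^\\^", "", obj))
    } else if (pred == "rdf:type") {
      if (obj == "owl:NamedIndividual") ax_declaration("NamedIndividual", subj)
      else ax_class_assertion(ce_atomic(obj), subj)
    } else {
      ax_property_assertion(pred, subj, obj)
    }
    out[[length(out) + 1L]] <- ax
  }
  out
}
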