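# Import catalogs and the import graph. A catalog maps ontology IRIs to
# local paths with a declared layer kind (vocabulary, module, axiomfile,
# combinator, perspective, external_stub); all imports must resolve inside
# the catalog — there is no network resolution. The import graph must be a
# DAG; closures are reachability.

FILE_KINDS <- c("vocabulary", "module", "axiomfile", "combinator",
                "perspective", "external_stub")

#' Construct an import catalog
#'
#' @param dir directory against which the catalog's relative paths resolve.
#' @param entries list of entries, each a list with `iri`, `path`, `kind`
#'   (one of vocabulary, module, axiomfile, combinator, perspective,
#'   external_stub) and optionally `component = TRUE` for the main component
#'   vocabularies.
#' @param perspectives named character vector: perspective name -> root IRI.
#' @return a `bao_catalog`.
#' @export
import_catalog <- function(dir, entries, perspectives = character()) {
  iris <- vapply(entries, `[[`, "", "iri")
  stopifnot(!anyDuplicated(iris),
            all(vapply(entries, `[[`, "", "kind") %in% FILE_KINDS))
  names(entries) <- iris
  structure(list(dir = dir, entries = entries,
                 perspectives = unlist(perspectives) %||% character()),
            class = "bao_catalog")
}

#' @export
print.bao_catalog <- function(x, ...) {
  kinds <- vapply(x$entries, `[[`, "", "kind")
  cat("<import catalog> ", length(x$entries), " files in ", x$dir, "\n",
      sep = "")
  print(table(kinds))
  invisible(x)
}

#' Read / write a catalog file (YAML)
#'
#' @param path path to the catalog YAML file; relative entry paths resolve
#'   against its directory.
#' @return [read_catalog()]: a `bao_catalog`.
#' @export
read_catalog <- function(path) {
  y <- yaml::read_yaml(path)
  import_catalog(dirname(path), y$files,
                 perspectives = unlist(y$perspectives) %||% character())
}

#' @rdname read_catalog
#' @param catalog a `bao_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  entries <- lapply(unname(catalog$entries), function(e)
    e[!vapply(e, is.null, NA)])
  yaml::write_yaml(list(files = entries,
                        perspectives = as.list(catalog$perspectives)), path)
  invisible(path)
}

catalog_path <- function(catalog, iri) {
  e <- catalog$entries[[iri]]
  if (is.null(e)) stop(sprintf("IRI not in catalog: %s", iri), call. = FALSE)
  file.path(catalog$dir, e$path)
}

load_catalog_file <- function(catalog, iri) {
  e <- catalog$entries[[iri]]
  if (is.null(e)) stop(sprintf("IRI not in catalog: %s", iri), call. = FALSE)
  onto <- read_ontology_file(catalog_path(catalog, iri))
  structure(list(iri = iri, path = e$path, kind = e$kind, ontology = onto),
            class = "bao_ontology_file")
}

#' @export
print.bao_ontology_file <- function(x, ...) {
  cat("<ontology file> ", x$iri, " [", x$kind, "] ", x$path, "\n", sep = "")
  print(x$ontology)
  invisible(x)
}

#' Build the import graph of a catalog
#'
#' Parses every catalogued file; one node per file, one directed edge per
#' direct import (importer -> imported). An import whose target IRI is not
#' in the catalog is an error naming the IRI.
#'
#' @param catalog a `bao_catalog`.
#' @return a `bao_import_graph`: list with `nodes`, `edges` (two-column
#'   data frame) and the parsed `files`.
#' @export
build_import_graph <- function(catalog) {
  files <- lapply(names(catalog$entries), function(iri)
    load_catalog_file(catalog, iri))
  names(files) <- names(catalog$entries)
  edges <- data.frame(from = character(), to = character())
  for (f in files) {
    for (imp in f$ontology$imports) {
      if (!(imp %in% names(catalog$entries)))
        stop(sprintf("unresolvable import in %s: %s", f$iri, imp),
             call. = FALSE)
      edges <- rbind(edges, data.frame(from = f$iri, to = imp))
    }
  }
  structure(list(nodes = names(files), edges = edges, files = files),
            class = "bao_import_graph")
}

#' @export
print.bao_import_graph <- function(x, ...) {
  cat("<import graph>", length(x$nodes), "files,", nrow(x$edges), "imports\n")
  invisible(x)
}

#' Import closure of a node
#'
#' All files reachable from `iri` along import edges, including `iri`.
#'
#' @param graph a `bao_import_graph`.
#' @param iri the root file IRI.
#' @return character vector of file IRIs (stable order: breadth-first, then
#'   sorted within each level).
#' @export
import_closure <- function(graph, iri) {
  if (!(iri %in% graph$nodes))
    stop(sprintf("IRI not in import graph: %s", iri), call. = FALSE)
  seen <- iri
  frontier <- iri
  while (length(frontier)) {
    nxt <- sort(unique(graph$edges$to[graph$edges$from %in% frontier]))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Validation reports
#'
#' @param file the file IRI (or a graph-level label) the report concerns.
#' @param violations list of violations, each a list with `rule`, `subject`
#'   and `message`.
#' @return a `bao_validation_report`; `passed` is `TRUE` iff `violations`
#'   is empty.
#' @export
validation_report <- function(file, violations = list()) {
  structure(list(file = file, violations = violations,
                 passed = length(violations) == 0L),
            class = "bao_validation_report")
}

#' @export
print.bao_validation_report <- function(x, ...) {
  cat("<validation report> ", x$file, ": ",
      if (x$passed) "passed" else paste0(length(x$violations), " violation(s)"),
      "\n", sep = "")
  for (v in x$violations)
    cat("  [", v$rule, "] ", v$subject, ": ", v$message, "\n", sep = "")
  invisible(x)
}

violation <- function(rule, subject, message)
  list(rule = rule, subject = subject, message = message)

#' Check that an import graph is acyclic
#'
#' The layered framework presumes a DAG of imports; this reports one witness
#' cycle per strongly connected component (self-imports included).
#'
#' @param graph a `bao_import_graph`.
#' @return a `bao_validation_report`.
#' @export
assert_acyclic <- function(graph) {
  violations <- list()
  if (nrow(graph$edges)) {
    g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                       vertices = graph$nodes)
    comp <- igraph::components(g, mode = "strong")
    for (ci in which(comp$csize > 1L)) {
      members <- sort(names(comp$membership)[comp$membership == ci])
      violations[[length(violations) + 1L]] <- violation(
        "imports-acyclic", members[[1L]],
        paste0("import cycle: ", paste(members, collapse = " -> "),
               " -> ", members[[1L]]))
    }
    self <- graph$edges$from[graph$edges$from == graph$edges$to]
    for (s in unique(self))
      violations[[length(violations) + 1L]] <- violation(
        "imports-acyclic", s, "file imports itself")
  }
  validation_report("<import graph>", violations)
}
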