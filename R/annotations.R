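# Spreadsheet-style assay annotation tables: column headers map to ontology
# relations, cell text maps to ontology classes by label, and each row
# becomes a small set of ABox assertions about one assay individual.

#' Construct an annotation table
#'
#' @param df a data frame of character cells (one row per assay).
#' @param id_column name of the identifier column.
#' @return a `bao_annotation_table`.
#' @export
annotation_table <- function(df, id_column) {
  stopifnot(id_column %in% names(df))
  df[] <- lapply(df, as.character)
  structure(list(columns = names(df), rows = df, id_column = id_column),
            class = "bao_annotation_table")
}

#' @export
print.bao_annotation_table <- function(x, ...) {
  cat("<annotation table>", nrow(x$rows), "rows;",
      "identifier:", x$id_column, "\n")
  cat("  columns:", paste(x$columns, collapse = ", "), "\n")
  invisible(x)
}

#' Read an annotation table from CSV/TSV
#'
#' Cells are kept verbatim (empty cells become missing values). A row whose
#' arity differs from the header is an error naming the row; a missing
#' identifier column is an error.
#'
#' @param path the file path.
#' @param delimiter field delimiter: `","` (CSV) or `"\t"` (TSV).
#' @param id_column identifier column name; defaults to the first column.
#' @return a `bao_annotation_table`.
#' @export
read_annotation_table <- function(path, delimiter = ",", id_column = NULL) {
  counts <- utils::count.fields(path, sep = delimiter, quote = "\"",
                                blank.lines.skip = FALSE)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[[1L]])[[1L]]
    stop(sprintf("ragged row %d in %s: %d fields where the header has %d",
                 bad - 1L, path, counts[[bad]], counts[[1L]]), call. = FALSE)
  }
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", na.strings = "",
                          blank.lines.skip = FALSE)
  if (is.null(id_column)) id_column <- names(df)[[1L]]
  if (!(id_column %in% names(df)))
    stop(sprintf("missing identifier column '%s' in %s", id_column, path),
         call. = FALSE)
  annotation_table(df, id_column)
}

#' Header mappings
#'
#' A header mapping takes each non-identifier column header to a predicate
#' IRI and an object kind (`"class_term"` for cells naming ontology classes,
#' `"literal"` for numeric cells with a `unit`). The default mapping covers
#' the fixture's documented header set.
#'
#' @return a named list of `list(predicate, kind, unit)` entries.
#' @export
default_header_mapping <- function() {
  list(
    "assay design method" = list(predicate = "bao:has_design_method",
                                 kind = "class_term"),
    "physical detection method" = list(predicate = "bao:has_detection_method",
                                       kind = "class_term"),
    "assay format" = list(predicate = "bao:has_assay_format",
                          kind = "class_term"),
    "endpoint" = list(predicate = "bao:has_endpoint", kind = "class_term"),
    "mode of action" = list(predicate = "bao:has_mode_of_action",
                            kind = "class_term"),
    "signal direction" = list(predicate = "bao:has_signal_direction",
                              kind = "class_term"))
}

#' Read a header mapping from YAML
#' @param path a YAML file: header -> {predicate, kind, unit}.
#' @return a named list usable by [table_to_triples()].
#' @export
read_header_mapping <- function(path) yaml::read_yaml(path)

ind_iri <- function(x) paste0("bao:", gsub("[^A-Za-z0-9_.\\-]", "_",
                                           trimws(x)))

#' Translate an annotation table into ABox assertions
#'
#' Per row: the identifier cell names an assay individual, typed
#' `bao:bioassay`; every non-empty mapped cell contributes either an object
#' property assertion to a deterministic skolem individual typed by the
#' cell's class (matched against the ontology by exact label after
#' whitespace normalization and case folding; ambiguity is an error), or a
#' data assertion for literal columns. Unmapped headers and unresolvable
#' cell terms are errors naming the row and column.
#'
#' @param table a `bao_annotation_table`.
#' @param mapping a header mapping (see [default_header_mapping()]).
#' @param kb a `bao_ontology` providing the signature and labels.
#' @return a list of `bao_axiom` assertions (loadable as an ABox axiom
#'   file).
#' @export
table_to_triples <- function(table, mapping, kb) {
  sig <- make_signature(kb)
  headers <- setdiff(table$columns, table$id_column)
  unmapped <- setdiff(headers, names(mapping))
  if (length(unmapped))
    stop(sprintf("unmapped header(s): %s", paste(unmapped, collapse = ", ")),
         call. = FALSE)
  for (h in headers) {
    pred <- mapping[[h]]$predicate
    if (!(pred %in% c(sig$roles, sig$data_properties)))
      stop(sprintf("mapping predicate not in ontology signature: %s", pred),
           call. = FALSE)
  }
  out <- list()
  for (r in seq_len(nrow(table$rows))) {
    id <- table$rows[[table$id_column]][[r]]
    assay <- ind_iri(id)
    out <- c(out, list(ax_class_assertion(ce_atomic("bao:bioassay"), assay)))
    for (h in headers) {
      cell <- table$rows[[h]][[r]]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      spec <- mapping[[h]]
      if (spec$kind == "class_term") {
        cls <- tryCatch(resolve_name(cell, "classes", sig),
                        error = function(e)
                          stop(sprintf("row %d, column '%s': %s", r, h,
                                       conditionMessage(e)), call. = FALSE))
        filler <- paste0(assay, "_", gsub("[^A-Za-z0-9]+", "_", h))
        out <- c(out, list(
          ax_property_assertion(spec$predicate, assay, filler),
          ax_class_assertion(ce_atomic(cls), filler)))
      } else if (spec$kind == "literal") {
        val <- suppressWarnings(as.numeric(cell))
        if (is.na(val))
          stop(sprintf("row %d, column '%s': not a numeric literal: '%s'",
                       r, h, cell), call. = FALSE)
        out <- c(out, list(ax_data_assertion(
          spec$predicate, assay, val, spec$unit %||% "uo:dimensionless")))
      } else {
        stop(sprintf("unknown object kind '%s' for header '%s'",
                     spec$kind, h), call. = FALSE)
      }
    }
  }
  out
}

#' Retrieve assays by a molecular participant of their design method
#'
#' Reasoning-backed retrieval: returns the assay individuals entailed to be
#' instances of
#' `bioassay and ('has assay method' some ('assay design method' and
#' ('has participant' some <participant>)))` — so assays are found through
#' the formal definitions of their annotated design methods even when the
#' participant itself was never annotated.
#'
#' @param kb a `bao_ontology` including the annotation ABox.
#' @param participant a declared class IRI (e.g. the luciferase enzyme).
#' @param node_cap see [is_satisfiable()].
#' @return sorted character vector of assay individual IRIs.
#' @export
query_assays_by_participant <- function(kb, participant, node_cap = 50000L) {
  if (!(participant %in% signature_of(kb)$classes))
    stop(sprintf("unknown participant IRI: %s", participant), call. = FALSE)
  expr <- ce_and(
    ce_atomic("bao:bioassay"),
    ce_some("bao:has_assay_method",
            ce_and(ce_atomic("bao:assay_design_method"),
                   ce_some("bao:has_participant", ce_atomic(participant)))))
  retrieve_instances(kb, expr, node_cap)
}

#' Write the bundled example annotation table and mapping
#'
#' Writes the five-assay luciferase annotation table as CSV (or TSV) plus
#' the matching header-mapping YAML.
#'
#' @param path output path for the table.
#' @param mapping_path optional output path for the mapping YAML.
#' @param delimiter `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_example_annotations <- function(path, mapping_path = NULL,
                                      delimiter = ",") {
  utils::write.table(assay_table_rows(), path, sep = delimiter,
                     row.names = FALSE, qmethod = "double")
  if (!is.null(mapping_path))
    yaml::write_yaml(default_header_mapping(), mapping_path)
  invisible(path)
}
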