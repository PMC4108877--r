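annot_kb <- build_perspective("bao:perspective_core", bao_mini)
annot_mapping <- default_header_mapping()

test_that("annotation tables read from CSV and TSV identically, and ragged\
 rows are rejected", {
  csv <- tempfile(fileext = ".csv")
  tsv <- tempfile(fileext = ".tsv")
  write_example_annotations(csv)
  write_example_annotations(tsv, delimiter = "\t")
  t_csv <- read_annotation_table(csv)
  t_tsv <- read_annotation_table(tsv, delimiter = "\t")
  expect_identical(t_csv$rows, t_tsv$rows)
  expect_identical(t_csv$columns, t_tsv$columns)
  expect_identical(nrow(t_csv$rows), 5L)
  ragged <- tempfile(fileext = ".csv")
  writeLines(c("assay id,assay design method", "a1,x,extra", "a2,y"), ragged)
  expect_error(read_annotation_table(ragged), "ragged row 1")
  expect_error(read_annotation_table(csv, id_column = "nope"),
               "missing identifier column")
})

test_that("rows translate into typed individuals with one assertion per\
 non-empty cell", {
  df <- data.frame(
    `assay id` = "A1",
    `assay design method` = "ATP quantitation using luciferase",
    `physical detection method` = NA_character_,
    check.names = FALSE)
  tab <- annotation_table(df, "assay id")
  asserts <- table_to_triples(tab, annot_mapping, annot_kb)
  strs <- vapply(asserts, axiom_str, "")
  expect_length(asserts, 3L)  # typing + (edge + filler typing); empty cell none
  expect_true("ClassAssertion(bao:bioassay bao:A1)" %in% strs)
  expect_true(any(grepl(
    "ObjectPropertyAssertion\\(bao:has_design_method bao:A1", strs)))
  expect_true(any(grepl(
    "ClassAssertion\\(bao:ATP_quantitation_using_luciferase", strs)))
  # empty table gives the empty assertion set
  empty <- annotation_table(df[0, , drop = FALSE], "assay id")
  expect_length(table_to_triples(empty, annot_mapping, annot_kb), 0L)
  # a cell naming an unknown class is an error carrying row and column
  bad <- annotation_table(data.frame(
    `assay id` = "A1", `assay design method` = "no such method",
    check.names = FALSE), "assay id")
  expect_error(table_to_triples(bad, annot_mapping, annot_kb),
               "row 1, column 'assay design method'")
  # an unmapped header is an error
  extra <- annotation_table(data.frame(
    `assay id` = "A1", mystery = "x", check.names = FALSE), "assay id")
  expect_error(table_to_triples(extra, annot_mapping, annot_kb),
               "unmapped header")
})

test_that("triple count per row is the typing plus two per non-empty\
 mapped class cell", {
  tab <- annotation_table(assay_table_rows(), "assay id")
  asserts <- table_to_triples(tab, annot_mapping, annot_kb)
  non_empty <- sum(!is.na(as.matrix(
    tab$rows[setdiff(tab$columns, "assay id")])))
  expect_length(asserts, nrow(tab$rows) + 2L * non_empty)
})

test_that("assays are retrieved by participants that were never annotated", {
  kb <- merge_ontologies(list(annot_kb,
                              ontology("t:abox", table_to_triples(
                                annotation_table(assay_table_rows(),
                                                 "assay id"),
                                annot_mapping, annot_kb))))
  # no cell anywhere mentions the luciferase enzyme
  expect_false(any(grepl("monooxygenase",
                         unlist(assay_table_rows()), fixed = TRUE)))
  hits <- query_assays_by_participant(kb, "bao:Luciferin_4-monooxygenase")
  expect_identical(hits, paste0("bao:", sprintf("assay_%04d", 1:5)))
  # ATP participation is entailed only for the two ATP-defined methods
  expect_identical(query_assays_by_participant(kb, "bao:ATP"),
                   c("bao:assay_0002", "bao:assay_0004"))
  # a participant no design method references retrieves nothing
  expect_identical(query_assays_by_participant(kb, "bao:DNA"), character())
  expect_error(query_assays_by_participant(kb, "bao:nothing_here"),
               "unknown participant")
})

test_that("turtle serialization is deterministic and round-trips", {
  asserts <- table_to_triples(annotation_table(assay_table_rows(),
                                               "assay id"),
                              annot_mapping, annot_kb)
  f1 <- tempfile(fileext = ".ttl")
  f2 <- tempfile(fileext = ".ttl")
  write_turtle(asserts, f1)
  write_turtle(rev(asserts), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_turtle(f1)
  expect_setequal(vapply(back, axiom_str, ""),
                  unique(vapply(asserts, axiom_str, "")))
  # the empty set yields a prefix-only header
  f3 <- tempfile(fileext = ".ttl")
  write_turtle(list(), f3)
  lines <- readLines(f3)
  expect_true(all(startsWith(lines[nzchar(lines)], "@prefix")))
  expect_length(read_turtle(f3), 0L)
})

test_that("data assertions round-trip through turtle with value and unit", {
  asserts <- list(
    ax_data_assertion("bao:has_endpoint_value", "bao:ep1", 0.5,
                      "uo:micromolar"),
    ax_declaration("NamedIndividual", "bao:ep1"))
  f <- tempfile(fileext = ".ttl")
  write_turtle(asserts, f)
  back <- read_turtle(f)
  expect_setequal(vapply(back, axiom_str, ""),
                  vapply(asserts, axiom_str, ""))
})
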