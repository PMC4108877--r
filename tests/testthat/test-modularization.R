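make_toy_catalog <- function(dir, files, perspectives = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(names(files), function(iri) {
    path <- paste0(gsub("[^A-Za-z0-9]", "_", iri), ".ofn")
    write_ontology_file(files[[iri]], file.path(dir, path))
    list(iri = iri, path = path, kind = attr(files[[iri]], "kind") %||%
           "module")
  })
  import_catalog(dir, entries, perspectives)
}

with_kind <- function(onto, kind) { attr(onto, "kind") <- kind; onto }
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the import graph resolves edges and closures", {
  dir <- file.path(tempdir(), "toy-imports")
  files <- list(
    "t:A" = ontology("t:A", list(), imports = "t:B"),
    "t:B" = ontology("t:B", list(), imports = "t:C"),
    "t:C" = ontology("t:C", list()))
  g <- build_import_graph(make_toy_catalog(dir, files))
  expect_setequal(paste(g$edges$from, g$edges$to),
                  c("t:A t:B", "t:B t:C"))
  expect_setequal(import_closure(g, "t:A"), c("t:A", "t:B", "t:C"))
  # diamond: the shared node appears once in the closure
  dir2 <- file.path(tempdir(), "toy-diamond")
  g2 <- build_import_graph(make_toy_catalog(dir2, list(
    "t:A" = ontology("t:A", list(), imports = c("t:B", "t:C")),
    "t:B" = ontology("t:B", list(), imports = "t:D"),
    "t:C" = ontology("t:C", list(), imports = "t:D"),
    "t:D" = ontology("t:D", list()))))
  cl <- import_closure(g2, "t:A")
  expect_length(cl, 4L)
  expect_identical(sum(cl == "t:D"), 1L)
  # an import that the catalog cannot resolve is a named error
  dir3 <- file.path(tempdir(), "toy-unresolved")
  expect_error(build_import_graph(make_toy_catalog(dir3, list(
    "t:A" = ontology("t:A", list(), imports = "t:missing")))),
    "unresolvable import.*t:missing")
})

test_that("cycles and self-imports are reported, trees pass", {
  dir <- file.path(tempdir(), "toy-cycle")
  g <- build_import_graph(make_toy_catalog(dir, list(
    "t:A" = ontology("t:A", list(), imports = "t:B"),
    "t:B" = ontology("t:B", list(), imports = "t:A"))))
  rep <- assert_acyclic(g)
  expect_false(rep$passed)
  expect_match(rep$violations[[1L]]$message, "cycle")
  dir2 <- file.path(tempdir(), "toy-self")
  rep2 <- assert_acyclic(build_import_graph(make_toy_catalog(dir2, list(
    "t:A" = ontology("t:A", list(), imports = "t:A")))))
  expect_false(rep2$passed)
  dir3 <- file.path(tempdir(), "toy-tree")
  rep3 <- assert_acyclic(build_import_graph(make_toy_catalog(dir3, list(
    "t:A" = ontology("t:A", list(), imports = c("t:B", "t:C")),
    "t:B" = ontology("t:B", list()),
    "t:C" = ontology("t:C", list())))))
  expect_true(rep3$passed)
})

test_that("layer purity rules accept and reject the right axioms", {
  vocab_bad <- list(iri = "t:v", kind = "vocabulary", ontology = ontology(
    "t:v", list(ax_subclass(ce_atomic("t:A"),
                            ce_some("t:r", ce_atomic("t:B"))))))
  rep <- validate_artifact(vocab_bad)
  expect_false(rep$passed)
  expect_identical(rep$violations[[1L]]$rule, "vocabulary-subsumption-only")

  axfile_bad <- list(iri = "t:x", kind = "axiomfile", ontology = ontology(
    "t:x", list(ax_declaration("Class", "t:X"))))
  rep2 <- validate_artifact(axfile_bad)
  expect_false(rep2$passed)
  expect_identical(rep2$violations[[1L]]$rule, "axiomfile-no-declarations")

  taxonomy <- list(iri = "t:t", kind = "vocabulary", ontology = ontology(
    "t:t", list(ax_declaration("Class", "t:A"),
                ax_declaration("Class", "t:B"),
                ax_subclass(ce_atomic("t:A"), ce_atomic("t:B")),
                ax_annotation("t:A", "rdfs:label", "a"))))
  expect_true(validate_artifact(taxonomy)$passed)

  comb_bad <- list(iri = "t:c", kind = "combinator", ontology = ontology(
    "t:c", list(ax_equivalent(list(ce_atomic("t:A"), ce_atomic("t:B"))))))
  rep3 <- validate_artifact(comb_bad)
  expect_false(rep3$passed)
  expect_identical(rep3$violations[[1L]]$rule, "combinator-cross-namespace")
})

test_that("self-containedness detects terms missing from the closure", {
  dir <- file.path(tempdir(), "toy-selfcont")
  files <- list(
    "t:core" = with_kind(ontology("t:core", list(
      ax_subclass(ce_atomic("t:A"), ce_atomic("t:B"))), imports = "t:voc"),
      "module"),
    "t:voc" = with_kind(ontology("t:voc", list(
      ax_declaration("Class", "t:A"))), "vocabulary"))
  g <- build_import_graph(make_toy_catalog(dir, files))
  rep <- check_self_contained(g$files[["t:core"]], g)
  expect_false(rep$passed)
  expect_true(any(vapply(rep$violations, function(v)
    v$subject == "t:B", NA)))
  # the empty, import-free file is trivially self-contained
  dir2 <- file.path(tempdir(), "toy-empty")
  g2 <- build_import_graph(make_toy_catalog(dir2, list(
    "t:e" = ontology("t:e", list()))))
  expect_true(check_self_contained(g2$files[["t:e"]], g2)$passed)
  # the generated BAO-mini core is self-contained
  gm <- build_import_graph(bao_mini)
  expect_true(check_self_contained(gm$files[["bao:core"]], gm)$passed)
})

test_that("perspective building is deterministic and order-invariant", {
  p1 <- build_perspective("bao:perspective_complete", bao_mini)
  p2 <- build_perspective("bao:perspective_complete", bao_mini)
  expect_identical(serialize_ontology(p1), serialize_ontology(p2))
  permuted <- bao_mini
  permuted$entries <- rev(permuted$entries)
  p3 <- build_perspective("bao:perspective_complete", permuted)
  expect_identical(serialize_ontology(p1), serialize_ontology(p3))
  # merged axioms equal the union over the closure (set semantics)
  g <- build_import_graph(bao_mini)
  closure <- import_closure(g, "bao:perspective_complete")
  expected <- sort(unique(unlist(lapply(closure, function(i)
    vapply(g$files[[i]]$ontology$axioms, axiom_str, "")))))
  expect_identical(sort(vapply(p1$axioms, axiom_str, "")), expected)
  expect_length(p1$imports, 0L)
})

test_that("module extraction is upward closure and monotone in seeds", {
  ext <- ontology("ex:tax", list(
    ax_declaration("Class", "ex:root"),
    ax_declaration("Class", "ex:X"),
    ax_declaration("Class", "ex:Y"),
    ax_declaration("Class", "ex:other"),
    ax_subclass(ce_atomic("ex:X"), ce_atomic("ex:root")),
    ax_subclass(ce_atomic("ex:Y"), ce_atomic("ex:X")),
    ax_subclass(ce_atomic("ex:other"), ce_atomic("ex:root")),
    ax_annotation("ex:Y", "rdfs:label", "the Y")))
  mod <- extract_module(ext, "ex:Y")
  expect_setequal(signature_of(mod)$classes, c("ex:Y", "ex:X", "ex:root"))
  expect_length(Filter(function(a) a$kind == "subclass", mod$axioms), 2L)
  expect_true(any(vapply(mod$axioms, function(a)
    a$kind == "annotation" && a$text == "the Y", NA)))
  expect_length(extract_module(ext, character())$axioms, 0L)
  expect_error(extract_module(ext, "ex:nope"), "unknown seed")
  m1 <- extract_module(ext, "ex:Y")
  m2 <- extract_module(ext, c("ex:Y", "ex:other"))
  expect_true(all(vapply(m1$axioms, axiom_str, "") %in%
                  vapply(m2$axioms, axiom_str, "")))
})

test_that("combinators bridge namespaces and reject conflicts", {
  comb <- make_combinator(list(
    list(internal = "bao:cell_line_cell", external = "clo:cell_line_cell",
         relation = "equivalent"),
    list(internal = "bao:kinase", external = "ex:protein_kinase",
         relation = "subclass")))
  strs <- vapply(comb$axioms, axiom_str, "")
  expect_true("SubClassOf(bao:kinase ex:protein_kinase)" %in% strs)
  expect_true(any(grepl("EquivalentClasses", strs)))
  expect_true(validate_artifact(list(iri = comb$iri, kind = "combinator",
                                     ontology = comb))$passed)
  expect_length(make_combinator(list())$axioms, 0L)
  expect_error(make_combinator(list(
    list(internal = "bao:x", external = "ex:y", relation = "equivalent"),
    list(internal = "bao:x", external = "ex:y", relation = "subclass"))),
    "conflicting")
})
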