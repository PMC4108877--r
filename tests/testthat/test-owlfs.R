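test_that("a minimal file parses into its axioms", {
  f <- tempfile(fileext = ".ofn")
  writeLines(c(
    "Prefix(t:=<http://example.org/test/>)",
    "Ontology(t:mini",
    "Declaration(Class(t:A))",
    "SubClassOf(t:A owl:Thing)",
    ")"), f)
  onto <- read_ontology_file(f)
  expect_identical(onto$iri, "t:mini")
  expect_length(onto$axioms, 2L)
})

test_that("constructs outside the subset error by name, never drop\
 silently", {
  f <- tempfile(fileext = ".ofn")
  writeLines(c(
    "Ontology(t:bad",
    "SubObjectPropertyOf(ObjectPropertyChain(t:r t:s) t:t)",
    ")"), f)
  expect_error(read_ontology_file(f), "unsupported construct.*Chain")
  f2 <- tempfile(fileext = ".ofn")
  writeLines(c("Ontology(t:bad2",
               "SubClassOf(DataSomeValuesFrom(t:p t:d) t:A)", ")"), f2)
  expect_error(read_ontology_file(f2), "unsupported construct")
  f3 <- tempfile(fileext = ".ofn")
  writeLines("Ontology(t:x SubClassOf(t:A)", f3)
  expect_error(read_ontology_file(f3), "line")
})

test_that("role characteristics parse as stored metadata", {
  f <- tempfile(fileext = ".ofn")
  writeLines(c("Ontology(t:rc",
               "Declaration(ObjectProperty(t:part_of))",
               "TransitiveObjectProperty(t:part_of)", ")"), f)
  onto <- read_ontology_file(f)
  chars <- Filter(function(a) a$kind == "role_characteristic", onto$axioms)
  expect_length(chars, 1L)
  expect_identical(chars[[1L]]$characteristic, "transitive")
  # stored but rejected by the reasoner
  expect_error(kb_is_consistent(onto), "unsupported construct")
})

test_that("serialization is canonical: insertion order never matters", {
  ax <- list(ax_declaration("Class", "t:A"),
             ax_declaration("Class", "t:B"),
             ax_subclass(ce_atomic("t:A"), ce_atomic("t:B")),
             ax_annotation("t:A", "rdfs:label", "a"))
  s1 <- serialize_ontology(ontology("t:o", ax))
  s2 <- serialize_ontology(ontology("t:o", rev(ax)))
  expect_identical(s1, s2)
  empty <- serialize_ontology(ontology("t:empty"))
  expect_match(empty, "Ontology\\(t:empty\\n\\)\\n")
})

test_that("every generated fixture file round-trips structurally", {
  for (e in bao_mini$entries) {
    onto <- read_ontology_file(file.path(bao_mini$dir, e$path))
    f <- tempfile(fileext = ".ofn")
    write_ontology_file(onto, f)
    back <- read_ontology_file(f)
    expect_identical(sort(vapply(back$axioms, axiom_str, "")),
                     sort(vapply(onto$axioms, axiom_str, "")),
                     info = e$path)
    expect_setequal(back$imports, onto$imports)
    # serialize(parse(serialize(x))) is a byte-stable fixpoint
    f2 <- tempfile(fileext = ".ofn")
    write_ontology_file(back, f2)
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(f2, "raw", file.size(f2)), info = e$path)
  }
})

test_that("the complete perspective serializes to a stable checksum across\
 builds", {
  s1 <- serialize_ontology(build_perspective("bao:perspective_complete",
                                             bao_mini))
  dir2 <- file.path(tempdir(), "bao-mini-checksum")
  cat2 <- generate_bao_mini(dir2, panel_m = 3L, panel_n = 4L)
  s2 <- serialize_ontology(build_perspective("bao:perspective_complete",
                                             cat2))
  expect_identical(s1, s2)
})

test_that("the command-line dispatcher drives the toolkit end to end", {
  out <- file.path(tempdir(), "cli-fixture")
  expect_identical(cli_main(c("generate-fixture", "--out", out)), 0L)
  expect_identical(
    suppressMessages(utils::capture.output(
      st <- cli_main(c("validate", file.path(out, "catalog.yaml"))))),
    "all checks passed")
  expect_identical(st, 0L)
  built <- tempfile(fileext = ".ofn")
  expect_identical(cli_main(c("build", file.path(out, "catalog.yaml"),
                              "--perspective", "bao:perspective_core",
                              "--out", built)), 0L)
  expect_true(file.exists(built))
  o <- utils::capture.output(
    st2 <- cli_main(c("check", built, "'measure group'", "bioassay")))
  expect_identical(st2, 0L)
  expect_identical(o, "entailed ")
  # nonzero exit and report on a broken catalog
  broken <- file.path(tempdir(), "cli-broken")
  generate_bao_mini(broken)
  vb <- read_ontology_file(file.path(broken, "vocab_bioassay.ofn"))
  vb$axioms <- c(vb$axioms, list(ax_subclass(
    ce_atomic("bao:bioassay"), ce_some("bao:has_endpoint",
                                       ce_atomic("bao:bioassay")))))
  write_ontology_file(ontology(vb$iri, vb$axioms, vb$imports),
                      file.path(broken, "vocab_bioassay.ofn"))
  o2 <- utils::capture.output(
    st3 <- cli_main(c("validate", file.path(broken, "catalog.yaml"))))
  expect_identical(st3, 1L)
  expect_true(any(grepl("vocabulary-subsumption-only", o2)))
})
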