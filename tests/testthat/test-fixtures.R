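test_that("BAO-mini has six component vocabularies and eleven external\
 stubs, and every file validates", {
  expect_identical(n_component_vocabularies(bao_mini), 6L)
  expect_identical(n_external_stubs(bao_mini), 11L)
  reports <- validate_catalog(bao_mini)
  for (r in reports) expect_true(r$passed, info = r$file)
})

test_that("fixture generation is bit-deterministic", {
  dir2 <- file.path(tempdir(), "bao-mini-rerun")
  generate_bao_mini(dir2, panel_m = 3L, panel_n = 4L)
  for (e in bao_mini$entries) {
    a <- readBin(file.path(bao_mini$dir, e$path), "raw",
                 file.size(file.path(bao_mini$dir, e$path)))
    b2 <- readBin(file.path(dir2, e$path), "raw",
                  file.size(file.path(dir2, e$path)))
    expect_identical(a, b2, info = e$path)
  }
})

test_that("the luciferase suite entails, and never asserts, the printed\
 classification", {
  h <- classify(lucif_suite)
  expect_identical(direct_subclasses(h, bul), five_assays)
  # membership in the defined class is inference-only
  asserted_under_bul <- Filter(function(ax)
    ax$kind == "subclass" && ax$sup$kind == "atomic" && ax$sup$name == bul,
    lucif_suite$axioms)
  expect_length(asserted_under_bul, 0L)
  # the shared chemiluminescence detection method is asserted for all five
  for (assay in five_assays)
    expect_true(any(vapply(lucif_suite$axioms, function(ax)
      ax$kind == "subclass" && ax$sub$kind == "atomic" &&
        ax$sub$name == assay &&
        grepl("bao:chemiluminescence", axiom_str(ax)), NA)))
})

test_that("the design-method subsumption is inferred, not told", {
  sub <- "bao:ATP_coupled_enzyme_activity_measurement_method"
  sup <- "bao:ATP_quantitation_using_luciferase"
  expect_true(check_subsumption(lucif_suite, sub, sup))
  told <- Filter(function(ax)
    ax$kind == "subclass" && ax$sub$kind == "atomic" &&
      ax$sub$name == sub && ax$sup$kind == "atomic" && ax$sup$name == sup,
    lucif_suite$axioms)
  expect_length(told, 0L)
})

test_that("measure group is inferred under bioassay through the overlapping\
 definition", {
  axioms <- generate_measure_group_axioms()
  vocab_axioms <- list(
    ax_declaration("Class", "bao:bioassay"),
    ax_declaration("Class", "bao:measure_group"),
    ax_declaration("Class", "bao:assay_method"),
    ax_declaration("Class", "bao:endpoint"))
  kb <- ontology("t:mg", c(vocab_axioms, axioms))
  expect_true(check_subsumption(kb, "bao:measure_group", "bao:bioassay"))
  # no atomic subsumption is asserted between the two
  expect_false(any(vapply(axioms, function(ax)
    ax$kind == "subclass" && ax$sub$kind == "atomic" &&
      ax$sub$name == "bao:measure_group" &&
      ax$sup$kind == "atomic" && ax$sup$name == "bao:bioassay", NA)))
  # the justification pivots on the bioassay equivalence axiom
  j <- justify(kb, ax_subclass(ce_atomic("bao:measure_group"),
                               ce_atomic("bao:bioassay")))
  expect_true(any(vapply(j, function(ax) ax$kind == "equivalent", NA)))
  # removing the equivalence breaks the entailment
  no_equiv <- Filter(function(ax) ax$kind != "equivalent", kb$axioms)
  expect_false(check_subsumption(ontology("t:mg2", no_equiv),
                                 "bao:measure_group", "bao:bioassay"))
})

test_that("panel construction follows the m*n + n + 1 closed formula", {
  for (m in 1:5)
    for (n in 1:5)
      expect_length(measure_group_classes(generate_panel_assay(m, n)),
                    m * n + n + 1L)
  # two-level derived-from DAG for m = 3, n = 2
  p <- generate_panel_assay(3L, 2L)
  derived <- Filter(function(ax)
    ax$kind == "subclass" && ax$sup$kind == "some" &&
      ax$sup$role == "bao:is_derived_from", p$axioms)
  src <- vapply(derived, function(ax) ax$sub$name, "")
  dst <- vapply(derived, function(ax) ax$sup$filler$name, "")
  # each first-level group aggregates the m base groups of its target
  expect_identical(sum(src == "bao:measure_group_target1"), 3L)
  expect_identical(sum(src == "bao:measure_group_target2"), 3L)
  # the profile group aggregates the n first-level groups
  expect_setequal(dst[src == "bao:measure_group_profile"],
                  c("bao:measure_group_target1", "bao:measure_group_target2"))
  # base groups derive from nothing
  expect_false(any(grepl("conc", src)))
})

test_that("panel measure groups classify under bioassay", {
  catalog <- bao_mini
  core <- build_perspective("bao:perspective_core", catalog)
  p <- generate_panel_assay(2L, 2L)
  kb <- merge_ontologies(list(core, p))
  h <- classify(kb)
  for (mg in measure_group_classes(p))
    expect_true(is_subsumed(h, mg, "bao:bioassay"), info = mg)
  # and 'measure group' itself is inferred, not asserted, under bioassay
  expect_true(is_subsumed(h, "bao:measure_group", "bao:bioassay"))
})

test_that("cell cycle state assay terms are declared in the vocabularies", {
  core <- build_perspective("bao:perspective_core", bao_mini)
  declared <- signature_of(declarations(core))$classes
  needed <- paste0("bao:", c(
    "S_phase_assessment", "M_phase_assessment", "fluorescence_microscopy",
    "intensity_parameter", "counting_parameter",
    "percent_apoptotic_cells", "percent_mitotic_cells",
    "percent_interphase_cells", "percent_DNA_replicated_cells",
    "percent_G2_arrested_cells", "percent_mitotic_arrested_cells"))
  expect_true(all(needed %in% declared))
})
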