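test_that("satisfiability verdicts carry verified models", {
  expect_false(is_satisfiable(chain_kb, ce_bottom())$satisfiable)
  expect_false(is_satisfiable(chain_kb,
    ce_and(ce_atomic("t:A"), ce_not(ce_atomic("t:A"))))$satisfiable)
  res <- is_satisfiable(lucif_suite,
                        ce_atomic("bao:luciferase_reporter_gene_assay"))
  expect_true(res$satisfiable)
  expect_true(verify_model(res$model, lucif_suite))
})

test_that("subsumption reduces to unsatisfiability and follows told chains", {
  expect_true(check_subsumption(chain_kb, "t:A", "t:C"))
  expect_false(check_subsumption(chain_kb, "t:A", "t:D"))
  expect_true(check_subsumption(chain_kb, ce_atomic("t:D"), ce_top()))
  expect_true(check_subsumption(lucif_suite,
                                "bao:luciferase_reporter_gene_assay", bul))
  expect_true(check_subsumption(
    lucif_suite, "bao:ATP_coupled_enzyme_activity_measurement_method",
    "bao:ATP_quantitation_using_luciferase"))
})

test_that("classification produces a reduced hierarchy with equivalents and\
 unsatisfiable classes under owl:Nothing", {
  kb <- ontology("t:h", list(
    ax_declaration("Class", "t:A"),
    ax_declaration("Class", "t:B"),
    ax_subclass(ce_atomic("t:C"), ce_atomic("t:D")),
    ax_subclass(ce_atomic("t:D"), ce_atomic("t:C")),
    ax_subclass(ce_atomic("t:U"), ce_and(ce_atomic("t:A"),
                                         ce_not(ce_atomic("t:A"))))))
  h <- classify(kb)
  # declared classes without axioms are direct children of Top
  expect_identical(h$direct_supers[["t:A"]], "owl:Thing")
  expect_identical(h$direct_supers[["t:B"]], "owl:Thing")
  # mutual subsumption groups as equivalents
  expect_true(any(vapply(h$equivalents, function(g)
    all(c("t:C", "t:D") %in% g), NA)))
  # the unsatisfiable class joins owl:Nothing
  expect_false(h$satisfiable[["t:U"]])
  expect_true(any(vapply(h$equivalents, function(g)
    all(c("t:U", "owl:Nothing") %in% g), NA)))
  # entailed subsumption is reflexive and transitive on the output
  m <- h$subsumes
  expect_true(all(diag(m)))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      if (m[i, j]) expect_true(all(m[i, m[j, ]]))
})

test_that("asserted atomic subsumptions all appear as entailed", {
  h <- classify(chain_kb)
  expect_true(is_subsumed(h, "t:A", "t:B"))
  expect_true(is_subsumed(h, "t:B", "t:C"))
  expect_true(is_subsumed(h, "t:D", "t:E"))
  expect_true(is_subsumed(h, "t:A", "t:C"))
  expect_false(is_subsumed(h, "t:C", "t:A"))
})

test_that("mutual subsumption coincides with equivalence groups", {
  kb <- ontology("t:eq", list(
    ax_equivalent(list(ce_atomic("t:A"),
                       ce_some("t:r", ce_atomic("t:B")))),
    ax_equivalent(list(ce_atomic("t:C"),
                       ce_some("t:r", ce_atomic("t:B"))))))
  expect_true(check_subsumption(kb, "t:A", "t:C"))
  expect_true(check_subsumption(kb, "t:C", "t:A"))
  h <- classify(kb)
  expect_true(any(vapply(h$equivalents, function(g)
    all(c("t:A", "t:C") %in% g), NA)))
})

test_that("instance checking and retrieval work over the ABox", {
  kb <- ontology("t:i", list(
    ax_declaration("Class", "t:A"),
    ax_class_assertion(ce_atomic("t:bioassay"), "t:a1"),
    ax_declaration("NamedIndividual", "t:fresh")))
  expect_true(check_instance(kb, "t:a1", "t:bioassay"))
  expect_false(check_instance(kb, "t:fresh", "t:A"))
  expect_error(check_instance(kb, "t:nobody", "t:A"), "unknown individual")
  expect_identical(retrieve_instances(kb, ce_top()),
                   c("t:a1", "t:fresh"))
  expect_identical(retrieve_instances(kb, ce_bottom()), character())
})

test_that("an annotated individual is retrieved through its design method", {
  abox <- list(
    ax_class_assertion(ce_atomic("bao:bioassay"), "bao:a1"),
    ax_property_assertion("bao:has_design_method", "bao:a1", "bao:a1_dm"),
    ax_class_assertion(ce_atomic("bao:ATP_quantitation_using_luciferase"),
                       "bao:a1_dm"))
  kb <- ontology(lucif_suite$iri, c(lucif_suite$axioms, abox))
  expect_true(check_instance(kb, "bao:a1", bul))
  expect_identical(retrieve_instances(kb, bul), "bao:a1")
})

test_that("justifications are minimal and deterministic", {
  target <- ax_subclass(ce_atomic("t:A"), ce_atomic("t:C"))
  j <- justify(chain_kb, target)
  expect_setequal(vapply(j, axiom_str, ""),
                  c("SubClassOf(t:A t:B)", "SubClassOf(t:B t:C)"))
  # every single deletion breaks the entailment (checked independently)
  for (i in seq_along(j))
    expect_false(entails(ontology("t:j", j[-i]), target))
  expect_length(justify(chain_kb,
                        ax_subclass(ce_atomic("t:A"), ce_atomic("t:A"))), 0L)
  expect_error(justify(chain_kb,
                       ax_subclass(ce_atomic("t:C"), ce_atomic("t:A"))),
               "not entailed")
})

test_that("the luciferase justification never mentions the other assays", {
  j <- justify(lucif_suite,
               ax_subclass(ce_atomic("bao:luciferase_reporter_gene_assay"),
                           ce_atomic(bul)))
  other <- setdiff(five_assays, "bao:luciferase_reporter_gene_assay")
  for (ax in j) {
    sig <- signature_of(list(ax))
    expect_length(intersect(sig$classes, other), 0L)
  }
})

test_that("the model checker evaluates the direct semantics", {
  one <- interpretation(1L)
  expect_true(verify_model(one, ontology("t:empty")))
  bad <- interpretation(2L, class_ext = list("t:C" = 1:2, "t:D" = 2L))
  expect_false(verify_model(bad, ontology("t:v", list(
    ax_subclass(ce_atomic("t:C"), ce_atomic("t:D"))))))
  expect_true(verify_model(bad, ontology("t:v2", list(
    ax_subclass(ce_atomic("t:D"), ce_atomic("t:C"))))))
})

test_that("tableau agrees with the exhaustive model search on random\
 ontologies", {
  set.seed(2026)
  for (k in 1:80) {
    kb <- random_ontology()
    res <- is_satisfiable(kb)
    if (res$satisfiable) {
      expect_true(verify_model(res$model, kb))
    } else {
      expect_null(find_model_exhaustive(kb, 3L))
    }
  }
})

test_that("unsupported constructs and resource limits error loudly", {
  expect_error(is_satisfiable(chain_kb, ce_min(2L, "t:r", ce_atomic("t:A"))),
               "unsupported construct")
  expect_error(is_satisfiable(ontology("t:rc", list(
    ax_role_characteristic("transitive", "t:r"))), ce_atomic("t:A")),
    "unsupported construct")
  hard <- ontology("t:hard", list(
    ax_subclass(ce_top(), ce_some("t:r", ce_or(ce_atomic("t:A"),
                                               ce_atomic("t:B"))))))
  expect_error(is_satisfiable(hard, ce_atomic("t:A"), node_cap = 1L),
               "resource-limit")
})
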