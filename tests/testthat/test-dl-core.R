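test_that("the surface parser builds the documented expression trees", {
  e <- parse_class_expression(
    paste0("bioassay and ('has assay method' some ('assay design method'",
           " and ('has participant' some 'Luciferin 4-monooxygenase')))"),
    lucif_sig)
  expect_equal(ce_str(e), ce_str(ce_and(
    ce_atomic("bao:bioassay"),
    ce_some("bao:has_assay_method",
            ce_and(ce_atomic("bao:assay_design_method"),
                   ce_some("bao:has_participant",
                           ce_atomic("bao:Luciferin_4-monooxygenase")))))))
  expect_equal(ce_str(parse_class_expression("owl:Thing", lucif_sig)),
               "owl:Thing")
  # the parser preserves structure: no normalization of negations
  e2 <- parse_class_expression("not (bioassay and chemiluminescence)",
                               lucif_sig)
  expect_equal(e2$kind, "not")
  expect_equal(e2$arg$kind, "and")
})

test_that("parser errors are positioned and never invent names", {
  expect_error(parse_class_expression("bioassay and", lucif_sig),
               "syntax error")
  expect_error(parse_class_expression("bioassay and (chemiluminescence",
                                      lucif_sig), "position")
  expect_error(parse_class_expression("no_such_class", lucif_sig),
               "unknown class name.*no_such_class")
  expect_error(parse_class_expression("'has assay method' some nothing_here",
                                      lucif_sig), "unknown class")
})

test_that("and/or arguments are flattened, deduplicated and order-free", {
  a <- ce_atomic("t:A"); b2 <- ce_atomic("t:B"); c2 <- ce_atomic("t:C")
  expect_true(ce_equal(ce_and(a, ce_and(b2, c2)), ce_and(ce_and(c2, b2), a)))
  expect_true(ce_equal(ce_or(a, a, b2), ce_or(b2, a)))
  expect_identical(ce_and(a, a), a)
  expect_gte(length(ce_and(a, b2)$args), 2L)
})

test_that("negation normal form matches the textbook identities", {
  a <- ce_atomic("t:A"); b2 <- ce_atomic("t:B"); c2 <- ce_atomic("t:C")
  expect_equal(ce_str(to_nnf(ce_not(ce_and(c2, b2)))),
               ce_str(ce_or(ce_not(c2), ce_not(b2))))
  expect_equal(ce_str(to_nnf(ce_not(ce_some("t:r", c2)))),
               ce_str(ce_only("t:r", ce_not(c2))))
  expect_equal(ce_str(to_nnf(ce_not(ce_not(a)))), ce_str(a))
  expect_error(to_nnf(ce_nominal("t:i")), "unsupported construct")
})

test_that("NNF is idempotent, signature-preserving and model-invariant", {
  set.seed(7)
  classes <- c("t:A", "t:B", "t:C")
  roles <- c("t:r", "t:s")
  for (k in 1:40) {
    e <- baomini:::random_concept(3L, classes, roles)
    n1 <- to_nnf(e)
    expect_equal(ce_str(to_nnf(n1)), ce_str(n1))
    sig_e <- signature_of(list(ax_subclass(e, ce_top())))
    sig_n <- signature_of(list(ax_subclass(n1, ce_top())))
    expect_true(all(sig_n$classes %in% sig_e$classes))
    expect_true(all(sig_n$roles %in% sig_e$roles))
    interp <- random_interpretation(list(classes = classes, roles = roles))
    expect_identical(eval_concept(e, interp), eval_concept(n1, interp))
  }
})

test_that("signature_of partitions IRIs by entity kind", {
  sig <- signature_of(list(ax_subclass(ce_atomic("t:A"),
                                       ce_some("t:r", ce_atomic("t:B")))))
  expect_identical(sig$classes, c("t:A", "t:B"))
  expect_identical(sig$roles, "t:r")
  empty <- signature_of(list())
  expect_identical(lengths(empty), c(classes = 0L, roles = 0L,
                                     individuals = 0L, data_properties = 0L))
  suite_sig <- signature_of(lucif_suite)
  expect_true(all(five_assays %in% suite_sig$classes))
  expect_true("bao:Luciferin_4-monooxygenase" %in% suite_sig$classes)
})

test_that("internalization turns GCIs into one global NNF constraint", {
  c2 <- ce_atomic("t:C"); d2 <- ce_atomic("t:D")
  expect_equal(ce_str(internalize(list(ax_subclass(c2, d2)))),
               ce_str(to_nnf(ce_or(ce_not(c2), d2))))
  expect_equal(ce_str(internalize(list(ax_equivalent(list(c2, d2))))),
               ce_str(to_nnf(ce_and(ce_or(ce_not(c2), d2),
                                    ce_or(ce_not(d2), c2)))))
  expect_equal(ce_str(internalize(list())), "owl:Thing")
})
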