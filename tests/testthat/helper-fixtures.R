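# Shared fixtures, built once per test run (everything is generated in
# code; nothing is read from stored data).

lucif_suite <- generate_luciferase_suite()
lucif_sig <- make_signature(lucif_suite)

bao_mini_dir <- file.path(tempdir(), "bao-mini-fixture")
bao_mini <- generate_bao_mini(bao_mini_dir, panel_m = 3L, panel_n = 4L)

# a small knowledge base with a told chain, used across reasoner tests
chain_kb <- ontology("t:chain", list(
  ax_subclass(ce_atomic("t:A"), ce_atomic("t:B")),
  ax_subclass(ce_atomic("t:B"), ce_atomic("t:C")),
  ax_subclass(ce_atomic("t:D"), ce_atomic("t:E"))))

bul <- "bao:bioassay_uses_luciferase"
five_assays <- paste0("bao:", sort(c(
  "cell_viability_ATP_quantitation_assay",
  "cytochrome_P450_enzyme_activity_assay",
  "kinase_activity_assay",
  "luciferase_enzyme_activity_assay",
  "luciferase_reporter_gene_assay")))

random_interpretation <- function(sig, max_domain = 3L) {
  d <- sample(seq_len(max_domain), 1L)
  class_ext <- lapply(stats::setNames(sig$classes, sig$classes),
                      function(cl) which(stats::runif(d) < 0.5))
  role_ext <- lapply(stats::setNames(sig$roles, sig$roles), function(r) {
    pairs <- expand.grid(seq_len(d), seq_len(d))
    as.matrix(pairs[stats::runif(nrow(pairs)) < 0.4, , drop = FALSE])
  })
  interpretation(d, class_ext, role_ext)
}
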