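# Deterministic generator for "BAO-mini": a compact layered bioassay
# ontology with six component vocabularies (bioassay, assay biology, assay
# method, assay format, assay endpoint, assay screened entity) plus a
# property vocabulary, a core module, axiom files carrying the
# measure-group and luciferase modeling, eleven external stub taxonomies
# with a combinator, an optional annotation ABox, a kinase panel module and
# two perspectives (core-only and complete). Generation involves no
# randomness: two runs produce byte-identical files.

b <- function(x) paste0("bao:", x)

fx_label <- function(iri) gsub("_", " ", sub("^[^:]*:", "", iri))

fx_class <- function(iri, parent = NULL, label = fx_label(iri)) {
  c(list(ax_declaration("Class", iri),
         ax_annotation(iri, "rdfs:label", label)),
    if (!is.null(parent)) list(ax_subclass(ce_atomic(iri), ce_atomic(parent))))
}

fx_prop <- function(iri, parent = NULL) {
  c(list(ax_declaration("ObjectProperty", iri),
         ax_annotation(iri, "rdfs:label", fx_label(iri))),
    if (!is.null(parent)) list(ax_subrole(iri, parent)))
}

fx_taxonomy <- function(iri, edges, roots) {
  # edges: named character vector child -> parent
  axioms <- do.call(c, c(lapply(roots, fx_class),
                         lapply(names(edges), function(ch)
                           fx_class(ch, edges[[ch]])),
                         list(list())))
  ontology(iri, axioms)
}

# ---- component vocabularies ---------------------------------------------

vocab_bioassay <- function() {
  ax <- c(
    fx_class(b("bioassay")),
    fx_class(b("bioassay_uses_luciferase"),
             label = "bioassay uses luciferase"),
    fx_class(b("measure_group")),
    fx_class(b("panel_assay"), b("bioassay")),
    fx_class(b("profiling_assay"), b("bioassay")),
    fx_class(b("binding_assay"), b("bioassay")),
    fx_class(b("cell_cycle_assay"), b("bioassay")),
    fx_class(b("cell_cycle_state_assay"), b("cell_cycle_assay")),
    fx_class(b("cell_viability_assay"), b("bioassay")),
    fx_class(b("cytotoxicity_assay"), b("bioassay")),
    fx_class(b("enzyme_activity_assay"), b("bioassay")),
    fx_class(b("gene_expression_assay"), b("bioassay")),
    fx_class(b("redistribution_assay"), b("bioassay")),
    fx_class(b("signal_transduction_assay"), b("bioassay")),
    fx_class(b("luciferase_reporter_gene_assay"), b("bioassay")),
    fx_class(b("cell_viability_ATP_quantitation_assay"), b("bioassay")),
    fx_class(b("cytochrome_P450_enzyme_activity_assay"), b("bioassay")),
    fx_class(b("kinase_activity_assay"), b("bioassay")),
    fx_class(b("luciferase_enzyme_activity_assay"), b("bioassay")))
  ontology(b("vocab_bioassay"), ax)
}

vocab_biology <- function() {
  ax <- c(
    fx_class(b("biological_macromolecule")),
    fx_class(b("protein"), b("biological_macromolecule")),
    fx_class(b("kinase"), b("protein")),
    fx_class(b("cytochrome_P450"), b("protein")),
    fx_class(b("Luciferin_4-monooxygenase"), b("protein"),
             label = "Luciferin 4-monooxygenase"),
    fx_class(b("DNA"), b("biological_macromolecule")),
    fx_class(b("molecular_entity")),
    fx_class(b("ATP"), b("molecular_entity")),
    fx_class(b("luciferin"), b("molecular_entity")),
    fx_class(b("oxyluciferin"), b("molecular_entity")),
    fx_class(b("EdU"), b("molecular_entity")),
    fx_class(b("anti-MPM-2_antibody"), b("molecular_entity")),
    fx_class(b("Hoechst_33342"), b("molecular_entity")),
    fx_class(b("cell_line_cell")),
    fx_class(b("cellular_component")),
    fx_class(b("biological_process")),
    fx_class(b("cell_phenotype")),
    fx_class(b("organism")))
  ontology(b("vocab_assay_biology"), ax)
}

vocab_method <- function() {
  ax <- c(
    fx_class(b("assay_method")),
    fx_class(b("assay_design_method"), b("assay_method")),
    fx_class(b("assay_supporting_method"), b("assay_method")),
    fx_class(b("physical_detection_method"), b("assay_method")),
    fx_class(b("computational_method"), b("assay_method")),
    fx_class(b("chemiluminescence"), b("physical_detection_method")),
    fx_class(b("fluorescence_microscopy"), b("physical_detection_method")),
    fx_class(b("S_phase_assessment"), b("assay_design_method")),
    fx_class(b("M_phase_assessment"), b("assay_design_method")),
    fx_class(b("assay_readout_parameter")),
    fx_class(b("intensity_parameter"), b("assay_readout_parameter")),
    fx_class(b("counting_parameter"), b("assay_readout_parameter")),
    # design methods with logical definitions keep declaration-only entries
    # here; their axioms live in the examples axiom file
    fx_class(b("ATP_quantitation_using_luciferase"),
             label = "ATP quantitation using luciferase"),
    fx_class(b("ATP_coupled_enzyme_activity_measurement_method"),
             label = "ATP coupled enzyme activity measurement method"),
    fx_class(b("luciferase_induced_gene_expression_quantitation"),
             b("assay_design_method")),
    fx_class(b("luciferin_coupled_cytochrome_P450_activity_measurement"),
             b("assay_design_method")),
    fx_class(b("luciferase_enzyme_activity_measurement"),
             b("assay_design_method")))
  ontology(b("vocab_assay_method"), ax)
}

vocab_format <- function() {
  ax <- c(
    fx_class(b("assay_format")),
    fx_class(b("cell_based_format"), b("assay_format")),
    fx_class(b("biochemical_format"), b("assay_format")),
    fx_class(b("organism_based_format"), b("assay_format")))
  ontology(b("vocab_assay_format"), ax)
}

vocab_endpoint <- function() {
  ax <- c(
    fx_class(b("endpoint")),
    fx_class(b("concentration_endpoint"), b("endpoint")),
    fx_class(b("concentration_response_endpoint"),
             b("concentration_endpoint")),
    fx_class(b("IC50"), b("concentration_response_endpoint")),
    fx_class(b("EC50"), b("concentration_response_endpoint")),
    fx_class(b("response_endpoint"), b("endpoint")),
    fx_class(b("percent_inhibition"), b("response_endpoint")),
    fx_class(b("percent_activation"), b("response_endpoint")),
    fx_class(b("percent_apoptotic_cells"), b("response_endpoint")),
    fx_class(b("percent_mitotic_cells"), b("response_endpoint")),
    fx_class(b("percent_interphase_cells"), b("response_endpoint")),
    fx_class(b("percent_DNA_replicated_cells"), b("response_endpoint")),
    fx_class(b("percent_G2_arrested_cells"), b("response_endpoint")),
    fx_class(b("percent_mitotic_arrested_cells"), b("response_endpoint")),
    fx_class(b("profile_endpoint"), b("endpoint")),
    fx_class(b("kinase_profile_endpoint"), b("profile_endpoint")),
    fx_class(b("mode_of_action")),
    fx_class(b("ligand_function_mode_of_action"), b("mode_of_action")),
    fx_class(b("inhibition"), b("ligand_function_mode_of_action")),
    fx_class(b("activation"), b("ligand_function_mode_of_action")),
    fx_class(b("ligand_binding_mode_of_action"), b("mode_of_action")),
    fx_class(b("signal_direction")),
    fx_class(b("signal_increase"), b("signal_direction")),
    fx_class(b("signal_decrease"), b("signal_direction")),
    fx_class(b("endpoint_action_correlation")),
    fx_class(b("direct_correlation"), b("endpoint_action_correlation")),
    fx_class(b("inverse_correlation"), b("endpoint_action_correlation")))
  ontology(b("vocab_assay_endpoint"), ax)
}

vocab_screened_entity <- function() {
  ax <- c(
    fx_class(b("screened_entity")),
    fx_class(b("small_molecule"), b("screened_entity")),
    fx_class(b("biologic"), b("screened_entity")))
  ontology(b("vocab_assay_screened_entity"), ax)
}

vocab_properties <- function() {
  ax <- c(
    fx_prop(b("has_assay_method")),
    fx_prop(b("has_design_method"), b("has_assay_method")),
    fx_prop(b("has_detection_method"), b("has_assay_method")),
    fx_prop(b("has_participant")),
    fx_prop(b("has_endpoint")),
    fx_prop(b("has_measure_group")),
    fx_prop(b("is_derived_from")),
    fx_prop(b("has_mode_of_action")),
    fx_prop(b("has_signal_direction")),
    fx_prop(b("has_assay_format")),
    fx_prop(b("has_screened_entity")),
    list(ax_declaration("DataProperty", b("has_endpoint_value")),
         ax_annotation(b("has_endpoint_value"), "rdfs:label",
                       "has endpoint value")))
  ontology(b("properties"), ax)
}

# ---- axiom files ---------------------------------------------------------

#' Measure-group axioms
#'
#' The bioassay class carries a necessary-and-sufficient definition over its
#' assay-method and endpoint restrictions, and the measure group is asserted
#' to satisfy exactly those conditions — with no direct subsumption between
#' the two, so that `measure group` is a subclass of `bioassay` only by
#' reasoning, never by assertion.
#'
#' @return a list of `bao_axiom` objects.
#' @export
generate_measure_group_axioms <- function() {
  list(
    ax_equivalent(list(
      ce_atomic(b("bioassay")),
      ce_and(ce_some(b("has_assay_method"), ce_atomic(b("assay_method"))),
             ce_some(b("has_endpoint"), ce_atomic(b("endpoint")))))),
    ax_subclass(ce_atomic(b("measure_group")),
                ce_some(b("has_assay_method"), ce_atomic(b("assay_method")))),
    ax_subclass(ce_atomic(b("measure_group")),
                ce_some(b("has_endpoint"), ce_atomic(b("endpoint")))))
}

axioms_core_file <- function() {
  ontology(b("axioms_core"), c(
    generate_measure_group_axioms(),
    list(ax_disjoint(list(ce_atomic(b("assay_design_method")),
                          ce_atomic(b("physical_detection_method")))))))
}

participant <- function(x) ce_some(b("has_participant"), ce_atomic(b(x)))

luciferase_design_method_axioms <- function() {
  adm <- ce_atomic(b("assay_design_method"))
  c(
    # defined design methods: the second is entailed, never asserted, as a
    # subclass of the first
    list(
      ax_equivalent(list(
        ce_atomic(b("ATP_quantitation_using_luciferase")),
        ce_and(adm, participant("ATP"), participant("luciferin"),
               participant("Luciferin_4-monooxygenase")))),
      ax_equivalent(list(
        ce_atomic(b("ATP_coupled_enzyme_activity_measurement_method")),
        ce_and(adm, participant("ATP"), participant("luciferin"),
               participant("Luciferin_4-monooxygenase"),
               participant("kinase"))))),
    # primitive design methods with direct luciferase participation
    list(
      ax_subclass(ce_atomic(b("luciferase_induced_gene_expression_quantitation")),
                  ce_and(participant("luciferin"),
                         participant("Luciferin_4-monooxygenase"))),
      ax_subclass(ce_atomic(b("luciferin_coupled_cytochrome_P450_activity_measurement")),
                  ce_and(participant("luciferin"),
                         participant("cytochrome_P450"),
                         participant("Luciferin_4-monooxygenase"))),
      ax_subclass(ce_atomic(b("luciferase_enzyme_activity_measurement")),
                  ce_and(participant("luciferin"),
                         participant("Luciferin_4-monooxygenase")))))
}

LUCIFERASE_ASSAYS <- c(
  "cell_viability_ATP_quantitation_assay",
  "cytochrome_P450_enzyme_activity_assay",
  "kinase_activity_assay",
  "luciferase_enzyme_activity_assay",
  "luciferase_reporter_gene_assay")

assay_design_of <- c(
  luciferase_reporter_gene_assay = "luciferase_induced_gene_expression_quantitation",
  cell_viability_ATP_quantitation_assay = "ATP_quantitation_using_luciferase",
  cytochrome_P450_enzyme_activity_assay = "luciferin_coupled_cytochrome_P450_activity_measurement",
  kinase_activity_assay = "ATP_coupled_enzyme_activity_measurement_method",
  luciferase_enzyme_activity_assay = "luciferase_enzyme_activity_measurement")

assay_format_of <- c(
  luciferase_reporter_gene_assay = "cell_based_format",
  cell_viability_ATP_quantitation_assay = "cell_based_format",
  cytochrome_P450_enzyme_activity_assay = "biochemical_format",
  kinase_activity_assay = "biochemical_format",
  luciferase_enzyme_activity_assay = "biochemical_format")

luciferase_assay_axioms <- function() {
  out <- list(
    # the defined class, exactly as modeled: bioassay and ('has assay
    # method' some ('assay design method' and ('has participant' some
    # 'Luciferin 4-monooxygenase')))
    ax_equivalent(list(
      ce_atomic(b("bioassay_uses_luciferase")),
      ce_and(ce_atomic(b("bioassay")),
             ce_some(b("has_assay_method"),
                     ce_and(ce_atomic(b("assay_design_method")),
                            participant("Luciferin_4-monooxygenase")))))))
  for (assay in names(assay_design_of)) {
    out <- c(out, list(
      ax_subclass(ce_atomic(b(assay)),
                  ce_some(b("has_design_method"),
                          ce_atomic(b(assay_design_of[[assay]])))),
      # the physical detection method chemiluminescence is shared by all
      ax_subclass(ce_atomic(b(assay)),
                  ce_some(b("has_detection_method"),
                          ce_atomic(b("chemiluminescence")))),
      ax_subclass(ce_atomic(b(assay)),
                  ce_some(b("has_assay_format"),
                          ce_atomic(b(assay_format_of[[assay]]))))))
  }
  out
}

axioms_examples_file <- function() {
  ontology(b("axioms_examples"),
           c(luciferase_design_method_axioms(), luciferase_assay_axioms()))
}

#' Generate the luciferase assay suite
#'
#' A single merged ontology with the five mechanistically related luciferase
#' assays (reporter gene, cell viability ATP quantitation, cytochrome P450
#' enzyme activity, kinase activity, luciferase enzyme activity), their five
#' distinct assay design methods with luciferase (`Luciferin
#' 4-monooxygenase`) participation asserted directly or entailed through a
#' defined design method, the shared chemiluminescence detection method, and
#' the defined class `bioassay uses luciferase`. Membership of the assays in
#' the defined class is inference-only: nothing is asserted beneath it.
#'
#' @return a `bao_ontology`.
#' @export
generate_luciferase_suite <- function() {
  keep_classes <- b(c(
    "bioassay", "bioassay_uses_luciferase", names(assay_design_of),
    "assay_method", "assay_design_method", "physical_detection_method",
    "chemiluminescence", unname(assay_design_of),
    "assay_format", "cell_based_format", "biochemical_format",
    "biological_macromolecule", "protein", "kinase", "cytochrome_P450",
    "Luciferin_4-monooxygenase", "molecular_entity", "ATP", "luciferin"))
  vocab <- merge_ontologies(list(vocab_bioassay(), vocab_biology(),
                                 vocab_method(), vocab_format(),
                                 vocab_properties()))
  keep <- Filter(function(ax) {
    sig <- signature_of(list(ax))
    length(sig$classes) == 0L || all(sig$classes %in% keep_classes)
  }, vocab$axioms)
  keep <- Filter(function(ax)
    !(ax$kind == "annotation") || ax$subject %in% keep_classes ||
      grepl("^bao:has_", ax$subject), keep)
  ontology(b("luciferase_suite"),
           c(keep, luciferase_design_method_axioms(),
             luciferase_assay_axioms()))
}

# ---- panel assays --------------------------------------------------------

#' Generate a kinase concentration-response profiling panel assay
#'
#' Models a panel in which compounds are tested at `m` screening
#' concentrations against `n` kinase targets by two-stage measure-group
#' aggregation: `m * n` base measure groups (one per concentration-target
#' pair, carrying a percent-inhibition response endpoint), `n` first-level
#' derived measure groups (aggregating over concentrations, each carrying an
#' IC50 concentration-response endpoint), and one top-level derived measure
#' group carrying the kinase profile endpoint — `m * n + n + 1` measure
#' groups in total, all linked to one panel bioassay class. Endpoint
#' individuals carry synthetic values from a fixed formula (base response at
#' concentration i against target j is `100 - 5 * i - 2 * j` percent; the
#' IC50 for target j is `0.5 * j` micromolar), inert for reasoning.
#'
#' @param m number of screening concentrations (>= 1).
#' @param n number of kinase targets (>= 1).
#' @param target_kind IRI of the target class.
#' @return a `bao_ontology` (kind `module`; imports the BAO-mini core).
#' @export
generate_panel_assay <- function(m, n, target_kind = b("kinase")) {
  stopifnot(m >= 1, n >= 1)
  panel <- b("kinase_concentration_response_profiling_panel_assay")
  mg <- function(x) b(paste0("measure_group_", x))
  axioms <- fx_class(panel, b("panel_assay"))
  link <- function(mgi) list(
    ax_subclass(ce_atomic(panel),
                ce_some(b("has_measure_group"), ce_atomic(mgi))))
  add_mg <- function(iri, varied, extra) {
    axioms <<- c(axioms, fx_class(iri, b("measure_group")), extra, link(iri),
                 list(ax_annotation(iri, b("varied_parameter"), varied)))
  }
  for (j in seq_len(n)) {
    for (i in seq_len(m)) {
      base <- mg(sprintf("conc%d_target%d", i, j))
      add_mg(base, "concentration", list(
        ax_subclass(ce_atomic(base),
                    ce_some(b("has_endpoint"),
                            ce_atomic(b("percent_inhibition"))))))
    }
    first <- mg(sprintf("target%d", j))
    add_mg(first, "target", c(
      list(ax_subclass(ce_atomic(first),
                       ce_some(b("has_endpoint"), ce_atomic(b("IC50"))))),
      lapply(seq_len(m), function(i)
        ax_subclass(ce_atomic(first),
                    ce_some(b("is_derived_from"),
                            ce_atomic(mg(sprintf("conc%d_target%d", i, j))))))))
  }
  profile <- mg("profile")
  add_mg(profile, "target", c(
    list(ax_subclass(ce_atomic(profile),
                     ce_some(b("has_endpoint"),
                             ce_atomic(b("kinase_profile_endpoint"))))),
    lapply(seq_len(n), function(j)
      ax_subclass(ce_atomic(profile),
                  ce_some(b("is_derived_from"),
                          ce_atomic(mg(sprintf("target%d", j))))))))
  # synthetic endpoint individuals (inert data assertions, fixed formula)
  for (j in seq_len(n)) {
    for (i in seq_len(m)) {
      ep <- b(sprintf("endpoint_conc%d_target%d", i, j))
      axioms <- c(axioms, list(
        ax_declaration("NamedIndividual", ep),
        ax_class_assertion(ce_atomic(b("percent_inhibition")), ep),
        ax_data_assertion(b("has_endpoint_value"), ep, 100 - 5 * i - 2 * j,
                          "uo:percent")))
    }
    ep <- b(sprintf("endpoint_IC50_target%d", j))
    axioms <- c(axioms, list(
      ax_declaration("NamedIndividual", ep),
      ax_class_assertion(ce_atomic(b("IC50")), ep),
      ax_data_assertion(b("has_endpoint_value"), ep, 0.5 * j,
                        "uo:micromolar")))
  }
  axioms <- c(axioms, list(
    ax_annotation(panel, b("target_kind"), target_kind)))
  ontology(b("panel"), axioms, imports = b("core"))
}

#' Measure-group classes of an ontology
#'
#' Classes asserted (directly or through told atomic subsumptions) beneath
#' `bao:measure_group`.
#'
#' @param onto a `bao_ontology`.
#' @return sorted character vector of class IRIs.
#' @export
measure_group_classes <- function(onto) {
  parents <- list()
  for (ax in onto$axioms)
    if (ax$kind == "subclass" && is_atomic_pair(ax))
      parents[[ax$sub$name]] <- c(parents[[ax$sub$name]], ax$sup$name)
  under <- function(iri) {
    any(iri == b("measure_group")) ||
      any(vapply(parents[[iri]] %||% character(), under, NA))
  }
  cls <- setdiff(named_classes(onto), b("measure_group"))
  sort(cls[vapply(cls, under, NA)])
}

# ---- external stubs and combinator --------------------------------------

external_stub_ontologies <- function() {
  list(
    "go:go" = fx_taxonomy("go:go", c(
      "go:kinase_activity" = "go:molecular_function",
      "go:protein_binding" = "go:molecular_function",
      "go:cell_cycle" = "go:biological_process",
      "go:cell_death" = "go:biological_process"),
      c("go:molecular_function", "go:biological_process")),
    "clo:clo" = fx_taxonomy("clo:clo", c(
      "clo:HEK293_cell" = "clo:cell_line_cell",
      "clo:HeLa_cell" = "clo:cell_line_cell"),
      "clo:cell_line_cell"),
    "uo:uo" = fx_taxonomy("uo:uo", c(
      "uo:concentration_unit" = "uo:unit",
      "uo:micromolar" = "uo:concentration_unit",
      "uo:nanomolar" = "uo:concentration_unit",
      "uo:percent" = "uo:unit",
      "uo:dimensionless" = "uo:unit"),
      "uo:unit"),
    "ncbitaxon:ncbitaxon" = fx_taxonomy("ncbitaxon:ncbitaxon", c(
      "ncbitaxon:Mammalia" = "ncbitaxon:organism",
      "ncbitaxon:Homo_sapiens" = "ncbitaxon:Mammalia"),
      "ncbitaxon:organism"),
    "doid:doid" = fx_taxonomy("doid:doid", c(
      "doid:cancer" = "doid:disease"),
      "doid:disease"),
    "chebi:chebi" = fx_taxonomy("chebi:chebi", c(
      "chebi:ATP" = "chebi:molecular_entity",
      "chebi:luciferin" = "chebi:molecular_entity"),
      "chebi:molecular_entity"),
    "uberon:uberon" = fx_taxonomy("uberon:uberon", c(
      "uberon:liver" = "uberon:anatomical_entity",
      "uberon:kidney" = "uberon:anatomical_entity"),
      "uberon:anatomical_entity"),
    "pato:pato" = fx_taxonomy("pato:pato", c(
      "pato:intensity" = "pato:quality",
      "pato:optical_quality" = "pato:quality"),
      "pato:quality"),
    "iao:iao" = fx_taxonomy("iao:iao", c(
      "iao:document" = "iao:information_content_entity"),
      "iao:information_content_entity"),
    "ro:ro" = ontology("ro:ro", c(
      fx_prop("ro:has_participant"),
      fx_prop("ro:part_of"))),
    "bfo:bfo" = fx_taxonomy("bfo:bfo", c(
      "bfo:continuant" = "bfo:entity",
      "bfo:occurrent" = "bfo:entity",
      "bfo:material_entity" = "bfo:continuant",
      "bfo:process" = "bfo:occurrent"),
      "bfo:entity"))
}

combinator_file <- function() {
  onto <- make_combinator(list(
    list(internal = b("ATP"), external = "chebi:ATP",
         relation = "equivalent"),
    list(internal = b("luciferin"), external = "chebi:luciferin",
         relation = "equivalent"),
    list(internal = b("molecular_entity"),
         external = "chebi:molecular_entity", relation = "equivalent"),
    list(internal = b("cell_line_cell"), external = "clo:cell_line_cell",
         relation = "equivalent"),
    list(internal = b("biological_process"),
         external = "go:biological_process", relation = "equivalent"),
    list(internal = b("organism"), external = "ncbitaxon:organism",
         relation = "equivalent"),
    list(internal = b("bioassay"), external = "bfo:process",
         relation = "subclass"),
    list(internal = b("endpoint"),
         external = "iao:information_content_entity",
         relation = "subclass")),
    iri = b("combinators"))
  # property bridge: role equivalence expressed as mutual subsumption
  ontology(onto$iri, c(onto$axioms, list(
    ax_subrole(b("has_participant"), "ro:has_participant"),
    ax_subrole("ro:has_participant", b("has_participant")))))
}

# ---- annotation ABox -----------------------------------------------------

ASSAY_IDS <- sprintf("assay_%04d", 1:5)

assay_table_rows <- function() {
  data.frame(
    `assay id` = ASSAY_IDS,
    `assay design method` = fx_label(b(unname(assay_design_of))),
    `physical detection method` = "chemiluminescence",
    `assay format` = fx_label(b(unname(assay_format_of))),
    endpoint = c("percent inhibition", "IC50", "percent inhibition",
                 "IC50", "EC50"),
    `mode of action` = c("inhibition", "inhibition", "inhibition",
                         "inhibition", "activation"),
    `signal direction` = c("signal increase", "signal decrease",
                           "signal increase", "signal decrease",
                           "signal increase"),
    check.names = FALSE)
}

abox_annotations_file <- function() {
  kb <- merge_ontologies(list(vocab_bioassay(), vocab_biology(),
                              vocab_method(), vocab_format(),
                              vocab_endpoint(), vocab_properties()))
  mapping <- default_header_mapping()
  tab <- annotation_table(assay_table_rows(), id_column = "assay id")
  asserts <- table_to_triples(tab, mapping, kb)
  inds <- signature_of(asserts)$individuals
  ontology(b("abox_annotations"),
           c(asserts,
             lapply(inds, function(a) ax_declaration("NamedIndividual", a))))
}

# ---- the full catalog ----------------------------------------------------

#' Generate the BAO-mini fixture catalog
#'
#' Writes the complete layered fixture to `out_dir`: six component
#' vocabularies plus a property vocabulary, the core module, the
#' measure-group and luciferase axiom files, eleven external stub
#' taxonomies, a combinator, a kinase panel module, optionally the
#' annotation ABox, and two perspectives (`core` without external content
#' and `complete` with everything). The catalog passes all modularization
#' validators; generation is deterministic.
#'
#' @param out_dir output directory (created if needed).
#' @param panel_m,panel_n panel dimensions passed to
#'   [generate_panel_assay()].
#' @param with_abox include the annotation ABox file.
#' @return the `bao_catalog` (also written as `catalog.yaml`).
#' @export
generate_bao_mini <- function(out_dir, panel_m = 3L, panel_n = 4L,
                              with_abox = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "external"), showWarnings = FALSE)
  components <- list(vocab_bioassay(), vocab_biology(), vocab_method(),
                     vocab_format(), vocab_endpoint(),
                     vocab_screened_entity())
  vocabs <- c(components, list(vocab_properties()))
  axfiles <- list(axioms_core_file(), axioms_examples_file())
  core <- ontology(b("core"), list(),
                   imports = c(vapply(vocabs, `[[`, "", "iri"),
                               vapply(axfiles, `[[`, "", "iri")))
  stubs <- external_stub_ontologies()
  comb <- combinator_file()
  panel <- generate_panel_assay(panel_m, panel_n)
  persp_core <- ontology(b("perspective_core"), list(), imports = b("core"))
  complete_imports <- c(b("core"), names(stubs), comb$iri, panel$iri,
                        if (with_abox) b("abox_annotations"))
  persp_complete <- ontology(b("perspective_complete"), list(),
                             imports = complete_imports)

  entries <- list()
  add_entry <- function(onto, path, kind, component = NULL) {
    write_ontology_file(onto, file.path(out_dir, path))
    entries[[length(entries) + 1L]] <<-
      c(list(iri = onto$iri, path = path, kind = kind),
        if (isTRUE(component)) list(component = TRUE))
  }
  for (i in seq_along(components))
    add_entry(components[[i]],
              paste0(sub("^bao:", "", components[[i]]$iri), ".ofn"),
              "vocabulary", component = TRUE)
  add_entry(vocab_properties(), "properties.ofn", "vocabulary")
  add_entry(axfiles[[1L]], "axioms_core.ofn", "axiomfile")
  add_entry(axfiles[[2L]], "axioms_examples.ofn", "axiomfile")
  add_entry(core, "core.ofn", "module")
  for (iri in names(stubs))
    add_entry(stubs[[iri]],
              file.path("external", paste0(sub("^.*:", "", iri), ".ofn")),
              "external_stub")
  add_entry(comb, "combinators.ofn", "combinator")
  add_entry(panel, "panel.ofn", "module")
  if (with_abox)
    add_entry(abox_annotations_file(), "abox_annotations.ofn", "axiomfile")
  add_entry(persp_core, "perspective_core.ofn", "perspective")
  add_entry(persp_complete, "perspective_complete.ofn", "perspective")

  catalog <- import_catalog(out_dir, entries,
                            perspectives = c(core = b("perspective_core"),
                                             complete = b("perspective_complete")))
  write_catalog(catalog, file.path(out_dir, "catalog.yaml"))
  catalog
}

#' Component and stub counts of a catalog
#'
#' @param catalog a `bao_catalog`.
#' @return [n_component_vocabularies()]: number of files flagged as main
#'   component vocabularies; [n_external_stubs()]: number of external stub
#'   files.
#' @export
n_component_vocabularies <- function(catalog)
  sum(vapply(catalog$entries, function(e) isTRUE(e$component), NA))

#' @rdname n_component_vocabularies
#' @export
n_external_stubs <- function(catalog)
  sum(vapply(catalog$entries, `[[`, "", "kind") == "external_stub")
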