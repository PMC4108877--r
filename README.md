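# baomini

Ontologies of high-throughput screening (HTS) bioassays let reasoning
engines do work that flat annotation vocabularies cannot: assays annotated
only with their *assay design method* can be classified as mechanistically
related — for example, as "assays that use luciferase" — because the design
methods carry formal definitions of their molecular participants. `baomini`
is an R toolkit for building and reasoning over such ontologies at desk
scale. It is aimed at ontology engineers and computational chemical
biologists who want a self-contained, inspectable environment for
modular-ontology engineering and description-logic inference, without a
Java reasoner stack.

The package has three connected parts:

1. **A description-logic reasoner** for the ALC fragment with atomic role
   hierarchies. Class expressions follow the grammar
   *C, D ← A | ⊤ | ⊥ | ¬C | C ⊓ D | C ⊔ D | ∀R.C | ∃R.C*, knowledge bases
   consist of a TBox (axioms *C ⊑ D*, *C ≡ D*, disjointness), an RBox
   (atomic role inclusions) and an ABox (*C(a)*, *R(a, b)*). Subsumption
   reduces to concept unsatisfiability, decided by a tableau with lazy
   unfolding of absorbed axioms, internalization of residual general class
   inclusions (GCIs), ancestor subset blocking and memoized label-set
   satisfiability. Every satisfiable verdict exports a finite model that an
   independent direct-semantics checker (`verify_model()`) accepts.
   On top of satisfiability sit `classify()` (the inferred class
   hierarchy), `check_instance()` / `retrieve_instances()` and `justify()`
   (deletion-minimal axiom sets for an entailment).
2. **A layered modularization framework**: ontology files are typed as
   vocabularies (terms and plain subsumption only), modules, axiom files
   (logic over imported terms, no class/property declarations), combinators
   (atomic cross-namespace bridges), external stubs and perspectives
   (views merged over an acyclic `owl:imports` graph), with validators for
   each layer's purity rules, self-containedness and import acyclicity.
3. **A deterministic fixture generator** ("BAO-mini") that emulates a
   modular bioassay ontology: six component vocabularies (bioassay, assay
   biology, assay method, assay format, assay endpoint, screened entity),
   measure-group and luciferase-assay axioms, eleven external stub
   taxonomies with a combinator, a kinase concentration-response profiling
   panel built by two-stage measure-group aggregation, and spreadsheet-style
   assay annotation tables that translate into RDF triples (Turtle) for
   reasoning-backed retrieval.

## Worked example

```r
library(baomini)

suite <- generate_luciferase_suite()
h <- classify(suite)
direct_subclasses(h, "bao:bioassay_uses_luciferase")
#> [1] "bao:cell_viability_ATP_quantitation_assay"
#> [2] "bao:cytochrome_P450_enzyme_activity_assay"
#> [3] "bao:kinase_activity_assay"
#> [4] "bao:luciferase_enzyme_activity_assay"
#> [5] "bao:luciferase_reporter_gene_assay"
```

All five assays land under the defined class

> `bioassay and ('has assay method' some ('assay design method' and
> ('has participant' some 'Luciferin 4-monooxygenase')))`

although none of them is asserted there: each assay only names its own
design method, and participation of the luciferase enzyme is asserted for —
or, for the ATP-based methods, entailed by — those method definitions. The
same mechanism classifies `'ATP coupled enzyme activity measurement
method'` under `'ATP quantitation using luciferase'` without any told
subsumption, and `justify()` recovers the six axioms responsible:

```r
j <- justify(suite, ax_subclass(
  ce_atomic("bao:luciferase_reporter_gene_assay"),
  ce_atomic("bao:bioassay_uses_luciferase")))
length(j)
#> [1] 6
```

The modular fixture and the measure-group inference:

```r
catalog <- generate_bao_mini("bao-mini")   # 26 files + catalog.yaml
all(vapply(validate_catalog(catalog), `[[`, NA, "passed"))
#> [1] TRUE
core <- build_perspective("bao:perspective_core", catalog)
check_subsumption(core, "bao:measure_group", "bao:bioassay")
#> [1] TRUE
```

`measure group` is nowhere asserted beneath `bioassay`; the subsumption
follows from the bioassay's necessary-and-sufficient definition over its
assay-method and endpoint restrictions, which the measure group is asserted
to satisfy. Annotation tables close the loop: the bundled five-assay table
never mentions luciferase in any cell, yet

```r
complete <- build_perspective("bao:perspective_complete", catalog)
query_assays_by_participant(complete, "bao:Luciferin_4-monooxygenase")
#> [1] "bao:assay_0001" "bao:assay_0002" "bao:assay_0003" "bao:assay_0004"
#> [5] "bao:assay_0005"
```

A thin command-line wrapper ships in `inst/cli/baomini` with verbs
`generate-fixture`, `validate`, `build`, `classify`, `check`, `justify`,
`annotate` and `query`.

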