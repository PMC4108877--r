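---
title: "Modular bioassay ontologies and desk-scale description-logic reasoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular bioassay ontologies and desk-scale description-logic reasoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baomini)
```

## The problem

High-throughput screening assays are described by many interacting
concepts: the biological model system (format), the mechanism that turns a
perturbation into a signal (assay design method), the technology that
detects the signal (physical detection method), the molecular participants,
and the measured results (endpoints, grouped into measure groups).
Annotating assays with flat terms is not enough to find mechanistically
related assays: five luciferase assays each carry a *different* design
method, and their shared detection method (chemiluminescence) is too
generic to be informative. What they share is a molecular participant — the
luciferase enzyme — buried inside the formal definitions of their design
methods. Recovering that relationship is a reasoning task.

`baomini` packages the two ingredients this takes: a modularization
discipline for building the ontology out of small, checkable files, and a
description-logic reasoner that derives the inferred class hierarchy.

## The logic and the reasoner

The supported fragment is ALC with atomic role hierarchies. Class
expressions are built from atomic classes by complement, intersection,
union and the two quantifiers over roles; the TBox holds subsumption,
equivalence and disjointness axioms, the RBox atomic role inclusions, and
the ABox class and role assertions about individuals. Cardinality
restrictions, nominals and self-restrictions are *representable* (the
parser and serializer accept them, because real ontologies contain them)
but any attempt to reason over them raises an unsupported-construct error:
the reasoner never silently approximates. The same holds for role
characteristics (transitivity and friends), which are parsed as metadata
and rejected at reasoning time.

Subsumption `C ⊑ D` is decided as unsatisfiability of `C ⊓ ¬D`. The
decision procedure works as follows:

* **Absorption (lazy unfolding).** Axioms `A ⊑ C` with atomic `A` fire
  only when `A` enters a node label. A class with exactly one axiom, an
  equivalence `A ≡ C` with acyclic dependencies, is treated as *defined*:
  `A` unfolds to `C` and `¬A` to `¬C`. All remaining general inclusions
  are internalized into a single global NNF concept that every node must
  satisfy. This matters because the fixture's interesting inferences all
  pivot on definitions — absorbing them keeps the global constraint small.
* **Label-set recursion with memoization.** Because the fragment has no
  inverse roles and no nominals, an existential successor's subtree
  depends only on its initial label (the filler, the applicable universal
  restrictions, and the global constraint). Each successor is therefore
  decided as an independent label-set satisfiability problem. Verdicts are
  memoized per knowledge base: unsatisfiable verdicts are absolute and
  always cached; satisfiable verdicts are cached once every blocking loop
  they relied on has been discharged within their own subtree. Shared
  subproblems make classification (which asks thousands of subsumption
  questions) cheap.
* **Propositional handling.** Disjunctions are processed with boolean
  constraint propagation (a disjunct whose complement is present is
  closed; a single open disjunct is deterministic) and binary semantic
  branching — after a disjunct fails, its negation is asserted before the
  alternative is tried. Branch order follows the canonical sorted form of
  the disjunction, so every run is bit-for-bit reproducible without any
  random seed.
* **Termination.** Ancestor subset blocking: a label that is a subset of
  an ancestor's label on the current expansion path is satisfiable by
  looping back to the ancestor. Labels are drawn from a finite closure, so
  expansion terminates. A configurable work cap (default 50,000 steps)
  aborts pathological inputs with a resource-limit error rather than
  hanging.
* **Models as witnesses.** Every satisfiable verdict is backed by a finite
  model reconstructed from the memoized decisions; the test suite checks
  each one with `verify_model()`, a direct evaluator of the semantics
  (class extensions as sets over a finite domain). Defined classes get
  their extensions re-evaluated from their definitions in dependency order
  so asserted equivalences hold exactly in the exported structure.

Named individuals are handled in a small graph over the asserted role
edges; instance checking adds the complement assertion and tests
consistency. Since the fragment cannot propagate information *backwards*
along edges, an instance check only needs the individuals forward-reachable
from the queried one — the implementation restricts to that set after a
single global consistency check.

`classify()` orders classes lexicographically, seeds told subsumers, prunes
by transitivity, groups mutual subsumers into equivalence classes (an
unsatisfiable class joins `owl:Nothing`) and reduces the result
transitively to direct-superclass links. `justify()` shrinks the axiom set
by single deletions in canonical order, which yields a deterministic,
single-deletion-minimal justification.

### What the random-ontology suite does and does not show

The reasoner is exercised against two independent oracles: the model
checker (soundness: every SAT verdict's model verifies) and an exhaustive
search for models with at most three domain elements (the search uses
three-valued interval evaluation to prune, but prunes only branches that
provably contain no model, so it remains exhaustive). Five hundred random
knowledge bases with at most six axioms, four atomic classes, two roles and
expression depth three are checked per run. This demonstrates agreement on
the fragment's small instances; it is not a proof, and it says nothing
about constructs outside the fragment, which are rejected rather than
approximated. Real released ontologies are far larger than BAO-mini; the
engine is built for desk-scale fixtures and teaching-sized ontologies, not
for million-axiom corpora.

## The layered modularization framework

Files are typed by layer, and each layer has a checkable contract:

| kind | contract |
|------|----------|
| `vocabulary` | declarations, labels, atomic-to-atomic subsumptions (and, for property vocabularies, atomic role inclusions) — nothing else |
| `axiomfile` | logical axioms over imported terms; no class or property declarations (individuals may be declared, so ABox files fit here) |
| `combinator` | only atomic equivalence/subsumption bridges whose two sides live in different namespaces |
| `module`, `perspective` | free content, but must be self-contained over their import closure: every IRI used is declared somewhere inside it |
| `external_stub` | a stand-in taxonomy for an external source; unconstrained |

Imports must form a DAG (`assert_acyclic()` reports one witness cycle per
strongly connected component), every import must resolve inside the
catalog (no network), and `build_perspective()` merges the deduplicated
union of axioms over the closure — canonical structural equality is the
deduplication key, axioms are ordered by kind then canonical string, so
merging is commutative, associative and byte-deterministic. The build
pipeline mirrors a six-step discipline: vocabularies first, then the core
module that imports them, then axiom files over core terms, then the
external layer (stubs plus combinators), then ABox files, then
perspectives. The two shipped perspectives demonstrate the
with/without-upper-level split: `bao:perspective_core` stays self-contained
with no external content at all, `bao:perspective_complete` adds the
eleven stubs, the combinator and the annotation ABox.

`extract_module()` implements external-module extraction as upward closure
along asserted atomic subsumptions from seed terms, with declarations and
optional labels. That is this package's defined behavior — real extraction
pipelines differ in which axioms they keep; upward closure is the variant
that preserves the ancestry a combinator bridge needs, and it is monotone
in the seed set, which makes it property-testable. Whether property files
in production ontologies obey the vocabulary purity rule is an open
question in the field; here property vocabularies are explicitly allowed
to declare properties and assert atomic role inclusions, and nothing more.

## What BAO-mini emulates

The generator is deterministic — no randomness anywhere — so two runs
produce byte-identical files, and the catalog doubles as a regression
fixture. It emulates:

* **Six component vocabularies** (bioassay, assay biology, assay method,
  assay format, assay endpoint, assay screened entity) plus a property
  vocabulary. Term inventories are small (a few hundred classes in total)
  but cover the concepts the axioms need, including the cell-cycle state
  assay terms (S/M phase assessment, fluorescence microscopy,
  intensity/counting readout parameters, six percent-endpoint classes).
* **The measure-group model.** A measure group links sets of experimental
  results to one bioassay and can be derived from other measure groups.
  The bioassay carries a necessary-and-sufficient definition
  (`bioassay ≡ ∃has_assay_method.assay_method ⊓ ∃has_endpoint.endpoint`);
  the measure group is asserted to satisfy exactly those conditions, and
  the subsumption `measure group ⊑ bioassay` is consequently derivable but
  never asserted — asserting it directly would misstate the modeling
  intent, which is that the equivalence-like behavior must come out of the
  axioms. The exact axiom spelling is this package's reconstruction; the
  contract is the set of entailments, and the tests pin those.
* **The five luciferase assays**, each with its own design method; the
  luciferase participant (`Luciferin 4-monooxygenase`) is asserted
  directly for three methods and entailed through defined methods for the
  two ATP-based ones, so the classification exercises both told and
  derived participation. The defined class `bioassay uses luciferase` is
  kept in an examples axiom file, since it is an illustration rather than
  core modeling.
* **A kinase concentration-response profiling panel**: compounds tested at
  `m` concentrations against `n` kinase targets. Two-stage aggregation —
  first over concentrations (one IC50 endpoint per kinase), then over
  kinases (one profile endpoint) — yields `m*n + n + 1` measure-group
  classes linked by `is_derived_from` restrictions. Default dimensions are
  m = 3, n = 4: large enough to make the two aggregation levels visible,
  small enough to classify in seconds. Endpoint individuals carry inert
  synthetic values from a fixed formula (base response
  `100 − 5·i − 2·j` percent; IC50 `0.5·j` µM) — they exercise the
  data-assertion path and deliberately model nothing about real kinase
  pharmacology.
* **Annotation tables.** A five-row spreadsheet (assay id, assay design
  method, physical detection method, assay format, endpoint, mode of
  action, signal direction) maps to ABox triples: one typed assay
  individual per row, one assertion per non-empty cell, fillers as
  deterministic skolem individuals named from the assay id and header.
  Cell text resolves to classes by exact label match after whitespace
  normalization and case folding; an ambiguous label is an error, never a
  guess. The header set is this package's documented convention — the
  column headers of production annotation spreadsheets vary by project.

What the fixture does **not** emulate: real release files or IRIs, real
class counts, real external-ontology content (the stubs are a few classes
each), or any measured screening data. Passing tests on BAO-mini show the
machinery is correct on a faithful miniature, not that any particular
production ontology validates.

## Numerical and design choices

* Equality of expressions and axioms is string equality of a canonical
  serialization; `and`/`or` arguments are flattened, deduplicated,
  complement-folded and sorted at construction. This makes deduplication,
  diffing and determinism trivial, at the cost of not preserving the
  author's argument order (the Manchester-syntax parser preserves
  *structure* — it never rewrites negations — but argument order inside a
  conjunction is canonical).
* The file dialect is a subset of OWL 2 Functional-Style Syntax rather
  than OWL/XML: line-oriented, diff-friendly, and parseable bit-exactly.
  Entities are CURIEs against a fixed prefix table; `Import` takes the
  same CURIEs. Everything outside the subset errors by construct name.
* In the grammar, the roles under cardinality restrictions are stored
  as plain role references; whether they must be simple roles (as the
  convention for the full logic has it) is left open, which is harmless
  here because the reasoner rejects cardinalities outright.
* Tableau work cap: 50,000 steps by default, overridable per call. The
  test problem sizes (suite classification over ~30 classes, core
  perspective over ~90, 500 random ontologies, panels up to 5×5) were
  chosen so the whole suite runs in about two minutes on one CPU.
* `justify()` uses deletion order = canonical axiom order; different
  orders can yield different (equally minimal) justifications, so fixing
  the order fixes the output.

## Known limitations

Reasoning is restricted to ALC plus atomic role hierarchies: no inverses,
no role chains, no transitivity, no cardinality or nominal reasoning, no
datatype reasoning (endpoint values and units ride along as inert data
assertions and are queryable but never influence satisfiability). The
instance-level machinery assumes the unique-name-free, forward-only
semantics of this fragment. Classification is quadratic in the number of
named classes with told/transitive pruning — fine for hundreds of classes,
not for hundreds of thousands. The Turtle reader handles exactly the
subset the writer emits.
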