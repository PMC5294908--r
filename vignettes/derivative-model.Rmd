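---
title: "The derivative diagnosis model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The derivative diagnosis model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncolattice)
library(dplyr)
```

## The integration problem

ICD-10 and ICD-O-3 both record cancer diagnoses in electronic health
records, but they are structurally heterogeneous. ICD-10 encodes each
neoplastic diagnosis as a single code combining a behavior (malignant,
in situ, benign, uncertain) with a site (C50.2 is *malignant neoplasm of
the upper-inner quadrant of breast*). ICD-O-3 splits the same information
across two axes: a topography code for the site of origin and a
five-digit morphology code whose first four digits give the histology
and whose fifth digit gives the behavior (`8140/3` is *adenocarcinoma,
malignant primary*). No code-to-code equivalence can exist between the
two systems; the only correspondences are between an ICD-10 code and a
topography–morphology *pair*.

`oncolattice` builds a bridge between the two systems out of an
NCIt-style source ontology: an automatically constructed "derivative"
model in which a **diagnosis class** is defined by two existential
restrictions,

```
Diagnosis(m, t)  ==  EXISTS has_finding . m
                 AND EXISTS has_primary_anatomic_site . ReflexivePart(t)
```

where `m` is a morphology class and `ReflexivePart(t)` covers an
anatomical entity `t` *together with all its parts*
(`t OR EXISTS part_of . t`, the S-node pattern). The reflexive part is
what lets a tumour recorded against the whole breast subsume one
recorded against a quadrant of the breast.

## Components of the model

**Anatomy order.** The source ontology's anatomy axis is reduced to a
directed graph over three edge kinds: `is_a`,
`anatomic_structure_is_physical_part_of` and
`anatomic_structure_has_location`. The order `s <=A t` is plain directed
reachability over the union of the three, all treated as transitive and
freely composable. This deliberately reproduces NCIt-style propagation,
including its debatable consequences — a cell granule is reachable from
the skin through a cell-part chain, so a reflexive-part class built on
an organ covers cellular components too. The package reproduces this
behaviour rather than "fixing" it, because the retained diagnosis
classes are anchored to concepts the source ontology actually asserts;
the transitivity of part-whole relations across granularity levels
remains contested in the literature and is surfaced, not resolved, here.

**Reflexive-part lattice.** Topographies are collected as the union of
all primary-site fillers of all neoplasm concepts plus, by default,
every anatomy concept above them (`ancestor_completion = TRUE`, a config
switch). Completion is on by default because evaluation needs coarse
classes — e.g. a *Large Intestine* reflexive part shared by a colon
combination and a rectosigmoid code — even when no concept asserts the
coarse site directly. One class per topography is materialized; the
S-node union definition is emitted only at serialization time. Direct
edges are the transitive reduction (Hasse diagram) of `<=A` restricted
to the collected set.

**Morphology axis.** One class per distinct ICD-O-3 code annotated in
the source, each placed under exactly one of six behavior roots (benign,
uncertain benign/malignant, in situ, malignant primary, malignant
metastatic, uncertain primary/metastatic), mapped from the fifth digit
(`0,1,2,3,6,9` respectively). The axis is deliberately **flat** below
the behavior roots: two histologically related codes such as `9121/0`
(cavernous hemangioma) and `9120/0` (hemangioma NOS) are incomparable
classes. Histological specialization is not re-modelled here because the
source ontology's own subsumption hierarchy already carries it, and it
enters through the *refined index* instead: every neoplasm concept
inherits the morphology annotations and site fillers of all its `is_a`
ancestors. A code with the same histology but a different behavior digit
is a distinct class — ICD-O-3 forbids a morphology from having two
behaviors.

**Retention.** Candidate diagnoses are the cross product of the
candidate morphologies (specific codes *plus* the six behavior roots —
the printed class *"Malignant, primary site – Cecum Reflexive part"* is a
behavior-level candidate) with all reflexive parts. A candidate
`(m, t)` is retained iff at least one source concept satisfies it: some
inherited morphology below `m` and some inherited site reaching `t`.
Retention is computed by expanding, per concept, the up-sets of its
morphologies and sites and accumulating their cross product, so pruned
candidates never occupy storage; candidate enumeration itself streams in
bounded chunks. Whether candidates are pruned before or after full
enumeration cannot change the retained set, and the test suite checks the
indexed computation against an exhaustive double loop.

## Instantiation with terminology codes

Codes enter through a CUI crosswalk (MRCONSO-style RRF or plain TSV).

* **ICD-O-3 morphologies** bind to the class carrying the same code.
* **ICD-O-3 topographies** bind, via their CUI-shared anatomy concepts,
  to the minimal reflexive parts reachable above them. Codes whose
  targets all lie outside the anatomy axis are excluded as
  `NON_ANATOMY_ONLY` — these are crosswalk errors worth surfacing, not
  silently dropping.
* **ICD-10 codes** get a behavior from configurable block ranges
  (C00–C76 malignant primary; D00–D09 in situ; D10–D36 benign; C77–C79
  and D37–D48 excluded as secondary/uncertain). For each CUI-shared
  neoplasm concept, the satisfied diagnosis classes are computed from
  the concept's inherited morphologies **plus** the derived behavior,
  and the direct classes are the minimal elements of the union.
  Inherited morphologies are never filtered by the ICD-10 behavior:
  when a concept inherits both an in-situ and an invasive code, both
  survive to the audit, which is precisely how annotation clashes are
  detected. One note on block ranges: published descriptions of this
  integration exercise sometimes label C81–C96 as the excluded
  "secondary" block, although those are the haematological malignancies
  and secondary neoplasms conventionally sit in C77–C79; the defaults
  here follow the conventional reading, and both tables are
  configurable.

Binding is total: every code receives exactly one status
(`BOUND`, `UNMAPPED`, `NON_ANATOMY_ONLY`, `EXCLUDED_SCOPE`, `NO_SITE`),
and status counts are conserved per system. A mapped concept whose
satisfied set is empty despite having sites is reported as `NO_SITE`
with an explanatory reason rather than inventing a further status.

## Auditing

A code instantiating several mutually incomparable direct classes is a
symptom of source-ontology problems: `is_a` overloading (a cecum
neoplasm asserting Colon as a site although Cecum is neither a part nor
a subclass of Colon), missing part-whole links (Cecum and Colon both
unrelated to Colorectal Region), or inconsistent annotations (a
carcinoma-in-situ concept inheriting an invasive morphology through its
carcinoma ancestor). The audit reports, per category, how many bound
codes have more than one direct class; flags behavior conflicts (two
direct classes under different behavior roots); and, for every
multi-branch code, lists the pairwise `<=A`-incomparable site bases as
candidate missing relations. No threshold separates "overloading" from
legitimate multi-site diagnoses, so all multi-branch cases are reported
uniformly.

## Evaluation against a conversion gold standard

A SEER-style conversion table (topography, morphology-with-behavior,
ICD-10) is read with scope filters (metastatic `/6` and uncertain
`/1`, `/9` behaviors dropped by default) and stratified into
hematopoietic (ICD-10 C81–C96 or histology 9590–9993, configurable)
versus solid tumours. For each evaluable row — all three codes bound —
two questions are asked:

1. **Relatedness:** do the ICD-10 code and the combination instantiate a
   common diagnosis? "Branches" are operationalized as the *minimal*
   shared classes: the only order-theoretic reading consistent with
   direct-type reporting, since any shared class is above some minimal
   one.
2. **Rebuild:** nearest-code mapping by minimum hierarchical edge
   distance on the diagnosis Hasse diagram. The distance between two
   classes is the minimum over common ancestors of the summed upward
   step counts; between a code and a combination it is minimized over
   (direct class) × (minimal satisfied class) pairs. All argmin codes
   are kept — ties are *preserved* and reported as non-unique mappings,
   because collapsing them would hide exactly the ambiguity the model is
   supposed to reveal. Distances are computed on the diagnosis lattice
   only; traversing reflexive-part or morphology edges instead would
   give a different (also defensible) metric and is noted as an
   alternative, not implemented.

The edge distance satisfies symmetry and identity but is not asserted to
be a metric: common-ancestor distances can violate the triangle
inequality on lattices, and nothing downstream requires it.

## Synthetic data

The package ships generators rather than data files.

* `demo_ontology()` encodes, deterministically, the classic problem
  fragments of this integration task: the breast/quadrant partonomy; a
  GI partonomy in which Cecum, Colon and Colorectal Region are mutually
  unrelated below Large Intestine; a malignant cecum neoplasm asserting
  five sites; the in-situ/invasive annotation clash above a stage-0
  breast concept; the cavernous/NOS hemangioma pair; a topography
  crosswalked only to a disease concept; and the Birbeck-granule
  cell-part chain below Skin. The adenocarcinoma ancestor carries the
  `/3` annotation that keeps behavior-level classes retained at the GI
  sites. `demo_bundle()` adds matching terminologies, a crosswalk, a
  small conversion table and frozen truth tables, and replays the truth
  tables against the independent oracle at build time.
* `random_ontology()` draws DAGs over a topological ranking (acyclic by
  construction) with configurable densities; defaults (20 anatomy, 15
  neoplasm concepts, 8 codes, edge density 0.15, site/annotation rates
  0.8/0.6) are sized so that a few dozen concepts produce non-trivial
  lattices while the saturation oracle stays exhaustive.
* `plant_gold_standard()` selects combinations whose nearest bound
  ICD-10 code is a strict unique argmin and records that code as gold,
  so recovery must be complete with zero non-unique mappings; adding an
  equidistant decoy (`add_decoy_code()`) flips exactly the affected
  combinations. This synthesizes the *recoverable* regime; it does not
  emulate the miss patterns of real conversion tables, where crosswalk
  gaps dominate.
* `scale_ontology()` produces a shallow 5,000-topography /
  994-morphology / 300-concept model used to exercise streaming
  candidate generation (5,000,000 pairs in bounded chunks) and indexed
  retention against a sampled per-candidate scan.

What passing these tests shows is that the construction, binding, audit
and evaluation machinery is exact under the documented semantics; what
it cannot show is coverage on the real NCIt/NCIm/SEER releases, whose
scale and idiosyncrasies (annotation gaps, crosswalk errors beyond the
patterns modelled here) are out of desk-scale reach.

## Numerical and engineering choices

* Subsumption is computed **structurally**, not with a DL reasoner: the
  pattern restricts the fragment enough that reachability over three
  edge kinds, a two-level morphology order and their product are sound
  and complete for it. A reasoner could serve as an external
  cross-check; it is not a dependency. The in-package cross-check is an
  independent rule-saturation oracle (boolean-matrix fixpoint, naive
  double loops) sharing no code with the engine.
* Cycles in the source are fatal at ingestion by default; silently
  collapsing strongly connected components would alter semantics.
  Antisymmetry violations in any order raise cycle errors naming an
  offending pair.
* All set-valued outputs are emitted in lexicographic id order, making
  every artifact byte-stable for a fixed configuration and seed; table
  artifacts carry a tool-version/config-hash header.
* Turtle support is a restricted, hand-written reader/writer covering
  exactly the documented subset (class declarations, `subClassOf`,
  `equivalentClass` with intersections/unions, `someValuesFrom` on the
  five roles, labels, one annotation property); the tabular NATIVE_TSV
  format is canonical and the two dialects round-trip identically. Axis
  membership in Turtle follows the root-descendant convention, with
  marker edges that are carriers only.
* Problem sizes in the default test run: oracle equivalence on 20 seeded
  ontologies of ≤ 40 concepts; lattice and evaluation checks on the demo
  fixture (34 concepts, 110 candidates, 38 retained classes); one scale
  pass at 5,000 × 1,000. These sizes give exhaustive oracles and short
  runtimes; nothing in the method depends on them.

## Known limitations

* Coverage is bounded by the source ontology and the crosswalk: concepts
  absent from the source, and codes without CUI links, cannot bind
  (lexical mapping recovery is out of scope).
* Metastatic (`/6`) and uncertain (`/1`, `/9`) behaviors are handled
  only as configurable exclusions, not modelled.
* Granularity of part-whole propagation is inherited from the source;
  cell-level reflexive parts are reproduced, not filtered.
* The audit ranks nothing: it reports every multi-branch code uniformly
  and proposes no automatic repair of the source ontology.

## A worked run

```{r worked, eval = FALSE}
bundle <- demo_bundle()
model <- bundle$model
glance(model)

# the cecum code lands on three mutually unrelated sites
filter(bundle$bindings, code == "C18.0")$direct[[1]]

audit <- audit_bindings(bundle$bindings, model)
tidy(audit)
autoplot(audit)
```
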