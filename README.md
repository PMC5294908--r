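# oncolattice

Automatic construction of a **derivative diagnosis model** that bridges
ICD-10 neoplasm codes and ICD-O-3 topography–morphology code pairs
through an NCIt-style oncology ontology — with auditing of the source
ontology's inconsistencies and evaluation against SEER-style conversion
tables.

## Who this is for

Cancer registries and clinical-data-warehouse teams routinely receive
the same tumour coded twice: reimbursement data carry ICD-10 (one code
per diagnosis, behavior + site fused), pathology and tumour-board data
carry ICD-O-3 (separate topography and morphology axes). There is no
code-level equivalence between the two systems; the only meaningful
links run between an ICD-10 code and a topography–morphology *pair*.
`oncolattice` derives those links from an ontology instead of
hand-curating them, and — as a side effect — turns multi-classified
codes into an auditing signal for the source ontology itself.

## The model

A diagnosis class is the intersection of two existential restrictions,

```
D(m, t)  ≡  ∃ disease_has_finding . m
         ⊓  ∃ disease_has_primary_anatomic_site . RP(t)
```

where `m` is an ICD-O-3 morphology class (stratified under six behavior
roots from the fifth code digit) and `RP(t) ≡ t ⊔ ∃ part_of . t` is the
**reflexive part** (S-node) of topography `t`: the site together with
all of its parts, under the transitive union of `is_a` and the two
part-whole roles. The package

1. builds the reflexive-part lattice over all topographies involved in
   diagnosis definitions,
2. builds the behavior-stratified morphology axis from the ontology's
   ICD-O-3 annotations,
3. streams the `m × t` candidate cross product and **retains** the
   classes structurally subsuming at least one source concept (through
   ancestor-closed "refined" morphology/site sets),
4. binds ICD-10 / ICD-O-3 codes into the lattice through CUI crosswalks,
5. audits multi-class instantiation (is_a overloading, behavior
   conflicts, incomparable sites), and
6. evaluates reconstructed mappings against a conversion gold standard
   by minimum hierarchical edge distance on the Hasse diagram.

Subsumption is computed structurally (graph algorithms, no DL reasoner)
and is certified in the test suite against an independent
rule-saturation oracle.

## Worked example

```r
library(oncolattice)
library(dplyr)

bundle <- demo_bundle()      # deterministic fixture, oracle-verified
glance(bundle$model)
#> # A tibble: 1 × 6
#>   n_concepts n_topographies n_morphologies n_candidates n_retained retention_pct
#> 1         34             10              5          110         38          34.5
```

From 34 concepts the build collects 10 topographies and 5 annotated
morphologies, enumerates `(5 + 6) × 10 = 110` candidate diagnosis
expressions and retains the 38 that subsume at least one concept.

```r
filter(bundle$bindings, code == "C18.0")$direct[[1]]
#> [1] "DX:MALIGNANT_PRIMARY@NCIT:A_CEC" "DX:MALIGNANT_PRIMARY@NCIT:A_COL"
#> [3] "DX:MALIGNANT_PRIMARY@NCIT:A_CRR"
```

The malignant-cecum code instantiates *three* direct classes — cecum,
colon and colorectal region reflexive parts — because the source
ontology asserts all three as primary sites while relating none of them
to each other. That is the audit signal:

```r
audit <- audit_bindings(bundle$bindings, bundle$model)
tidy(audit)
#> # A tibble: 6 × 4
#>   category             n_bound n_multi pct_multi
#> 1 ICD-10                     5       2        40
#> 2 ICD-10 Benign              0       0        NA
#> 3 ICD-10 In situ             1       1       100
#> 4 ICD-10 Malignant           4       1        25
#> 5 ICD-O-3 Topographies       2       0         0
#> 6 ICD-O-3 Morphologies       5       0         0

audit$conflicts[, c("code", "kind", "behaviors")]
#> 1 D05   BEHAVIOR_CONFLICT IN_SITU;MALIGNANT_PRIMARY
```

`D05` (carcinoma in situ of breast) inherits both an in-situ and an
invasive morphology through the source hierarchy — a tumour cannot be
both, so the binding is flagged. `autoplot(audit)`,
`autoplot(evaluation)` and `autoplot(bundle$model$lattice)` draw the
corresponding figures; `evaluate_against_gold()` scores relatedness and
nearest-code rebuild against a conversion table.

A thin CLI (`inst/cli/oncolattice.R`) wraps the same pipeline:
`simulate` writes a fixture bundle, `run` executes
build → bind → audit → evaluate from a YAML config and writes
`model.ttl`, `bindings.tsv` and the audit/eval reports.

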