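---
title: "Methods: the epokb knowledge-base engine and its evaluation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the epokb knowledge-base engine and its evaluation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epokb)
```

## The model

`epokb` represents an application ontology plus a sign-centric knowledge
base for ectopic-pregnancy ultrasound imaging. The world is a set of named
concepts organized into subsumption hierarchies under designated roots —
imaging signs, types of ectopic pregnancy (by implantation site), anatomical
structures, and the three technical hierarchies (examination route,
examination mode, echographic view). Knowledge about a sign is attached as
existential restrictions over a fixed object-property hierarchy:

* `suggests` — sign to type of ectopic pregnancy;
* `hasLocation` — sign to anatomical structure;
* `requiresRoute`, `requiresMode`, `requiresView` — sign to technical
  element, grouped under their common parent `requires`.

Two further axiom forms close the model: *defined classes*
`D ≡ G ⊓ ∃p₁.C₁ ⊓ … ⊓ ∃pₖ.Cₖ` (necessary-and-sufficient sign categories such
as "color Doppler sign"), and pairwise *disjointness* between implantation
sites.

### Reasoning and its assumptions

The reasoner deliberately covers only the EL-style fragment this model uses:
conjunction, existential restriction, subproperty expansion, and subsumption.
There is no negation, no universal quantification, no role chains, and no
individuals. Everything a full OWL-DL reasoner would infer on such a
knowledge base is reachable by the two rules implemented here:

1. **Classification.** `S ⊑ D` for a defined class
   `D ≡ G ⊓ ∃p₁.C₁ ⊓ …` exactly when `S ⊑* G` and, for every conjunct,
   `S` carries an asserted-or-inherited restriction `∃p′.C′` with `p′ ⊑ p`
   in the property hierarchy and `C′ ⊑* C`. This is iterated to fixpoint
   because a new membership also confers the defined class's own
   restrictions on its members, which can satisfy further definitions.
2. **Materialization.** A relation `(s, p, c)` holds when some ancestor of
   the sign `s` asserts `∃p′.c′` with `p′ ⊑ p` and `c` a named ancestor of
   `c′` strictly below the root appropriate for `p`. Provenance
   (`asserted`, `inherited_from:<ancestor>`, `filler_generalized:<filler>`)
   is retained for every triple.

Two semantic decisions were genuinely open and are resolved as follows:

* **Membership edges are all entailed memberships.** `classify_defined()`
  reports `(S, D)` for *every* concept `S` entailed under `D` but not
  asserted there — including descendants of other members. The alternative
  (only "direct" new edges, as a DL class hierarchy view would draw them)
  depends on the order in which the fixpoint discovers memberships; the
  entailment view is order-independent, which makes oracle comparisons and
  planted ground truth exact.
* **Filler generalization stops below the category root.** Objects of
  `suggests` are reported only for named classes strictly under the
  ectopic-pregnancy root, mirroring the one-step granularity of the
  suggestion query; analogously for anatomy and the technical roots.

The subsumption graph must be a DAG (multiple parents are allowed and occur:
"color Doppler mode (2D)" is both a color Doppler mode and a 2D mode; every
classified sign gains defined-class parents). A cycle — asserted, or arising
because two defined classes turn out mutually subsuming — is an error, not a
warning: the data model has no notion of equivalent named classes.

### Queries

`suggest_types_for_signs()` implements the at-least-one-sign semantics: a
type (direct child of the disorder root) is suggested when at least one
selected sign has an inherited `suggests` restriction whose filler it
subsumes. Results are `DISTINCT`, ordered by label (case-insensitive,
identifier tie-break), and monotone in the selection. When a label is
missing in the requested language the English label is used instead of
dropping the result — on valid knowledge bases (English mandatory for signs)
the two behaviours coincide.

`sign_profile()` reports, per property, the *most specific* fillers of the
sign's inherited relations: an ancestor filler entailed by a more specific
one (the plain color Doppler mode next to its 2D variant) is suppressed, so
a sign's profile matches the knowledge-base card for that sign and a child
sign inherits its parent's profile unchanged.

`structures_in_view()` answers the competency question "which anatomical
structures are visible in a view" *via signs*: the union of `hasLocation`
fillers over all signs whose inherited `requiresView` covers the view or a
descendant. The knowledge base asserts no direct view-to-structure
relations, so a direct reading would be vacuously empty; the via-signs
reading is an interpretation and is flagged as such here.

## Serialization

The native format is JSON with a published schema
(`inst/extdata/kb.schema.json`); serialization is canonical (concepts by
identifier, axioms by a canonical key), so saves are byte-identical and
`load(save(kb))` is the identity. The Turtle subset covers exactly the
constructs the model can express (`rdfs:subClassOf` with a named class or a
`someValuesFrom` restriction node, `owl:equivalentClass` with an
intersection of one named genus plus restrictions, `owl:disjointWith`, SKOS
annotations, and plain `epo:PMID` / `epo:ImagePath` / `epo:FMAID` triples);
anything else in an imported file is skipped with a warning. A disjoint set
is exported as pairwise `owl:disjointWith` triples, so the Turtle round-trip
preserves the deductive closure but not axiom grouping — the closure, the
materialized relations and the consistency verdict are invariants of the
round-trip, and the tests check precisely those.

## Evaluation statistics

### Proportion of agreement

For one sign on one image, with `k` of `x` panel observers annotating:
agreements are the concordant-positive pairs `C(k,2)`; trials are all pairs
`C(x,2)`. Three conventions are forced by the published worked example and
table, and are worth stating explicitly:

* **Both-absent pairs are not agreements.** With `k = 5`, `x = 6` the
  worked example counts 10 agreements out of 15 — not 11 — so the pair of
  observers who both omitted the sign does not count as agreeing.
* **A (sign, image) pair enters the table only if at least one observer
  annotated it** (`annotation_matrix()` emits no row otherwise). This is
  the only rule consistent with finite per-sign image counts in the
  published table; it also means `p_a` estimates agreement *conditional on
  the sign being raised at all*.
* **Rendering.** Percentages are rounded half-up to 2 decimals
  (`percent_round()`); the worked example's "66%" for 10/15 uses integer
  truncation (`percent_trunc()`). Both renderings are exposed.

The 95% CI is Wald: `p ± 1.96·√(p(1−p)/n)`, clipped to `[0, 1]` (the
published clipped lower bound 0.00 for the rarest sign confirms clipping
rather than a score interval). Recomputation of the published table shows it
mixes two variants of this formula: the per-sign rows match only when the CI
is computed from the proportion *rounded to the printed 2-decimal percent*
(23 of 24 rows exactly), while the pooled total row matches only the *exact*
proportion. `agreement_row()` therefore takes
`ci_proportion = c("rounded", "exact")`, defaulting to `"rounded"`;
`agreement_table()` uses `"exact"` for its pooled total. One published upper
bound (25.50 for the fluid-collection row; we compute 25.49) is
irreproducible under any single convention — a documented internal
inconsistency of the source table, not an implementation defect. The same
row's printed counts are inconsistent with its own percentage and CI;
`table4_counts()` carries the unique correction (4 agreements, 26
disagreements, 2 images) consistent with the row's percentage, its CI and
the pooled total.

### Precision

Precision is `|relevant ∩ observed| / |observed|` per image-observer unit,
micro-averaged (summed intersections over summed observations), against a
per-image gold standard; units with empty observed sets drop out of the
average, and recall is out of scope by design. Whether the original
evaluation aggregated per image or per case is not stated; per image is
implemented because the gold standard is naturally per image.

## Synthetic data

`generate_random_kb()` draws a DAG taxonomy top-down under six roots, plants
restrictions on sign concepts and appends defined classes whose genus may be
an earlier defined class (so classification must cascade). Defaults
(60 concepts, ≤2 parents, 3 defined classes, restriction density 0.3 per
three trials) are sized to the fixture scale, an order of magnitude below
the production ontology, to keep thousand-trial property tests fast; the
oracle-equivalence tests also run at 200 concepts. Ground truth is recorded
*during generation* (planted ancestor sets) and by a naive order-free set
evaluation of the defined classes, structurally independent of the
reasoner's vectorized fixpoint. A drawn world in which two defined classes
are mutually subsuming is rejected and deterministically redrawn from a
derived seed, since the data model treats that as a cycle.

`generate_session()` emulates the evaluation design: a panel of `x`
observers (default 6, graded 3/2/1 senior / senior-registrar / registrar), a
gold standard drawn per image with sign prevalence `prevalence` (default
0.3), and independent observers marking a present sign with probability
`sensitivity` (default 0.9) and an absent one with `fp_rate` (default 0.05).
Defaults are the regimes exercised in the acceptance criteria; prevalence
0.3 reflects that a typical image shows a minority of the sign inventory.
Observer errors are independent across observers, images and signs — the
simplest model consistent with the design. Real annotation data are *not*
like this in at least three ways: observers are correlated (shared training,
the application's own suggestions), sensitivity varies by sign salience and
observer grade, and gold standards derived from reports are themselves
imperfect. A green parameter-recovery test therefore establishes that the
statistics recover the parameters *of this model* (pooled
`p_a → s²/(1−(1−s)^x)` under the inclusion rule, so `√p_a ≈ s`; precision →
the analytic PPV `πs/(πs+(1−π)f)`), not that real inter-observer agreement
behaves this way.

The mini fixture (`build_mini_epo()`) contains only content the source
material prints — the 24 evaluated signs plus the interstitial line sign,
the four implantation-site types (with tubal subtypes), the ring-of-fire
relation set and reference annotation, the four defined sign categories —
about 59 concepts; it does not invent the remaining ~1,300 concepts of the
production ontology, and fixture tests assert manifest counts, never
production-ontology metrics. Identifiers are stable hashes of the English
preferred labels (`mini_epo_id()`), with the two root identifiers fixed to
their production values so the suggestion query's constants are real.

## Numerical and procedural choices

* Half-up rounding is implemented with an epsilon guard
  (`floor(x·10^d + 0.5 + 1e-9)`), since binary floats under-represent some
  decimal midpoints.
* All orderings are deterministic: radix (C-locale) sorts on identifiers,
  case-insensitive label sorts with identifier tie-breaks, canonical axiom
  keys. Re-running any inference or query is bitwise stable.
* Degenerate inputs: zero trials in `agreement_row()` is an error; `k = 0`
  contributes `(0, C(x,2))`; an empty query matches nothing; an empty
  selection suggests nothing; a sign never annotated yields an empty
  matrix, not a zero row.
* Generators save and restore the caller's RNG state and are pure functions
  of their parameters and seed.

## Known limitations

* The Turtle reader handles the documented subset only; it is not a general
  RDF parser (no blank-node subjects at top level, no datatyped semantics —
  typed literals are read as plain text).
* The reasoner is bounded by the EL fragment above; knowledge bases relying
  on richer OWL constructs must be reduced before import (unsupported
  constructs are skipped with a warning).
* The category of a concept is derived from its ancestry, so a concept
  reachable from two category roots takes the first of
  sign/disorder/anatomy/technical; the fixture and generators never produce
  such overlaps.
* Published aggregate results that depend on undistributed inputs (the
  clinical image set and its reports, the full production ontology) are not
  reproduced; they are replaced by property tests on synthetic data with
  known ground truth.
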