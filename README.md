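# epokb

A sign-centric knowledge-base engine for the annotation of ultrasound images
of ectopic pregnancy, with the evaluation statistics used to assess such
annotation systems.

Ectopic pregnancy — implantation of a gestational sac outside the endometrial
cavity — is diagnosed by transvaginal ultrasound, and the timing of the
diagnosis depends heavily on the operator's ability to recognize the relevant
imaging signs ("ring of fire", "tubal ring", ...). A knowledge base that
links each sign to the types of ectopic pregnancy it suggests, the anatomical
structures involved and the technical elements of image acquisition
(examination route, mode, echographic view) can drive an annotation
application that searches terms, suggests further signs and serves reference
images. `epokb` implements that whole stack natively in R, for
knowledge engineers and clinical-informatics researchers who want to build,
reason over and evaluate such resources without a triple store or an OWL
reasoner:

* **Data model and I/O** — concepts with SKOS-style multilingual labels and
  definitions, provenance annotations (PMID, reference-image path, FMA
  mapping), a fixed object-property hierarchy
  (`suggests`, `hasLocation`, `requires` ⊒ `requiresRoute` / `requiresMode` /
  `requiresView`), and axioms: asserted subsumption (a DAG, multiple parents
  allowed), existential restrictions `∃p.C`, defined classes
  `D ≡ G ⊓ ∃p₁.C₁ ⊓ …`, and disjointness. Serialized to a native JSON format
  (schemas in `inst/extdata/`) and to a documented Turtle subset.
* **Reasoner** — an EL-style engine: reflexive-transitive subsumption closure
  `⊑*`, defined-class classification to fixpoint (a sign carrying
  `requiresMode some "color Doppler mode (2D)"` is automatically classified
  under the defined class "color Doppler sign"), materialization of inherited
  sign relations with provenance, and disjointness consistency checking.
* **Suggestion queries** — ectopic-pregnancy types for selected signs
  (the at-least-one-sign semantics of the original application's SPARQL rule,
  reported at the granularity of direct children of the ectopic-pregnancy
  root), signs for types, per-sign profiles, reference images, and the
  competency questions (implantation sites; structures visible in a view).
* **Evaluation statistics** — for a panel of *x* observers of whom *k*
  annotated a sign on an image, agreements are the concordant-positive pairs
  `k(k−1)/2` out of `n = x(x−1)/2` trials; the proportion of agreement
  `p_a = Σ agreements / Σ trials` is pooled over images and reported with a
  Wald 95% CI `p ± 1.96·√(p(1−p)/n)` clipped to [0, 1]. Precision is the
  information-retrieval ratio `|relevant ∩ observed| / |observed|`,
  micro-averaged over image-observer units against a report-derived gold
  standard.
* **Fixtures and simulators** — a deterministic mini knowledge base
  reconstructed from published content, the published 24-row agreement table
  as data (with a faithful session reconstruction), and seeded generators for
  random knowledge bases (with planted ground truth) and annotation sessions
  (gold prevalence, per-observer sensitivity and false-positive rate).

## Worked example

```r
library(epokb)

kb  <- build_mini_epo()
cl  <- compute_closure(kb)
rel <- materialize_relations(kb, cl)

rof <- kb_concept_by_label(kb, "ring of fire sign")
suggest_types_for_signs(kb, rel, rof, closure = cl)
#>                  id           label                                  definition
#> 1 epo:OPPIO_8f5edf9 tubal pregnancy Ectopic pregnancy implanted in the fallo...
```

The ring-of-fire sign suggests tubal pregnancy: its asserted `suggests`
restriction points at the "tubal pregnancy" concept, which the query reports
because it sits one subsumption step under the ectopic-pregnancy root.
Classification works the other way round too — because the sign asserts
`requiresMode some "color Doppler mode (2D)"` and that mode is subsumed by
"color Doppler mode", `classify_defined(kb)` places it under the defined
class "color Doppler sign" (and under "tubal pregnancy sign", and — since the
2D Doppler mode is also a 2D mode — under "2D ultrasound sign").

Agreement statistics reproduce the published evaluation exactly. A sign
annotated on 4 images with 48 concordant and 12 discordant observer pairs:

```r
agreement_row(48, 12)
#> p_a 80.00% [69.88% - 90.12%] (48/60 pairs)

cp <- concordant_pairs(5, 6)   # 5 of 6 observers mark a sign on one image
#> $agreements [1] 10   $trials [1] 15
percent_trunc(cp$agreements / cp$trials)
#> [1] 66
```

Rebuilding the full published agreement table from a reconstructed session
(`table4_reproduction()`) ends with the pooled total row

```
  sign agreements disagreements images   pct pct_ci_low pct_ci_high
 Total       1283          1897    212 40.35      38.64       42.05
```

i.e. a total proportion of agreement of 40.35% [38.64–42.05]. Simulated
sessions close the loop: with per-observer sensitivity `s` and no false
positives, the pooled `p_a` concentrates near `s²` (two independent observers
must both mark the sign), and `sqrt(p_a)` recovers `s`; with false positives,
micro-precision matches the analytic positive predictive value.

## Command line

```sh
epokb fixture mini-epo --out kb.json
epokb validate kb.json
epokb infer kb.json --out relations.csv
epokb suggest --kb kb.json --signs epo:OPPIO_b29ce4e
epokb sim session --kb kb.json --images 200 --seed 13 --out session.json
epokb eval agreement --session session.json
```

(The `epokb` script is installed under `inst/exec/`; equivalently call
`epokb_cli(c("validate", "kb.json"))` from R.)

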