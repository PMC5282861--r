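Package: epokb
Title: Sign-Centric Knowledge Base Engine for Ectopic Pregnancy Ultrasound
    Image Annotation
Version: 0.1.0
Authors@R:
    person("EPO", "Maintainers", email = "epokb@example.org", role = c("aut", "cre"))
Description: An engine for sign-centric biomedical knowledge bases of the kind
    used to annotate ultrasound images of ectopic pregnancy. Provides an
    ontology data model (concepts with SKOS-style multilingual labels and
    definitions, a fixed object-property hierarchy, subsumption, existential
    restrictions, defined classes and disjointness) with JSON and Turtle-subset
    serialization; a lightweight EL-style subsumption reasoner that classifies
    defined classes, materializes inherited sign relations and checks
    disjointness consistency; a suggestion query layer (ectopic-pregnancy types
    for selected signs, signs for types, sign profiles, reference images,
    competency questions); annotation-session storage with report-derived gold
    standards; and the evaluation statistics used for semantic image
    annotation studies: information-retrieval precision and the multi-observer
    proportion of agreement with Wald 95% confidence intervals. Deterministic
    fixtures and seeded synthetic generators make every component testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
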