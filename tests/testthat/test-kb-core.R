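# kb_core: data model, validation, serialization, search

test_that("mini-EPO fixture validates cleanly and contains the ring of fire", {
  kb <- build_mini_epo()
  expect_identical(nrow(validate_kb(kb)), 0L)
  id <- kb_concept_by_label(kb, "ring of fire sign")
  expect_identical(id, mini_epo_id("ring of fire sign"))
  expect_match(id, "^epo:OPPIO_[0-9a-f]{7}$")
  # validate_kb is idempotent and side-effect free
  before <- kb_normalize(kb)
  invisible(validate_kb(kb))
  expect_identical(kb_normalize(kb), before)
})

test_that("validation reports cycles, dangling references and missing annotations", {
  a <- sign_concept("t:a", "alpha"); b <- sign_concept("t:b", "beta")
  kb <- tiny_kb(list(a, b),
                list(ax_subclass("t:a", "t:b"), ax_subclass("t:b", "t:a"),
                     ax_subclass("t:a", "t:S")))
  iss <- validate_kb(kb)
  expect_true("subsumption_cycle" %in% iss$code)
  expect_match(iss$subject[iss$code == "subsumption_cycle"], "t:a")
  expect_match(iss$subject[iss$code == "subsumption_cycle"], "t:b")

  # dangling reference
  kb2 <- tiny_kb(list(a), list(ax_subclass("t:a", "t:ghost")))
  expect_true("dangling_reference" %in% validate_kb(kb2)$code)

  # sign concept without an English definition
  nodef <- epo_concept("t:n", c(en = "naked sign"))
  kb3 <- tiny_kb(list(nodef), list(ax_subclass("t:n", "t:S")))
  iss3 <- validate_kb(kb3)
  expect_true("missing_annotation" %in% iss3$code)
  expect_true("t:n" %in% iss3$subject)

  # declared roots must exist: an empty concept set cannot be loaded
  f <- tempfile(fileext = ".json")
  empty <- tiny_kb()
  empty$concepts <- empty$concepts["t:S"]   # drop all but one root
  save_kb(empty, f)
  expect_error(load_kb(f), class = "epokb_validation_error")

  # unreachable concept
  orphan <- epo_concept("t:o", c(en = "orphan"))
  kb4 <- tiny_kb(list(orphan), list())
  expect_true("unreachable" %in% validate_kb(kb4)$code)
})

test_that("native JSON round-trip is the identity and saves are byte-identical", {
  for (sd in c(1, 2)) {
    kb <- random_kb_case(sd)$kb
    f <- tempfile(fileext = ".json")
    save_kb(kb, f)
    kb2 <- load_kb(f)
    expect_true(kb_equal(kb, kb2))
    b1 <- readBin(f, "raw", file.size(f))
    save_kb(kb2, f)
    expect_identical(readBin(f, "raw", file.size(f)), b1)
  }
  kb <- build_mini_epo()
  f <- tempfile(fileext = ".json")
  save_kb(kb, f)
  expect_true(kb_equal(kb, load_kb(f)))
})

test_that("Turtle export emits the documented subset and round-trips the closure", {
  kb <- build_mini_epo()
  f <- tempfile(fileext = ".ttl")
  save_kb(kb, f)
  ttl <- readLines(f)
  expect_true(any(grepl("owl:Restriction", ttl) & grepl("owl:onProperty epo:requiresMode", ttl)))
  expect_true(any(grepl("owl:intersectionOf", ttl)))
  expect_true(any(grepl("\"18936028\"", ttl)))

  cases <- c(list(kb), lapply(c(4, 9), function(sd) random_kb_case(sd)$kb))
  for (k in cases) {
    f <- tempfile(fileext = ".ttl")
    save_kb(k, f)
    k2 <- load_kb(f)
    cl1 <- compute_closure(k, validate = FALSE)
    cl2 <- compute_closure(k2, validate = FALSE)
    expect_setequal(names(cl1$ancestors), names(cl2$ancestors))
    for (id in names(cl1$ancestors))
      expect_setequal(cl1$ancestors[[id]], cl2$ancestors[[id]])
    r1 <- materialize_relations(k, cl1)
    r2 <- materialize_relations(k2, cl2)
    expect_identical(paste(r1$subject, r1$property, r1$object),
                     paste(r2$subject, r2$property, r2$object))
  }
})

test_that("Turtle import skips constructs outside the subset with a warning", {
  kb <- build_mini_epo()
  f <- tempfile(fileext = ".ttl")
  save_kb(kb, f)
  extra <- c(readLines(f),
             "epo:OPPIO_0000189 owl:sameAs epo:OPPIO_c000016 .",
             "epo:OPPIO_0000189 rdfs:seeAlso \"elsewhere\" .")
  writeLines(extra, f)
  expect_warning(kb2 <- load_kb(f), "skipped")
  expect_identical(sort(names(kb2$concepts)), sort(names(kb$concepts)))
  # foreign triples dropped, deductive content intact
  cl1 <- compute_closure(kb); cl2 <- compute_closure(kb2)
  for (id in names(cl1$ancestors))
    expect_setequal(cl1$ancestors[[id]], cl2$ancestors[[id]])
})

test_that("malformed files give format errors with context", {
  f <- tempfile(fileext = ".ttl")
  writeLines("epo:x a owl:Class", f)   # missing final dot
  expect_error(load_kb(f), class = "epokb_format_error")
  fj <- tempfile(fileext = ".json")
  writeLines("{not json", fj)
  expect_error(load_kb(fj), class = "epokb_format_error")
  expect_error(load_kb(tempfile(fileext = ".json")), class = "epokb_io_error")
})

test_that("search ranks exact preferred labels first, then prefix, then substring", {
  kb <- build_mini_epo()
  res <- search_terms(kb, "ring of f")
  expect_identical(res$label[1], "ring of fire sign")
  full <- search_terms(kb, "ring of fire sign")
  expect_identical(full$match[1], "exact")
  # substring ranks below prefix
  sub <- search_terms(kb, "ring", limit = 20)
  expect_true(all(diff(match(sub$match, c("exact", "prefix", "substring"))) >= 0))
  expect_true(mini_epo_id("tubal ring sign") %in% sub$id)
  # alternative-label-only match is retrieved
  alt <- search_terms(kb, "frimbrial")
  expect_identical(alt$id, mini_epo_id("fimbrial portion"))
  # French search never returns concepts without a French label
  fr <- search_terms(kb, "signe", lang = "fr", limit = 50)
  expect_identical(fr$id, mini_epo_id("ring of fire sign"))
  expect_identical(nrow(search_terms(kb, "")), 0L)
  expect_identical(nrow(search_terms(kb, "ring", limit = 1)), 1L)
  expect_error(search_terms(kb, "x", lang = "de"), class = "epokb_language_error")
})
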