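# reasoner: closure, classification, materialization, consistency

test_that("closure is reflexive and transitive on a chain", {
  a <- sign_concept("t:a", "a"); b <- sign_concept("t:b", "b")
  c <- sign_concept("t:c", "c")
  kb <- tiny_kb(list(a, b, c),
                list(ax_subclass("t:a", "t:b"), ax_subclass("t:b", "t:c"),
                     ax_subclass("t:c", "t:S")))
  cl <- compute_closure(kb)
  expect_setequal(cl$ancestors[["t:a"]], c("t:a", "t:b", "t:c", "t:S"))
  expect_setequal(cl$ancestors[["t:S"]], "t:S")   # reflexivity
})

test_that("compute_closure rejects cyclic input", {
  a <- sign_concept("t:a", "a"); b <- sign_concept("t:b", "b")
  kb <- tiny_kb(list(a, b),
                list(ax_subclass("t:a", "t:b"), ax_subclass("t:b", "t:a"),
                     ax_subclass("t:a", "t:S")))
  expect_error(compute_closure(kb), class = "epokb_validation_error")
  expect_error(compute_closure(kb, validate = FALSE), class = "epokb_cycle_error")
})

test_that("mini-EPO classification matches the published examples", {
  kb <- build_mini_epo()
  de <- classify_defined(kb)
  rof <- mini_epo_id("ring of fire sign")
  parents <- de$parent[de$child == rof]
  expect_true(mini_epo_id("color Doppler sign") %in% parents)
  expect_true(mini_epo_id("tubal pregnancy sign") %in% parents)
  expect_true(mini_epo_id("2D ultrasound sign") %in% parents)
  # a sign with no restrictions gains no defined-class parents
  plain <- mini_epo_id("endometrial trilaminar pattern")
  expect_false(plain %in% de$child)
})

test_that("property subsumption applies in classification and materialization", {
  # defined class stated over the parent property `requires` is matched by a
  # sign carrying the child property `requiresMode`
  m <- epo_concept("t:m", c(en = "mode m"))
  s <- sign_concept("t:x", "sign x")
  d <- sign_concept("t:d", "technical sign")
  kb <- tiny_kb(list(m, s, d),
                list(ax_subclass("t:m", "t:R2"),
                     ax_subclass("t:x", "t:S"),
                     ax_restriction("t:x", "requiresMode", "t:m"),
                     ax_defined("t:d", "t:S",
                                list(list(property = "requires", filler = "t:R2")))))
  de <- classify_defined(kb)
  expect_identical(de$child[de$parent == "t:d"], "t:x")
  rel <- materialize_relations(kb, compute_closure(kb))
  expect_true(any(rel$subject == "t:x" & rel$property == "requires" &
                    rel$object == "t:m"))
})

test_that("materialization propagates to descendants and is empty without restrictions", {
  kb <- build_mini_epo()
  rof <- mini_epo_id("ring of fire sign")
  child <- sign_concept("epo:OPPIO_child01", "planted child sign")
  kb$concepts[[child$id]] <- child
  kb$axioms <- c(kb$axioms, list(ax_subclass(child$id, rof)))
  cl <- compute_closure(kb)
  rel <- materialize_relations(kb, cl)
  expect_true(any(rel$subject == child$id & rel$property == "suggests" &
                    rel$object == mini_epo_id("tubal pregnancy")))
  prov <- rel$provenance[rel$subject == child$id & rel$property == "suggests" &
                           rel$object == mini_epo_id("tubal pregnancy")]
  expect_identical(prov, paste0("inherited_from:", rof))

  bare <- tiny_kb(list(sign_concept("t:x", "x")), list(ax_subclass("t:x", "t:S")))
  expect_identical(nrow(materialize_relations(bare, compute_closure(bare))), 0L)
})

test_that("closure, classification and materialization equal their oracles", {
  for (sd in 1:40) {
    g <- random_kb_case(sd)
    kb <- g$kb
    cl <- compute_closure(kb, validate = FALSE)
    orc <- oracle_infer(kb)
    # closure vs boolean matrix reachability
    for (id in names(cl$ancestors))
      expect_setequal(cl$ancestors[[id]], colnames(orc$M)[orc$M[id, ]])
    # classification vs exhaustive check, and vs the generator's planted truth
    de <- classify_defined(kb, validate = FALSE)
    expect_identical(de[, c("child", "parent")], orc$members)
    for (d in names(g$ground_truth$defined_members))
      expect_identical(sort(de$child[de$parent == d]),
                       g$ground_truth$defined_members[[d]])
    # materialization vs nested-loop enumeration
    rel <- materialize_relations(kb, cl)
    expect_identical(paste(rel$subject, rel$property, rel$object),
                     oracle_materialize(kb, orc$M))
  }
})

test_that("inference is idempotent and classification is monotone", {
  g <- random_kb_case(17)
  kb <- g$kb
  cl1 <- compute_closure(kb, validate = FALSE)
  rel1 <- materialize_relations(kb, cl1)
  cl2 <- compute_closure(kb, validate = FALSE)
  expect_identical(cl1$edges, cl2$edges)
  expect_identical(rel1, materialize_relations(kb, cl2))

  # adding an asserted restriction never removes a membership
  de1 <- classify_defined(kb, validate = FALSE)
  cats <- kb_categories(kb)
  sign_ids <- setdiff(names(cats)[cats == "sign"], kb$roots$sign)
  anat <- names(cats)[cats == "anatomy"][1]
  kb$axioms <- c(kb$axioms,
                 list(ax_restriction(sign_ids[1], "hasLocation", anat)))
  de2 <- classify_defined(kb, validate = FALSE)
  expect_true(all(paste(de1$child, de1$parent) %in% paste(de2$child, de2$parent)))
})

test_that("consistency checking flags exactly the planted violations", {
  kb <- build_mini_epo()
  cl <- compute_closure(kb)
  expect_identical(nrow(check_consistency(kb, cl)), 0L)

  # plant a concept under two disjoint types
  bad <- epo_concept("epo:OPPIO_badbad1", c(en = "impossible type"))
  kb$concepts[[bad$id]] <- bad
  kb$axioms <- c(kb$axioms,
                 list(ax_subclass(bad$id, mini_epo_id("tubal pregnancy")),
                      ax_subclass(bad$id, mini_epo_id("cervical pregnancy"))))
  rep <- check_consistency(kb, compute_closure(kb))
  expect_identical(unique(rep$concept), bad$id)
  expect_identical(nrow(rep), 1L)

  # disjointness without a common descendant is consistent
  x <- sign_concept("t:x", "x"); y <- sign_concept("t:y", "y")
  kb2 <- tiny_kb(list(x, y),
                 list(ax_subclass("t:x", "t:S"), ax_subclass("t:y", "t:S"),
                      ax_disjoint(c("t:x", "t:y"))))
  expect_identical(nrow(check_consistency(kb2, compute_closure(kb2))), 0L)
})
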