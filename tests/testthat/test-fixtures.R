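# fixtures: mini-EPO manifest, generators, planted ground truth

test_that("the built fixture matches its manifest field for field", {
  kb <- build_mini_epo()
  man <- mini_epo_manifest()
  expect_identical(length(kb$concepts), man$n_concepts)
  cats <- kb_categories(kb)
  expect_identical(sum(cats == "sign"), man$n_signs)
  defined <- vapply(Filter(function(a) a$kind == "equivalent_to_definition",
                           kb$axioms), `[[`, character(1), "class")
  expect_identical(sum(cats == "sign") - length(defined) - 1L,
                   man$n_primitive_signs)
  expect_identical(kb$roots$sign, man$sign_root)
  expect_identical(kb$roots$disorder, man$disorder_root)
  kinds <- vapply(kb$axioms, `[[`, character(1), "kind")
  expect_identical(table(kinds)[names(man$axiom_counts)],
                   as.table(man$axiom_counts)[names(man$axiom_counts)],
                   ignore_attr = TRUE)
  expect_identical(sum(lengths(lapply(kb$concepts, `[[`, "pmids"))),
                   as.integer(man$n_pmid_annotations))
  expect_identical(sum(lengths(lapply(kb$concepts, `[[`, "image_paths"))),
                   as.integer(man$n_image_annotations))
  # defined memberships recorded in the manifest hold exactly
  de <- classify_defined(kb)
  for (d in names(man$defined_memberships)) {
    got <- sort(vapply(de$child[de$parent == mini_epo_id(d)],
                       function(i) kb_pref_label(kb, i), character(1),
                       USE.NAMES = FALSE))
    expect_identical(got, man$defined_memberships[[d]])
  }
  # top-level disorder inventory
  cl <- compute_closure(kb)
  sites <- implantation_sites(kb, closure = cl)
  expect_identical(sort(sites$id), man$top_disorders)
})

test_that("builders and generators are deterministic", {
  expect_true(kb_equal(build_mini_epo(), build_mini_epo()))
  g1 <- generate_random_kb(n_concepts = 40, seed = 1)
  g2 <- generate_random_kb(n_concepts = 40, seed = 1)
  expect_true(kb_equal(g1$kb, g2$kb))
  expect_identical(g1$ground_truth, g2$ground_truth)
  g3 <- generate_random_kb(n_concepts = 40, seed = 2)
  expect_false(kb_equal(g1$kb, g3$kb))
  kb <- build_mini_epo()
  s1 <- generate_session(kb, n_images = 10, seed = 4)
  s2 <- generate_session(kb, n_images = 10, seed = 4)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$gold, s2$gold)
  # generators restore the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(generate_session(kb, n_images = 5, seed = 8))
  expect_identical(.Random.seed, before)
})

test_that("zero restriction density materializes nothing", {
  g <- generate_random_kb(n_concepts = 30, n_defined = 0,
                          restriction_density = 0, seed = 6)
  rel <- materialize_relations(g$kb, compute_closure(g$kb, validate = FALSE))
  expect_identical(nrow(rel), 0L)
})

test_that("session marginals match the requested probabilities", {
  kb <- build_mini_epo()
  # 25 primitive signs x 6 observers x n images; >= 10,000 Bernoulli draws
  s <- generate_session(kb, n_images = 80, sensitivity = 0.8, fp_rate = 0.05,
                        prevalence = 0.3, seed = 21)
  cats <- kb_categories(kb)
  defined <- vapply(Filter(function(a) a$kind == "equivalent_to_definition",
                           kb$axioms), `[[`, character(1), "class")
  signs <- setdiff(names(cats)[cats == "sign"], c(kb$roots$sign, defined))
  n_cells <- 80 * length(signs)
  n_gold <- sum(lengths(s$gold))
  tol <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(n_gold / n_cells - 0.3), tol(0.3, n_cells))

  gold_key <- unlist(lapply(names(s$gold), function(i)
    paste(i, s$gold[[i]])), use.names = FALSE)
  ann_key <- paste(s$annotations$image_id, s$annotations$concept)
  hits <- sum(ann_key %in% gold_key)              # marks on truly present signs
  sens_hat <- hits / (6 * n_gold)
  expect_lt(abs(sens_hat - 0.8), tol(0.8, 6 * n_gold))
  fp_hat <- (nrow(s$annotations) - hits) / (6 * (n_cells - n_gold))
  expect_lt(abs(fp_hat - 0.05), tol(0.05, 6 * (n_cells - n_gold)))
})

test_that("the noiseless limit gives perfect precision and unanimity", {
  kb <- build_mini_epo()
  s <- generate_session(kb, n_images = 15, sensitivity = 1, fp_rate = 0,
                        prevalence = 0.4, seed = 9)
  expect_identical(precision_report(s)$overall$precision, 1)
  tab <- agreement_table(s, sort(unique(s$annotations$concept)))
  expect_true(all(tab$pct == 100))
})

test_that("probability arguments are checked", {
  kb <- build_mini_epo()
  expect_error(generate_session(kb, sensitivity = 1.2),
               class = "epokb_domain_error")
  expect_error(generate_session(kb, n_observers = 1),
               class = "epokb_domain_error")
  expect_error(generate_random_kb(n_concepts = 3),
               class = "epokb_domain_error")
})

test_that("the reconstructed evaluation session matches the printed counts", {
  kb <- build_mini_epo()
  s <- build_table4_session(kb)
  counts <- table4_counts()
  expect_identical(nrow(s$observers), 6L)
  expect_identical(sort(table(s$observers$grade), decreasing = TRUE),
                   sort(table(c(rep("senior", 3), rep("senior_registrar", 2),
                                "registrar")), decreasing = TRUE),
                   ignore_attr = TRUE)
  for (i in c(1, 9, 14, 24)) {   # spot rows incl. ring of fire, tubal ring
    sg <- kb_concept_by_label(kb, tolower(counts$sign[i]))
    m <- annotation_matrix(s, sg)
    expect_identical(nrow(m), counts$images[i])
    expect_identical(sum(choose(m$k, 2)), counts$agreements[i] + 0)
    expect_identical(sum(choose(m$x, 2) - choose(m$k, 2)),
                     counts$disagreements[i] + 0)
  }
})
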