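# suggestion: query layer and competency questions

mini <- build_mini_epo()
mini_cl <- compute_closure(mini)
mini_rel <- materialize_relations(mini, mini_cl)

test_that("selected signs suggest their ectopic-pregnancy types", {
  rof <- mini_epo_id("ring of fire sign")
  st <- suggest_types_for_signs(mini, mini_rel, rof, closure = mini_cl)
  expect_identical(st$label, "tubal pregnancy")
  expect_false(any(is.na(st$definition)))
  expect_identical(nrow(suggest_types_for_signs(mini, mini_rel, character(0),
                                                closure = mini_cl)), 0L)
  expect_error(
    suggest_types_for_signs(mini, mini_rel, mini_epo_id("uterus"),
                            closure = mini_cl),
    class = "epokb_selection_error")
})

test_that("type suggestions are monotone, duplicate-free and stable", {
  cats <- kb_categories(mini)
  signs <- setdiff(names(cats)[cats == "sign"], mini$roots$sign)
  sel <- character(0)
  prev <- character(0)
  for (s in signs) {
    sel <- c(sel, s)
    st <- suggest_types_for_signs(mini, mini_rel, sel, closure = mini_cl)
    expect_true(all(prev %in% st$id))          # monotone
    expect_identical(anyDuplicated(st$id), 0L) # DISTINCT
    again <- suggest_types_for_signs(mini, mini_rel, sel, closure = mini_cl)
    expect_identical(st, again)                # stable
    prev <- st$id
  }
  # ordered by label
  expect_identical(prev, prev[order(tolower(vapply(prev, function(i)
    kb_pref_label(mini, i), character(1))), prev, method = "radix")])
})

test_that("signs are suggested for types, with exclusions", {
  tubal <- mini_epo_id("tubal pregnancy")
  ss <- suggest_signs_for_types(mini, mini_rel, tubal, closure = mini_cl)
  expect_true(all(c("ring of fire sign", "tubal ring sign") %in% ss$label))
  ex <- suggest_signs_for_types(mini, mini_rel, tubal,
                                exclude = mini_epo_id("ring of fire sign"),
                                closure = mini_cl)
  expect_false("ring of fire sign" %in% ex$label)
  # the fixture's planted cervical sign set is the manifest's
  cs <- suggest_signs_for_types(mini, mini_rel, mini_epo_id("cervical pregnancy"),
                                closure = mini_cl)
  man <- mini_epo_manifest()
  expect_true(all(vapply(man$signs_by_type[["cervical pregnancy"]],
                         mini_epo_id, character(1)) %in% cs$id))
  expect_identical(nrow(suggest_signs_for_types(mini, mini_rel, character(0),
                                                closure = mini_cl)), 0L)
})

test_that("the ring-of-fire profile matches its published relation set", {
  rof <- mini_epo_id("ring of fire sign")
  pr <- sign_profile(mini, mini_rel, rof, closure = mini_cl)
  lab <- function(ids) sort(vapply(ids, function(i) kb_pref_label(mini, i),
                                   character(1), USE.NAMES = FALSE))
  expect_identical(lab(pr$suggests), "tubal pregnancy")
  expect_identical(lab(pr$locations),
                   sort(c("ampulla", "tubal isthmus", "fimbrial portion")))
  expect_identical(lab(pr$routes), "vaginal route")
  expect_identical(lab(pr$modes), "color Doppler mode (2D)")
  expect_identical(lab(pr$views), "adnexal area view")

  # a planted child inherits the same profile
  kb <- mini
  kb$concepts[["epo:OPPIO_child01"]] <-
    sign_concept("epo:OPPIO_child01", "planted child sign")
  kb$axioms <- c(kb$axioms, list(ax_subclass("epo:OPPIO_child01", rof)))
  cl <- compute_closure(kb)
  rel <- materialize_relations(kb, cl)
  ch <- sign_profile(kb, rel, "epo:OPPIO_child01", closure = cl)
  for (f in c("suggests", "locations", "routes", "modes", "views"))
    expect_identical(ch[[f]], pr[[f]])

  # a sign with no relations has an all-empty profile
  none <- sign_profile(mini, mini_rel, mini_epo_id("intact endometrial midline echo"),
                       closure = mini_cl)
  expect_identical(lengths(none[c("suggests", "locations", "routes", "modes",
                                  "views")]),
                   c(suggests = 0L, locations = 0L, routes = 0L, modes = 0L,
                     views = 0L))
})

test_that("reference images return the sign's own annotations", {
  ri <- reference_images(mini, mini_epo_id("ring of fire sign"))
  expect_true("18936028" %in% ri$pmid)
  expect_true(any(!is.na(ri$image_path)))
  expect_identical(nrow(reference_images(mini, mini_epo_id("tubal ring sign"))), 0L)
  expect_error(reference_images(mini, "epo:OPPIO_nothere"),
               class = "epokb_lookup_error")
  man <- mini_epo_manifest()
  all_ri <- do.call(rbind, lapply(names(mini$concepts),
                                  function(i) reference_images(mini, i)))
  expect_identical(sum(!is.na(all_ri$pmid)), man$n_pmid_annotations)
  expect_identical(sum(!is.na(all_ri$image_path)), man$n_image_annotations)
})

test_that("competency questions are answered from the knowledge base", {
  sites <- implantation_sites(mini, closure = mini_cl)
  expect_true(all(c("tubal pregnancy", "cervical pregnancy",
                    "interstitial pregnancy",
                    "cesarean section scar pregnancy") %in% sites$label))
  # tubal subtypes are two steps down, not implantation sites at this level
  expect_false("ampullary pregnancy" %in% sites$label)

  v <- structures_in_view(mini, mini_rel, mini_epo_id("adnexal area view"),
                          closure = mini_cl)
  expect_true(all(c("ampulla", "tubal isthmus", "fimbrial portion") %in% v$label))
  empty <- structures_in_view(mini, mini_rel,
                              mini_epo_id("longitudinal view of the uterus"),
                              closure = mini_cl)
  expect_identical(nrow(empty), 0L)
  expect_error(structures_in_view(mini, mini_rel, mini_epo_id("uterus"),
                                  closure = mini_cl),
               class = "epokb_selection_error")

  nodis <- tiny_kb(list(sign_concept("t:x", "x")), list(ax_subclass("t:x", "t:S")))
  expect_identical(nrow(implantation_sites(nodis)), 0L)
})

test_that("type suggestion equals the nested-loop query oracle on random KBs", {
  set.seed(3)
  for (trial in 1:15) {
    g <- random_kb_case(trial + 100L, n = 10 + trial * 3L)
    kb <- g$kb
    cl <- compute_closure(kb, validate = FALSE)
    rel <- materialize_relations(kb, cl)
    cats <- kb_categories(kb)
    signs <- setdiff(names(cats)[cats == "sign"], kb$roots$sign)
    if (!length(signs)) next
    sel <- sample(signs, min(length(signs), 1 + trial %% 4))
    got <- suggest_types_for_signs(kb, rel, sel, closure = cl)
    want <- oracle_suggest_types(kb, sel, oracle_infer(kb)$M)
    expect_identical(got$id, want)
    # single-sign suggestion agrees with the profile generalized to types
    pr <- sign_profile(kb, rel, sel[1], closure = cl)
    one <- suggest_types_for_signs(kb, rel, sel[1], closure = cl)
    desc_objs <- unique(unlist(lapply(pr$suggests, function(o)
      cl$ancestors[[o]])))
    expect_true(all(one$id %in% c(desc_objs, pr$suggests)))
  }
})
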