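# metrics: concordant pairs, agreement rows, pooling, precision

test_that("concordant pairs follow k(k-1)/2 over x(x-1)/2", {
  expect_identical(concordant_pairs(5, 6), list(agreements = 10L, trials = 15L))
  expect_identical(concordant_pairs(0, 6), list(agreements = 0L, trials = 15L))
  expect_identical(concordant_pairs(6, 6), list(agreements = 15L, trials = 15L))
  expect_error(concordant_pairs(7, 6), class = "epokb_domain_error")
  expect_error(concordant_pairs(2, 1), class = "epokb_domain_error")
})

test_that("agreement rows render the published percentages and intervals", {
  r <- agreement_row(48, 12)
  expect_identical(c(r$pct, r$pct_ci_low, r$pct_ci_high), c(80.00, 69.88, 90.12))
  r <- agreement_row(1, 149)      # lower bound clipped from negative
  expect_identical(c(r$pct, r$pct_ci_low, r$pct_ci_high), c(0.67, 0.00, 1.98))
  expect_identical(r$ci_low, 0)
  r <- agreement_row(15, 0)       # unanimity: zero-width interval
  expect_identical(c(r$pct, r$pct_ci_low, r$pct_ci_high), c(100, 100, 100))
  expect_error(agreement_row(0, 0), class = "epokb_domain_error")
  # worked-example rendering: 10/15 prints as 66% under integer truncation
  r <- agreement_row(10, 5)
  expect_identical(percent_trunc(r$p_a), 66)
  expect_identical(r$pct, 66.67)
})

test_that("scaling counts keeps p_a but shrinks the interval", {
  a <- agreement_row(12, 18, ci_proportion = "exact")
  b <- agreement_row(48, 72, ci_proportion = "exact")
  expect_identical(a$p_a, b$p_a)
  expect_lt(b$ci_high - b$ci_low, a$ci_high - a$ci_low)
  expect_equal(a$se / b$se, 2, tolerance = 1e-12)  # root-n shrinkage
})

test_that("the pooled total is the trial-weighted mean of per-sign proportions", {
  kb <- build_mini_epo()
  s <- generate_session(kb, n_images = 25, sensitivity = 0.7, fp_rate = 0.1,
                        seed = 19)
  signs <- sort(unique(s$annotations$concept))
  tab <- agreement_table(s, signs)
  per <- tab[tab$sign != "Total", ]
  tot <- tab[tab$sign == "Total", ]
  n <- per$agreements + per$disagreements
  expect_equal(tot$agreements / (tot$agreements + tot$disagreements),
               sum((per$agreements / n) * n) / sum(n), tolerance = 1e-12)
  expect_error(agreement_table(s, character(0)), class = "epokb_domain_error")
  # single sign, single image, unanimity
  one <- epo_session(
    images = data.frame(image_id = "i", case_id = "c", cohort = "common"),
    observers = data.frame(id = paste0("o", 1:4)),
    annotations = data.frame(image_id = "i", observer = paste0("o", 1:4),
                             concept = signs[1]))
  t1 <- agreement_table(one, signs[1])
  expect_identical(t1$pct[t1$sign == "Total"], 100)
})

test_that("precision follows the information-retrieval definition", {
  gold <- list(img = c("A", "B", "E"))
  expect_identical(precision(list(img = c("A", "B", "C", "D")), gold)$precision, 0.5)
  expect_identical(precision(list(img = c("A", "B", "E")), gold)$precision, 1)
  # duplicated annotations and order do not matter
  expect_identical(precision(list(img = c("D", "C", "B", "A", "A")), gold)$precision, 0.5)
  # micro-average pools intersections over observations
  two <- precision(list(i1 = c("A", "B"), i2 = "C"),
                   list(i1 = "A", i2 = "Z"))
  expect_identical(two$precision, 1 / 3)
  # empty observed sets are excluded rather than counted as zero
  expect_identical(precision(list(i1 = "A", i2 = character(0)),
                             list(i1 = "A", i2 = "Z"))$precision, 1)
  expect_error(precision(list(mystery = "A"), gold), class = "epokb_gold_error")
})

test_that("session precision is exact on a constructed example", {
  kb <- build_mini_epo()
  rof <- mini_epo_id("ring of fire sign"); trs <- mini_epo_id("tubal ring sign")
  s <- epo_session(
    images = data.frame(image_id = c("i1", "i2"), case_id = "c",
                        cohort = "common"),
    observers = data.frame(id = c("o1", "o2")),
    annotations = rbind(
      data.frame(image_id = "i1", observer = "o1", concept = c(rof, trs)),
      data.frame(image_id = "i1", observer = "o2", concept = rof),
      data.frame(image_id = "i2", observer = "o1", concept = trs)),
    gold = list(i1 = rof, i2 = c(rof, trs)),
    kb = kb)
  rep <- precision_report(s)
  expect_identical(rep$overall$n_observed, 4L)
  expect_identical(rep$overall$n_relevant_observed, 3L)  # rof x2 on i1, trs on i2
  expect_identical(rep$overall$precision, 0.75)
  expect_identical(rep$per_sign$precision[rep$per_sign$sign == rof], 1)
  expect_identical(rep$per_sign$precision[rep$per_sign$sign == trs], 0.5)
})
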