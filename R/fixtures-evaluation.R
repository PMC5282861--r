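#' @title Published evaluation inputs
#' @description The printed per-sign agreement counts of the annotation study
#'   (six observers, five common cases, 33 images) treated as data inputs,
#'   plus a deterministic reconstruction of an annotation session that yields
#'   exactly those counts, so the full session-to-table pipeline can be
#'   exercised without the (undistributed) clinical images.
#' @name evaluation-fixtures
NULL

#' Printed per-sign agreement counts
#'
#' One row per evaluated sign: concordant-pair count, discordant-pair count
#' and number of contributing images, as published. One published row
#' ("fluid collection located centrally ...") prints counts inconsistent
#' with its own percentage, confidence interval and the pooled total; the
#' counts here (4, 26, 2 images) are the unique solution consistent with all
#' three.
#'
#' @return A data.frame `sign`, `agreements`, `disagreements`, `images`.
#' @export
table4_counts <- function() {
  data.frame(
    sign = table4_sign_labels(),
    agreements = c(48L, 143L, 45L, 226L, 122L, 119L, 82L, 63L, 39L, 64L, 22L,
                   19L, 14L, 45L, 24L, 110L, 24L, 33L, 21L, 4L, 4L, 10L, 1L, 1L),
    disagreements = c(12L, 37L, 15L, 104L, 58L, 76L, 53L, 57L, 36L, 71L, 38L,
                      41L, 31L, 120L, 66L, 325L, 96L, 162L, 114L, 26L, 41L,
                      125L, 44L, 149L),
    images = c(4L, 12L, 4L, 22L, 12L, 13L, 9L, 8L, 5L, 9L, 4L, 4L, 3L, 11L,
               6L, 29L, 8L, 13L, 9L, 2L, 3L, 9L, 3L, 10L),
    stringsAsFactors = FALSE)
}

# split a concordant-pair total over m images: find k_1..k_m (1 <= k_i <= x)
# with sum(choose(k_i, 2)) == target, preferring large k first
solve_k_vector <- function(target, m, x = 6L) {
  vals <- choose(seq_len(x), 2)          # 0, 1, 3, 6, 10, 15 for x = 6
  # reach[[r + 1]][v + 1]: v representable as a sum of exactly r terms
  vmax <- max(vals) * m
  reach <- vector("list", m + 1L)
  reach[[1]] <- c(TRUE, rep(FALSE, vmax))
  for (r in seq_len(m)) {
    prev <- reach[[r]]
    cur <- rep(FALSE, vmax + 1L)
    for (t in unique(vals)) {
      idx <- seq.int(t + 1L, vmax + 1L)
      cur[idx] <- cur[idx] | prev[idx - t]
    }
    reach[[r + 1L]] <- cur
  }
  feasible <- function(v, r) v >= 0 && v <= vmax && reach[[r + 1L]][v + 1L]
  ks <- integer(m)
  rem <- target
  for (i in seq_len(m)) {
    found <- FALSE
    for (k in rev(seq_len(x))) {
      if (vals[k] <= rem && feasible(rem - vals[k], m - i)) {
        ks[i] <- k; rem <- rem - vals[k]; found <- TRUE; break
      }
    }
    if (!found)
      epokb_stop(sprintf("cannot split %d pairs over %d images (x = %d)",
                         target, m, x), "epokb_domain_error")
  }
  ks
}

#' Reconstruct the common-cohort annotation session
#'
#' Builds a synthetic session of six observers (three seniors, two senior
#' registrars, one registrar) whose annotation matrix reproduces, sign by
#' sign, the published agreement counts of [table4_counts()]: for each sign a
#' per-image observer count vector `k` is solved such that the concordant
#' pairs sum to the printed value over the printed number of images. Image
#' identifiers are synthetic (the clinical images are not distributed);
#' agreement statistics are invariant to which observers form each `k`.
#'
#' @param kb The knowledge base naming the signs, normally
#'   [build_mini_epo()]; annotations reference its sign concepts.
#' @return An `epo_session` (no gold standard: the published reports are not
#'   distributed, so precision is not reconstructable).
#' @export
build_table4_session <- function(kb = build_mini_epo()) {
  counts <- table4_counts()
  observers <- data.frame(
    id = paste0("obs", 1:6),
    grade = c("senior", "senior", "senior", "senior_registrar",
              "senior_registrar", "registrar"),
    stringsAsFactors = FALSE)
  imgs <- list(); anns <- list()
  for (i in seq_len(nrow(counts))) {
    sign_id <- kb_concept_by_label(kb, tolower(counts$sign[i]))
    ks <- solve_k_vector(counts$agreements[i], counts$images[i], x = 6L)
    stopifnot(sum(choose(6, 2) - choose(ks, 2)) == counts$disagreements[i])
    for (j in seq_along(ks)) {
      img <- sprintf("t4img_%02d_%02d", i, j)
      imgs[[length(imgs) + 1L]] <- data.frame(
        image_id = img, case_id = sprintf("case_%02d", i), cohort = "common",
        stringsAsFactors = FALSE)
      anns[[length(anns) + 1L]] <- data.frame(
        image_id = img, observer = paste0("obs", seq_len(ks[j])),
        concept = sign_id, stringsAsFactors = FALSE)
    }
  }
  epo_session(images = do.call(rbind, imgs), observers = observers,
              annotations = do.call(rbind, anns), kb = kb)
}

# map printed table row labels to fixture sign identifiers
table4_sign_ids <- function(kb) {
  vapply(table4_sign_labels(),
         function(l) kb_concept_by_label(kb, tolower(l)), character(1))
}

#' Published agreement table, recomputed
#'
#' Runs the full pipeline — reconstructed session, annotation matrices,
#' pooled concordant pairs, proportions and CIs — and returns the agreement
#' table in the published row order with the pooled total row.
#'
#' @inheritParams build_table4_session
#' @return See [agreement_table()].
#' @export
table4_reproduction <- function(kb = build_mini_epo()) {
  session <- build_table4_session(kb)
  agreement_table(session, table4_sign_ids(kb), labels = table4_sign_labels())
}
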