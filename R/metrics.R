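#' @title Agreement and precision statistics
#' @description The evaluation statistics of the annotation study: the
#'   multi-observer proportion of agreement on the presence of a sign
#'   (concordant-positive observer pairs over all observer pairs, pooled over
#'   images, with a Wald 95% confidence interval) and information-retrieval
#'   precision of observer annotations against a report-derived gold
#'   standard. Only concordant-positive pairs count as agreements: a pair of
#'   observers who both omitted a sign on an annotated image disagrees with
#'   the annotators, which is what makes 5 annotators out of 6 score
#'   10/15 rather than 11/15.
#' @name metrics
NULL

#' Concordant observer pairs
#'
#' For one sign on one image annotated by `k` of `x` panel observers:
#' agreements are the concordant-positive pairs `k(k-1)/2`, trials all
#' observer pairs `x(x-1)/2`.
#'
#' @param k Number of observers who annotated the sign (0 <= k <= x).
#' @param x Panel size (>= 2).
#' @return A list with `agreements` and `trials`.
#' @export
concordant_pairs <- function(k, x) {
  if (x < 2) epokb_stop("panel size x must be >= 2", "epokb_domain_error")
  if (k < 0 || k > x)
    epokb_stop("k must satisfy 0 <= k <= x", "epokb_domain_error")
  list(agreements = as.integer(choose(k, 2)), trials = as.integer(choose(x, 2)))
}

#' Proportion of agreement with Wald 95% CI
#'
#' Computes `p_a = agreements / (agreements + disagreements)`, its standard
#' error `sqrt(p(1-p)/n)` and the 95% confidence interval `p +/- 1.96 SE`,
#' clipped to \[0, 1\].
#'
#' Two conventions are exposed for the proportion that feeds the CI, because
#' the published agreement table mixes them: `"rounded"` (default) first
#' rounds `p_a` half-up to the printed 2-decimal percent and reproduces the
#' per-sign rows, including the clipped 0.00 lower bound of the rare-sign
#' rows; `"exact"` uses the unrounded proportion and reproduces the pooled
#' total row. `p_a` itself is always exact. Percent fields are rendered
#' half-up to 2 decimals.
#'
#' @param agreements,disagreements Pair counts; their sum `n` (the trials)
#'   must be >= 1.
#' @param ci_proportion `"rounded"` or `"exact"` (see Details).
#' @return A list of class `epo_agreement` with fields `agreements`,
#'   `disagreements`, `trials`, `p_a`, `se`, `ci_low`, `ci_high` and the
#'   percent renderings `pct`, `pct_ci_low`, `pct_ci_high`.
#' @export
agreement_row <- function(agreements, disagreements,
                          ci_proportion = c("rounded", "exact")) {
  ci_proportion <- match.arg(ci_proportion)
  if (agreements < 0 || disagreements < 0)
    epokb_stop("counts must be non-negative", "epokb_domain_error")
  n <- agreements + disagreements
  if (n < 1) epokb_stop("at least one trial is required", "epokb_domain_error")
  p <- agreements / n
  pc <- if (ci_proportion == "rounded") round_half_up(p, 4) else p
  se <- sqrt(pc * (1 - pc) / n)
  lo <- max(0, pc - 1.96 * se)
  hi <- min(1, pc + 1.96 * se)
  structure(list(agreements = agreements, disagreements = disagreements,
                 trials = n, p_a = p, se = se, ci_low = lo, ci_high = hi,
                 pct = percent_round(p), pct_ci_low = percent_round(lo),
                 pct_ci_high = percent_round(hi)),
            class = "epo_agreement")
}

#' @export
print.epo_agreement <- function(x, ...) {
  cat(sprintf("p_a %.2f%% [%.2f%% - %.2f%%] (%d/%d pairs)\n",
              x$pct, x$pct_ci_low, x$pct_ci_high, x$agreements, x$trials))
  invisible(x)
}

#' Agreement table over a session
#'
#' For each sign, pools the concordant pairs over the images returned by
#' [annotation_matrix()] and computes the proportion of agreement with its
#' CI (per-row rounded-proportion convention); the total row pools agreements
#' and trials over all listed signs before computing `p_a` and its CI from
#' the exact pooled proportion. The pooled `p_a` equals the trial-weighted
#' mean of the per-sign proportions.
#'
#' @param session An annotation session with >= 2 observers.
#' @param signs Character vector of sign concept identifiers (>= 1); used as
#'   row order.
#' @param cohort Optional cohort filter passed to [annotation_matrix()].
#' @param labels Optional character vector of display labels for `signs`.
#' @return A data.frame with columns `sign`, `agreements`, `disagreements`,
#'   `images`, `pct`, `pct_ci_low`, `pct_ci_high`; the last row is the pooled
#'   `"Total"`.
#' @export
agreement_table <- function(session, signs, cohort = NULL, labels = NULL) {
  if (nrow(session$observers) < 2)
    epokb_stop("session must have at least two observers", "epokb_domain_error")
  if (!length(signs)) epokb_stop("empty sign list", "epokb_domain_error")
  if (is.null(labels)) labels <- signs
  rows <- lapply(seq_along(signs), function(i) {
    m <- annotation_matrix(session, signs[i], cohort)
    if (!nrow(m)) return(NULL)
    agr <- sum(choose(m$k, 2))
    tri <- sum(choose(m$x, 2))
    r <- agreement_row(agr, tri - agr, ci_proportion = "rounded")
    data.frame(sign = labels[i], agreements = agr, disagreements = tri - agr,
               images = nrow(m), pct = r$pct, pct_ci_low = r$pct_ci_low,
               pct_ci_high = r$pct_ci_high, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows))
    epokb_stop("no listed sign was annotated in the session",
               "epokb_domain_error")
  tot <- agreement_row(sum(rows$agreements), sum(rows$disagreements),
                       ci_proportion = "exact")
  rbind(rows, data.frame(sign = "Total", agreements = tot$agreements,
                         disagreements = tot$disagreements,
                         images = sum(rows$images), pct = tot$pct,
                         pct_ci_low = tot$pct_ci_low,
                         pct_ci_high = tot$pct_ci_high,
                         stringsAsFactors = FALSE))
}

#' Precision of observed sign sets against a gold standard
#'
#' Information-retrieval precision, `|relevant cut observed| / |observed|`,
#' computed per annotation unit (an image-observer pair) and micro-averaged:
#' the overall precision is the summed intersection size over the summed
#' observed size, so units with empty observed sets drop out. Invariant to
#' duplicated annotations and to their order.
#'
#' @param observed A list of character vectors of observed sign identifiers,
#'   named or paired with `image_ids`.
#' @param gold Named list, image_id -> character vector of relevant signs; an
#'   image with observations but no gold entry is an error naming the image.
#' @param image_ids Image of each observed set, recycled against `observed`;
#'   defaults to `names(observed)`.
#' @return A list with `n_observed`, `n_relevant_observed`, `precision`.
#' @export
precision <- function(observed, gold, image_ids = names(observed)) {
  if (is.null(image_ids))
    epokb_stop("observed sets must be named by image or image_ids given",
               "epokb_domain_error")
  n_obs <- 0L; n_hit <- 0L
  for (i in seq_along(observed)) {
    obs <- unique(observed[[i]])
    if (!length(obs)) next
    img <- image_ids[[i]]
    if (is.null(gold[[img]]))
      epokb_stop(paste0("no gold standard for image ", img),
                 "epokb_gold_error")
    n_obs <- n_obs + length(obs)
    n_hit <- n_hit + length(intersect(obs, gold[[img]]))
  }
  list(n_observed = n_obs, n_relevant_observed = n_hit,
       precision = if (n_obs) n_hit / n_obs else NA_real_)
}

#' Precision report for a session
#'
#' Applies [precision()] to every image-observer unit of a session with a
#' gold standard, micro-averaging overall and reporting each sign's own
#' precision (how often its use was confirmed by the report-derived gold).
#'
#' @param session An annotation session with a gold standard.
#' @param cohort Optional cohort filter.
#' @return A list with `overall` (as returned by [precision()]) and
#'   `per_sign` (data.frame `sign`, `observed`, `relevant_observed`,
#'   `precision`).
#' @export
precision_report <- function(session, cohort = NULL) {
  if (is.null(session$gold))
    epokb_stop("session has no gold standard", "epokb_gold_error")
  imgs <- session$images
  if (!is.null(cohort)) imgs <- imgs[imgs$cohort == cohort, , drop = FALSE]
  ann <- session$annotations
  ann <- ann[ann$image_id %in% imgs$image_id, , drop = FALSE]
  units <- split(ann$concept, paste(ann$image_id, ann$observer, sep = "\r"))
  unit_imgs <- vapply(strsplit(names(units), "\r", fixed = TRUE), `[[`,
                      character(1), 1L)
  overall <- precision(units, session$gold, unit_imgs)
  hit <- vapply(seq_len(nrow(ann)), function(i) {
    g <- session$gold[[ann$image_id[i]]]
    if (is.null(g))
      epokb_stop(paste0("no gold standard for image ", ann$image_id[i]),
                 "epokb_gold_error")
    ann$concept[i] %in% g
  }, logical(1))
  per <- stats::aggregate(hit, by = list(sign = ann$concept),
                          FUN = function(v) c(sum(v), length(v)))
  per_sign <- data.frame(sign = per$sign,
                         observed = per$x[, 2],
                         relevant_observed = per$x[, 1],
                         precision = per$x[, 1] / per$x[, 2],
                         stringsAsFactors = FALSE)
  per_sign <- per_sign[order(per_sign$sign, method = "radix"), , drop = FALSE]
  rownames(per_sign) <- NULL
  list(overall = overall, per_sign = per_sign)
}
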