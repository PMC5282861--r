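#' @title Annotation sessions
#' @description Storage and validation of annotation sessions: images grouped
#'   into clinical cases (a cohort common to all observers and
#'   observer-specific cohorts), observers with optional seniority grades,
#'   per-image per-observer sets of selected concepts, and an optional
#'   report-derived gold standard. Annotations have set semantics per
#'   (image, observer): re-selecting a concept is idempotent.
#' @name annotation
NULL

#' Create an annotation session
#'
#' @param images data.frame with columns `image_id`, `case_id`, `cohort`
#'   (`"common"` or `"specific"`).
#' @param observers data.frame with columns `id` and optionally `grade`
#'   (`senior`, `senior_registrar`, `registrar`).
#' @param annotations data.frame with columns `image_id`, `observer`,
#'   `concept`; duplicated rows are collapsed.
#' @param gold Optional named list, image_id -> character vector of sign
#'   concept identifiers from the report-derived gold standard.
#' @param kb Optional knowledge base the concepts refer to; enables
#'   referential and category checks.
#' @return An object of class `epo_session`.
#' @export
epo_session <- function(images, observers, annotations, gold = NULL, kb = NULL) {
  if (!("grade" %in% names(observers))) observers$grade <- NA_character_
  images <- data.frame(image_id = as.character(images$image_id),
                       case_id = as.character(images$case_id),
                       cohort = as.character(images$cohort),
                       stringsAsFactors = FALSE)
  observers <- data.frame(id = as.character(observers$id),
                          grade = as.character(observers$grade),
                          stringsAsFactors = FALSE)
  annotations <- data.frame(image_id = as.character(annotations$image_id),
                            observer = as.character(annotations$observer),
                            concept = as.character(annotations$concept),
                            stringsAsFactors = FALSE)
  annotations <- unique(annotations)
  annotations <- annotations[order(annotations$image_id, annotations$observer,
                                   annotations$concept, method = "radix"), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  if (!is.null(gold)) gold <- lapply(gold, function(g) sort_c(unique(g)))
  structure(list(images = images, observers = observers,
                 annotations = annotations, gold = gold, kb = kb),
            class = "epo_session")
}

#' @export
print.epo_session <- function(x, ...) {
  cat(sprintf("<epo_session> %d images, %d observers, %d annotations%s\n",
              nrow(x$images), nrow(x$observers), nrow(x$annotations),
              if (is.null(x$gold)) "" else ", with gold standard"))
  invisible(x)
}

#' Validate an annotation session
#'
#' Referential-integrity checks, reported as data with JSON-pointer-style
#' paths: unique image identifiers, annotations referencing known images and
#' observers, gold entries referencing known images, and (when a knowledge
#' base is attached) all concepts existing in it.
#'
#' @param session An annotation session.
#' @param kb Optional knowledge base overriding `session$kb`.
#' @return A data.frame `pointer`, `message`; zero rows when valid.
#' @export
validate_session <- function(session, kb = NULL) {
  kb <- kb %||% session$kb
  issues <- list()
  add <- function(pointer, message)
    issues[[length(issues) + 1L]] <<- data.frame(pointer = pointer,
                                                 message = message,
                                                 stringsAsFactors = FALSE)
  if (anyDuplicated(session$images$image_id))
    add("/images", "duplicate image_id values")
  if (anyDuplicated(session$observers$id))
    add("/observers", "duplicate observer ids")
  known_grades <- c("senior", "senior_registrar", "registrar", NA_character_)
  bad <- which(!(session$observers$grade %in% known_grades))
  for (i in bad) add(paste0("/observers/", i - 1L, "/grade"),
                     paste0("unknown grade: ", session$observers$grade[i]))
  ann <- session$annotations
  for (i in seq_len(nrow(ann))) {
    if (!(ann$image_id[i] %in% session$images$image_id))
      add(paste0("/annotations/", i - 1L, "/image_id"),
          paste0("unknown image: ", ann$image_id[i]))
    if (!(ann$observer[i] %in% session$observers$id))
      add(paste0("/annotations/", i - 1L, "/observer"),
          paste0("unknown observer: ", ann$observer[i]))
    if (!is.null(kb) && !(ann$concept[i] %in% kb_concept_ids(kb)))
      add(paste0("/annotations/", i - 1L, "/concept"),
          paste0("concept not in knowledge base: ", ann$concept[i]))
  }
  if (!is.null(session$gold)) {
    for (img in names(session$gold)) {
      if (!(img %in% session$images$image_id))
        add(paste0("/gold/", img), "gold entry for unknown image")
      if (!is.null(kb)) {
        for (cp in session$gold[[img]]) {
          if (!(cp %in% kb_concept_ids(kb)))
            add(paste0("/gold/", img),
                paste0("gold concept not in knowledge base: ", cp))
        }
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(pointer = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

session_to_list <- function(session) {
  df_rows <- function(df) {
    unname(lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row <- lapply(row, function(v) if (is.na(v)) NULL else v)
      row[!vapply(row, is.null, logical(1))]
    }))
  }
  obs <- session$observers[order(session$observers$id, method = "radix"), ,
                           drop = FALSE]
  imgs <- session$images[order(session$images$image_id, method = "radix"), ,
                         drop = FALSE]
  out <- list(format = "epokb-session", version = 1L,
              observers = df_rows(obs), images = df_rows(imgs),
              annotations = df_rows(session$annotations))
  if (!is.null(session$gold))
    out$gold <- lapply(session$gold[sort_c(names(session$gold))], as.list)
  out
}

#' Load and save annotation sessions
#'
#' Sessions are exchanged as JSON (schema published in
#' `inst/extdata/session.schema.json`). `load_session()` validates and raises
#' an error carrying JSON-pointer paths on referential violations;
#' serialization is deterministic, so `load(save(session))` is the identity.
#'
#' @param path File path.
#' @param session An annotation session.
#' @param kb Optional knowledge base for concept checks.
#' @return `load_session()` returns an `epo_session`.
#' @export
load_session <- function(path, kb = NULL) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  epokb_stop(paste0("JSON parse failure in ", path, ": ",
                                    conditionMessage(e)), "epokb_format_error"))
  if (!identical(x$format, "epokb-session"))
    epokb_stop("not an epokb-session JSON document", "epokb_format_error")
  getcol <- function(rows, field, default = NA_character_)
    vapply(rows, function(r) r[[field]] %||% default, character(1))
  session <- epo_session(
    images = data.frame(image_id = getcol(x$images, "image_id"),
                        case_id = getcol(x$images, "case_id"),
                        cohort = getcol(x$images, "cohort"),
                        stringsAsFactors = FALSE),
    observers = data.frame(id = getcol(x$observers, "id"),
                           grade = getcol(x$observers, "grade"),
                           stringsAsFactors = FALSE),
    annotations = data.frame(image_id = getcol(x$annotations, "image_id"),
                             observer = getcol(x$annotations, "observer"),
                             concept = getcol(x$annotations, "concept"),
                             stringsAsFactors = FALSE),
    gold = if (!is.null(x$gold)) lapply(x$gold, function(g) unlist(g) %||% character(0)),
    kb = kb)
  issues <- validate_session(session, kb)
  if (nrow(issues))
    epokb_stop(paste0("invalid session:\n",
                      paste0("  ", issues$pointer, ": ", issues$message,
                             collapse = "\n")),
               "epokb_validation_error", issues = issues)
  session
}

#' @rdname load_session
#' @export
save_session <- function(session, path) {
  json <- jsonlite::toJSON(session_to_list(session), auto_unbox = TRUE,
                           pretty = 2, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(NULL)
}

#' Per-image observer counts for a sign
#'
#' For one sign, returns one row per image on which at least one observer
#' annotated the sign: `k` is the number of annotating observers and `x` the
#' panel size. Images nobody annotated with the sign contribute no row
#' (they enter no agreement trial). Invariant to annotation order and to
#' duplicated input rows.
#'
#' @param session An annotation session.
#' @param sign Sign concept identifier.
#' @param cohort Optional cohort filter (`"common"` or `"specific"`).
#' @return A data.frame `image_id`, `k`, `x`.
#' @export
annotation_matrix <- function(session, sign, cohort = NULL) {
  if (!is.null(session$kb)) {
    cats <- kb_categories(session$kb)
    if (is.na(cats[sign]) || cats[[sign]] != "sign")
      epokb_stop(paste0(sign, " is not a sign concept"), "epokb_selection_error")
  }
  imgs <- session$images
  if (!is.null(cohort)) imgs <- imgs[imgs$cohort == cohort, , drop = FALSE]
  ann <- session$annotations
  ann <- ann[ann$concept == sign & ann$image_id %in% imgs$image_id, ,
             drop = FALSE]
  if (!nrow(ann)) {
    return(data.frame(image_id = character(0), k = integer(0), x = integer(0),
                      stringsAsFactors = FALSE))
  }
  counts <- table(ann$image_id)
  data.frame(image_id = sort_c(names(counts)),
             k = as.integer(counts[sort_c(names(counts))]),
             x = nrow(session$observers),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Session annotation summary
#'
#' Totals per cohort: number of annotation instances, distinct signs used,
#' and the annotations made by a single observer (no second observer marked
#' the same concept on the same image), with their share rendered at one
#' decimal.
#'
#' @inheritParams annotation_matrix
#' @return A list with `n_annotations`, `n_concepts`, `n_single`,
#'   `n_single_concepts`, `single_share_pct`.
#' @export
annotation_summary <- function(session, cohort = NULL) {
  imgs <- session$images
  if (!is.null(cohort)) imgs <- imgs[imgs$cohort == cohort, , drop = FALSE]
  ann <- session$annotations
  ann <- ann[ann$image_id %in% imgs$image_id, , drop = FALSE]
  key <- paste(ann$image_id, ann$concept)
  multi <- names(table(key))[table(key) >= 2]
  single <- !(key %in% multi)
  list(n_annotations = nrow(ann),
       n_concepts = length(unique(ann$concept)),
       n_single = sum(single),
       n_single_concepts = length(unique(ann$concept[single])),
       single_share_pct = if (nrow(ann))
         percent_round(sum(single) / nrow(ann), 1) else NA_real_)
}
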