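#' @title Suggestion queries
#' @description The query layer of the annotation application: given selected
#'   annotations it suggests ectopic-pregnancy types, further signs, the
#'   profile of a sign (types, locations, technical elements) and reference
#'   images, and answers the competency questions. Semantics follow the
#'   subsumption-path queries of the original application: sign selection is
#'   expanded through inherited restrictions, and types are reported at the
#'   granularity of direct children of the ectopic-pregnancy root.
#' @name suggestion
NULL

# direct children of the disorder root in the (asserted + defined) edge set
disorder_children <- function(kb, closure) {
  unique(closure$edges$child[closure$edges$parent == kb$roots$disorder])
}

label_order <- function(kb, ids, lang) {
  labels <- vapply(ids, function(id) kb_pref_label(kb, id, lang), character(1))
  ids[order(tolower(labels), ids, method = "radix")]
}

concept_definition <- function(kb, id, lang) {
  defs <- kb$concepts[[id]]$definitions
  hit <- defs$text[defs$lang == lang]
  if (!length(hit) && lang != "en") hit <- defs$text[defs$lang == "en"]
  if (length(hit)) hit[[1]] else NA_character_
}

assert_under <- function(kb, closure, ids, root, what) {
  for (id in ids) {
    if (is.null(closure$ancestors[[id]]))
      epokb_stop(paste0("unknown concept: ", id), "epokb_lookup_error")
    if (!(root %in% closure$ancestors[[id]]))
      epokb_stop(paste0(id, " is not a ", what), "epokb_selection_error")
  }
  invisible(NULL)
}

#' Suggest ectopic-pregnancy types for selected signs
#'
#' Returns exactly the types (direct children of the ectopic-pregnancy root)
#' such that at least one of the selected signs carries an inherited
#' `suggests` restriction whose filler is subsumed by the type. Distinct,
#' ordered by label ascending (case-insensitive, ties by identifier);
#' definitions are reported when present. Monotone in the selection: adding a
#' sign never removes a suggested type.
#'
#' @param kb A knowledge base.
#' @param relations Materialized relations from [materialize_relations()].
#' @param selected_signs Character vector of sign concept identifiers.
#' @param lang Language for labels and definitions (English fallback).
#' @param closure The [compute_closure()] result; computed when `NULL`.
#' @return A data.frame `id`, `label`, `definition`.
#' @export
suggest_types_for_signs <- function(kb, relations, selected_signs, lang = "en",
                                    closure = NULL) {
  if (is.null(closure)) closure <- compute_closure(kb)
  assert_under(kb, closure, selected_signs, kb$roots$sign, "sign")
  empty <- data.frame(id = character(0), label = character(0),
                      definition = character(0), stringsAsFactors = FALSE)
  if (!length(selected_signs)) return(empty)
  hits <- relations$object[relations$property == "suggests" &
                             relations$subject %in% selected_signs]
  ids <- intersect(unique(hits), disorder_children(kb, closure))
  if (!length(ids)) return(empty)
  ids <- label_order(kb, ids, lang)
  data.frame(
    id = ids,
    label = vapply(ids, function(i) kb_pref_label(kb, i, lang), character(1)),
    definition = vapply(ids, function(i) concept_definition(kb, i, lang),
                        character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Suggest signs for selected ectopic-pregnancy types
#'
#' All signs with an inherited `suggests` relation to any selected type or
#' one of its descendants, label-ordered; signs listed in `exclude` (e.g. the
#' user's current selection) are omitted.
#'
#' @inheritParams suggest_types_for_signs
#' @param selected_types Character vector of type concept identifiers (under
#'   the ectopic-pregnancy root).
#' @param exclude Sign identifiers to drop from the result.
#' @return A data.frame `id`, `label`.
#' @export
suggest_signs_for_types <- function(kb, relations, selected_types, lang = "en",
                                    exclude = character(0), closure = NULL) {
  if (is.null(closure)) closure <- compute_closure(kb)
  assert_under(kb, closure, selected_types, kb$roots$disorder,
               "type of ectopic pregnancy")
  empty <- data.frame(id = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  if (!length(selected_types)) return(empty)
  desc <- descendants_map(closure$ancestors)
  targets <- unique(unlist(desc[selected_types], use.names = FALSE))
  ids <- unique(relations$subject[relations$property == "suggests" &
                                    relations$object %in% targets])
  ids <- setdiff(ids, exclude)
  if (!length(ids)) return(empty)
  ids <- label_order(kb, ids, lang)
  data.frame(
    id = ids,
    label = vapply(ids, function(i) kb_pref_label(kb, i, lang), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Profile of a sign
#'
#' Partitions the sign's asserted and inherited relations by property:
#' suggested ectopic-pregnancy types, anatomical locations, and the
#' examination routes, modes and views the sign requires. Within each
#' property only the most specific fillers are reported (an ancestor filler
#' entailed by a more specific one — e.g. the plain color Doppler mode next
#' to its 2D variant — is suppressed), matching the knowledge-base view of a
#' sign; ordering is deterministic.
#'
#' @inheritParams suggest_types_for_signs
#' @param sign A sign concept identifier.
#' @return A list of class `epo_sign_profile` with character vectors
#'   `suggests`, `locations`, `routes`, `modes`, `views`.
#' @export
sign_profile <- function(kb, relations, sign, closure = NULL) {
  if (is.null(closure)) closure <- compute_closure(kb)
  assert_under(kb, closure, sign, kb$roots$sign, "sign")
  own <- relations[relations$subject == sign, , drop = FALSE]
  pick <- function(p) {
    objs <- unique(own$object[own$property == p])
    sort_c(most_specific(objs, closure$ancestors))
  }
  structure(list(sign = sign,
                 suggests = pick("suggests"),
                 locations = pick("hasLocation"),
                 routes = pick("requiresRoute"),
                 modes = pick("requiresMode"),
                 views = pick("requiresView")),
            class = "epo_sign_profile")
}

#' @export
print.epo_sign_profile <- function(x, ...) {
  cat("<sign profile>", x$sign, "\n")
  for (f in c("suggests", "locations", "routes", "modes", "views"))
    cat(sprintf("  %-10s %s\n", f, paste(x[[f]], collapse = ", ")))
  invisible(x)
}

#' Reference images and citations for a sign
#'
#' The sign's own PubMed and reference-image annotations; one row per
#' annotation, `NA` in the column that does not apply.
#'
#' @param kb A knowledge base.
#' @param sign A sign concept identifier.
#' @return A data.frame `sign`, `pmid`, `image_path`; zero rows when the sign
#'   is unannotated.
#' @export
reference_images <- function(kb, sign) {
  co <- kb$concepts[[sign]]
  if (is.null(co)) epokb_stop(paste0("unknown concept: ", sign),
                              "epokb_lookup_error")
  n1 <- length(co$pmids); n2 <- length(co$image_paths)
  data.frame(
    sign = rep(sign, n1 + n2),
    pmid = c(sort_c(co$pmids), rep(NA_character_, n2)),
    image_path = c(rep(NA_character_, n1), sort_c(co$image_paths)),
    stringsAsFactors = FALSE)
}

#' Implantation sites of ectopic pregnancy
#'
#' Answers the competency question "what are the different implantation
#' sites": the named classes one subsumption step under the
#' ectopic-pregnancy root, label-ordered.
#'
#' @inheritParams suggest_types_for_signs
#' @return A data.frame `id`, `label`.
#' @export
implantation_sites <- function(kb, lang = "en", closure = NULL) {
  if (is.null(closure)) closure <- compute_closure(kb)
  ids <- disorder_children(kb, closure)
  if (!length(ids)) {
    return(data.frame(id = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  ids <- label_order(kb, ids, lang)
  data.frame(id = ids,
             label = vapply(ids, function(i) kb_pref_label(kb, i, lang),
                            character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# drop ids that are strict ancestors of another id in the set
most_specific <- function(ids, anc) {
  if (length(ids) < 2) return(ids)
  keep <- vapply(ids, function(c) {
    !any(vapply(setdiff(ids, c), function(d) c %in% anc[[d]], logical(1)))
  }, logical(1))
  ids[keep]
}

# the echographic-view root: technical roots are stored in the fixed order
# route, mode, view
view_root <- function(kb) kb$roots$technical[[3]]

#' Anatomical structures visible in an echographic view
#'
#' Answers the competency question "what are the anatomical structures
#' visible in a view" through the signs: the union of `hasLocation` objects
#' over all signs whose inherited `requiresView` includes the view or one of
#' its descendants. (The knowledge base asserts no direct view-to-structure
#' relations, so the answer path runs via signs.)
#'
#' @inheritParams suggest_types_for_signs
#' @param view An echographic-view concept identifier.
#' @return A data.frame `id`, `label`, label-ordered.
#' @export
structures_in_view <- function(kb, relations, view, lang = "en",
                               closure = NULL) {
  if (is.null(closure)) closure <- compute_closure(kb)
  assert_under(kb, closure, view, view_root(kb), "echographic view")
  rel <- relations[relations$property == "requiresView", , drop = FALSE]
  in_view <- vapply(seq_len(nrow(rel)), function(i) {
    view %in% closure$ancestors[[rel$object[i]]]
  }, logical(1))
  signs <- unique(rel$subject[in_view])
  ids <- sort_c(unique(unlist(lapply(signs, function(s)
    sign_profile(kb, relations, s, closure = closure)$locations))))
  if (!length(ids)) {
    return(data.frame(id = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  ids <- label_order(kb, ids, lang)
  data.frame(id = ids,
             label = vapply(ids, function(i) kb_pref_label(kb, i, lang),
                            character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
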