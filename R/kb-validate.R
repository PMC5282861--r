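#' Validate a knowledge base
#'
#' Checks every structural invariant of the data model and returns the issues
#' found as data, not as errors: designated roots exist; all axiom references
#' resolve (no dangling concepts or properties); defined classes have at least
#' one restriction and disjoint sets at least two members; label languages are
#' configured and preferred labels are unique per language; the asserted
#' subsumption graph is acyclic; every concept is reachable from some root;
#' and every sign concept carries the minimal annotation set (one English
#' preferred label and one English definition).
#'
#' Idempotent and side-effect free; an empty issue list means the knowledge
#' base is valid.
#'
#' @param kb A knowledge base.
#' @return A data.frame with columns `code`, `subject`, `message`; zero rows
#'   when valid.
#' @export
validate_kb <- function(kb) {
  issues <- list()
  add <- function(code, subject, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, subject = subject, message = message,
      stringsAsFactors = FALSE)
  }
  ids <- kb_concept_ids(kb)

  if (!("en" %in% kb$languages))
    add("config", "<kb>", "configured languages must include 'en'")

  for (r in all_roots(kb))
    if (!(r %in% ids))
      add("missing_root", r, paste0("declared root ", r, " is not a concept"))

  # concept-level annotation checks
  for (co in kb$concepts) {
    bad <- setdiff(unique(c(co$pref_labels$lang, co$alt_labels$lang,
                            co$definitions$lang)), kb$languages)
    if (length(bad))
      add("bad_language", co$id,
          paste0("language(s) not configured: ", paste(bad, collapse = ", ")))
    dup <- co$pref_labels$lang[duplicated(co$pref_labels$lang)]
    if (length(dup))
      add("duplicate_pref_label", co$id,
          paste0("more than one preferred label for: ",
                 paste(unique(dup), collapse = ", ")))
    if (any(!nzchar(co$pref_labels$text)) || any(!nzchar(co$alt_labels$text)) ||
        any(!nzchar(co$definitions$text)))
      add("empty_text", co$id, "empty label or definition text")
  }

  # referential integrity of axioms
  ref <- function(ax_ids, what, key) {
    for (x in ax_ids) if (!(x %in% ids))
      add("dangling_reference", x, paste0(what, " references unknown concept ", x,
                                          " (", key, ")"))
  }
  for (ax in kb$axioms) {
    switch(ax$kind,
      subclass_of = ref(c(ax$child, ax$parent), "subclass axiom", ax$child),
      subclass_of_restriction = {
        ref(c(ax$child, ax$filler), "restriction axiom", ax$child)
        if (!(ax$property %in% kb$properties$id))
          add("unknown_property", ax$child,
              paste0("restriction uses unknown property ", ax$property))
      },
      equivalent_to_definition = {
        ref(c(ax$class, ax$genus), "defined class", ax$class)
        if (length(ax$restrictions) < 1)
          add("empty_definition", ax$class,
              "defined class must have at least one restriction")
        for (r in ax$restrictions) {
          ref(r$filler, "defined class", ax$class)
          if (!(r$property %in% kb$properties$id))
            add("unknown_property", ax$class,
                paste0("definition uses unknown property ", r$property))
        }
      },
      disjoint = {
        if (length(ax$classes) < 2)
          add("small_disjoint", paste(ax$classes, collapse = ","),
              "disjoint set must have at least two members")
        ref(ax$classes, "disjoint axiom", paste(ax$classes, collapse = ","))
      },
      add("unknown_axiom", "<kb>", paste0("unknown axiom kind: ", ax$kind))
    )
  }

  # property hierarchy acyclicity
  for (p in kb$properties$id) {
    anc <- property_ancestors(kb$properties, p)
    i <- match(anc[length(anc)], kb$properties$id)
    if (!is.na(i) && !is.na(kb$properties$parent[i]))
      add("property_cycle", p, "property hierarchy contains a cycle")
  }

  # structural checks that need a resolvable graph
  if (!length(issues)) {
    edges <- subclass_edges(kb)
    ts <- topo_sort_kb(ids, edges)
    if (is.null(ts$order)) {
      add("subsumption_cycle", paste(ts$cycle, collapse = ","),
          paste0("subsumption cycle involving: ", paste(ts$cycle, collapse = ", ")))
    } else {
      anc <- asserted_ancestors(kb)
      roots <- all_roots(kb)
      for (id in ids) {
        if (!any(roots %in% anc[[id]]))
          add("unreachable", id, "concept not reachable from any designated root")
      }
      # minimal annotation set for signs
      for (id in ids) {
        if (kb$roots$sign %in% anc[[id]]) {
          co <- kb$concepts[[id]]
          if (!any(co$pref_labels$lang == "en"))
            add("missing_annotation", id, "sign concept lacks an English preferred label")
          if (!any(co$definitions$lang == "en"))
            add("missing_annotation", id, "sign concept lacks an English definition")
        }
      }
    }
  }

  if (!length(issues)) {
    return(data.frame(code = character(0), subject = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

# internal: validate and raise on failure (used by load_kb and the reasoner)
assert_valid_kb <- function(kb) {
  issues <- validate_kb(kb)
  if (nrow(issues))
    epokb_stop(paste0("invalid knowledge base:\n",
                      paste0("  [", issues$code, "] ", issues$subject, ": ",
                             issues$message, collapse = "\n")),
               "epokb_validation_error", issues = issues)
  invisible(kb)
}
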