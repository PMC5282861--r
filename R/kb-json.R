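#' @title Native JSON serialization
#' @description The native exchange format is a single JSON document with a
#'   published schema (`inst/extdata/kb.schema.json`): configured languages,
#'   roots, property hierarchy, concepts (sorted by identifier) and axioms
#'   (sorted by a canonical key). Serialization is deterministic, so repeated
#'   saves of the same knowledge base are byte-identical and
#'   `load(save(kb))` is the identity on the data model.
#' @name kb-json
NULL

kb_to_list <- function(kb) {
  nk <- kb_normalize(kb)
  lang_list <- function(df) {
    if (!nrow(df)) return(list())
    unname(lapply(seq_len(nrow(df)),
                  function(i) list(text = df$text[i], lang = df$lang[i])))
  }
  concepts <- unname(lapply(nk$concepts, function(co) {
    out <- list(id = co$id,
                pref_labels = lang_list(co$pref_labels),
                alt_labels = lang_list(co$alt_labels),
                definitions = lang_list(co$definitions))
    if (!is.na(co$hidden_label)) out$hidden_label <- co$hidden_label
    if (!is.na(co$fma_id)) out$fma_id <- co$fma_id
    out$pmids <- as.list(co$pmids)
    out$image_paths <- as.list(co$image_paths)
    out
  }))
  axioms <- unname(lapply(nk$axioms, function(ax) {
    switch(ax$kind,
      subclass_of = list(kind = ax$kind, child = ax$child, parent = ax$parent),
      subclass_of_restriction = list(kind = ax$kind, child = ax$child,
                                     property = ax$property, filler = ax$filler),
      equivalent_to_definition = list(
        kind = ax$kind, class = ax$class, genus = ax$genus,
        restrictions = unname(lapply(ax$restrictions, function(r)
          list(property = r$property, filler = r$filler)))),
      disjoint = list(kind = ax$kind, classes = as.list(ax$classes))
    )
  }))
  props <- unname(lapply(seq_len(nrow(nk$properties)), function(i) {
    p <- list(id = nk$properties$id[i])
    if (!is.na(nk$properties$parent[i])) p$parent <- nk$properties$parent[i]
    p
  }))
  list(format = "epokb-kb", version = 1L,
       languages = as.list(nk$languages),
       roots = list(sign = nk$roots$sign, disorder = nk$roots$disorder,
                    anatomy = nk$roots$anatomy,
                    technical = as.list(nk$roots$technical)),
       properties = props, concepts = concepts, axioms = axioms)
}

kb_from_list <- function(x) {
  if (!identical(x$format, "epokb-kb"))
    epokb_stop("not an epokb-kb JSON document (missing format marker)",
               "epokb_format_error")
  df_lang <- function(l) {
    if (!length(l)) return(lang_df(NULL))
    data.frame(text = vapply(l, `[[`, character(1), "text"),
               lang = vapply(l, `[[`, character(1), "lang"),
               stringsAsFactors = FALSE)
  }
  concepts <- lapply(x$concepts, function(co) {
    epo_concept(co$id,
                pref_labels = df_lang(co$pref_labels),
                alt_labels = df_lang(co$alt_labels),
                definitions = df_lang(co$definitions),
                hidden_label = co$hidden_label %||% NULL,
                fma_id = co$fma_id %||% NULL,
                pmids = unlist(co$pmids) %||% character(0),
                image_paths = unlist(co$image_paths) %||% character(0))
  })
  axioms <- lapply(x$axioms, function(ax) {
    switch(ax$kind,
      subclass_of = ax_subclass(ax$child, ax$parent),
      subclass_of_restriction = ax_restriction(ax$child, ax$property, ax$filler),
      equivalent_to_definition = ax_defined(
        ax$class, ax$genus,
        lapply(ax$restrictions, function(r)
          list(property = r$property, filler = r$filler))),
      disjoint = ax_disjoint(unlist(ax$classes)),
      epokb_stop(paste0("unknown axiom kind in JSON: ", ax$kind),
                 "epokb_format_error")
    )
  })
  props <- data.frame(
    id = vapply(x$properties, `[[`, character(1), "id"),
    parent = vapply(x$properties, function(p) p$parent %||% NA_character_,
                    character(1)),
    stringsAsFactors = FALSE)
  epo_kb(concepts, axioms,
         sign_root = x$roots$sign, disorder_root = x$roots$disorder,
         anatomy_root = x$roots$anatomy,
         technical_roots = unlist(x$roots$technical),
         languages = unlist(x$languages), properties = props)
}

write_kb_json <- function(kb, path) {
  json <- jsonlite::toJSON(kb_to_list(kb), auto_unbox = TRUE, pretty = 2,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(NULL)
}

read_kb_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  epokb_stop(paste0("JSON parse failure in ", path, ": ",
                                    conditionMessage(e)), "epokb_format_error"))
  kb_from_list(x)
}

#' Load and save knowledge bases
#'
#' `load_kb()` reads a knowledge base from the native JSON format or the
#' documented Turtle subset and validates it (raising a validation error that
#' lists the offending concepts on dangling references or subsumption cycles).
#' `save_kb()` writes with deterministic ordering; for the native format
#' `load_kb(save_kb(kb))` is the identity, and for Turtle the round-trip
#' preserves the deductive closure.
#'
#' @param path File path; format is inferred from the extension (`.json` /
#'   `.ttl`) unless `format` is given.
#' @param format `"json"` or `"turtle"`.
#' @param kb A knowledge base.
#' @return `load_kb()` returns a validated `epo_kb`; `save_kb()` returns
#'   `invisible(NULL)`.
#' @export
load_kb <- function(path, format = c("auto", "json", "turtle")) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_path(path)
  if (!file.exists(path))
    epokb_stop(paste0("no such file: ", path), "epokb_io_error")
  kb <- switch(format, json = read_kb_json(path), turtle = read_kb_turtle(path))
  assert_valid_kb(kb)
  kb
}

#' @rdname load_kb
#' @export
save_kb <- function(kb, path, format = c("auto", "json", "turtle")) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_path(path)
  ok <- tryCatch({
    switch(format,
           json = write_kb_json(kb, path),
           turtle = write_kb_turtle(kb, path))
    TRUE
  }, error = function(e) {
    epokb_stop(paste0("cannot write ", path, ": ", conditionMessage(e)),
               "epokb_io_error")
  })
  invisible(NULL)
}

format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = "json",
         ttl = "turtle",
         turtle = "turtle",
         epokb_stop(paste0("cannot infer format from extension ", shQuote(ext),
                           "; pass format="), "epokb_io_error"))
}
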