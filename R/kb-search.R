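#' Search concepts by label
#'
#' Case-insensitive match of `query` against preferred and alternative labels
#' in the requested language (this is the auto-completion behind the
#' annotation search field). Exact preferred-label matches rank first, then
#' prefix matches, then substring matches; ties are broken by concept
#' identifier. A concept without any label in the requested language is never
#' returned, and an empty query matches nothing.
#'
#' @param kb A knowledge base.
#' @param query Query text.
#' @param lang Language tag; must be one of the configured languages.
#' @param limit Maximum number of results (>= 1).
#' @return A data.frame with columns `id`, `label`, `match`
#'   (`exact`/`prefix`/`substring`), at most `limit` rows, best first.
#' @export
search_terms <- function(kb, query, lang = "en", limit = 10L) {
  if (!(lang %in% kb$languages))
    epokb_stop(paste0("unknown language ", shQuote(lang), "; configured: ",
                      paste(kb$languages, collapse = ", ")),
               "epokb_language_error")
  if (limit < 1) epokb_stop("limit must be >= 1", "epokb_type_error")
  empty <- data.frame(id = character(0), label = character(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (!nzchar(query)) return(empty)
  q <- tolower(query)

  rows <- lapply(kb$concepts, function(co) {
    labs <- rbind(co$pref_labels, co$alt_labels)
    labs$pref <- c(rep(TRUE, nrow(co$pref_labels)),
                   rep(FALSE, nrow(co$alt_labels)))
    labs <- labs[labs$lang == lang, , drop = FALSE]
    if (!nrow(labs)) return(NULL)
    lt <- tolower(labs$text)
    score <- ifelse(labs$pref & lt == q, 0L,
             ifelse(startsWith(lt, q), 1L,
             ifelse(grepl(q, lt, fixed = TRUE), 2L, NA_integer_)))
    if (all(is.na(score))) return(NULL)
    best <- which.min(score)
    # display label: the preferred label in the language when present
    disp <- labs$text[labs$pref][1]
    if (is.na(disp)) disp <- labs$text[best]
    data.frame(id = co$id, label = disp,
               score = score[best], stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || !nrow(rows)) return(empty)
  rows <- rows[order(rows$score, rows$id, method = "radix"), , drop = FALSE]
  rows <- utils::head(rows, limit)
  data.frame(id = rows$id, label = rows$label,
             match = c("exact", "prefix", "substring")[rows$score + 1L],
             stringsAsFactors = FALSE, row.names = NULL)
}
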