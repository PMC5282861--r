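#' @title Knowledge-base data model
#' @description Constructors and accessors for the sign-centric knowledge
#'   base: concepts carrying SKOS-style multilingual annotations, a fixed
#'   object-property hierarchy, and axioms (asserted subsumption, existential
#'   restrictions, defined classes, disjointness).
#' @name kb-model
NULL

# --- language-tagged text ----------------------------------------------------

# normalize label/definition input to a data.frame(text, lang):
# accepts NULL, a named character vector (names = language tags), or a
# data.frame with columns text, lang.
lang_df <- function(x) {
  if (is.null(x) || (is.character(x) && length(x) == 0)) {
    return(data.frame(text = character(0), lang = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("text", "lang") %in% names(x)))
    return(data.frame(text = as.character(x$text), lang = as.character(x$lang),
                      stringsAsFactors = FALSE))
  }
  if (is.character(x)) {
    lang <- names(x)
    if (is.null(lang)) lang <- rep("en", length(x))
    lang[lang == ""] <- "en"
    return(data.frame(text = unname(x), lang = lang, stringsAsFactors = FALSE))
  }
  epokb_stop("labels must be a named character vector or data.frame(text, lang)",
             "epokb_type_error")
}

# --- property hierarchy ------------------------------------------------------

#' Default object-property hierarchy
#'
#' The fixed property set of the knowledge base: `suggests` (sign to
#' ectopic-pregnancy type), `hasLocation` (sign to anatomical structure) and
#' the three technical relations `requiresRoute`, `requiresMode`,
#' `requiresView`, grouped under their common parent `requires`.
#'
#' @return A data.frame with columns `id` and `parent` (`NA` for top
#'   properties).
#' @export
default_properties <- function() {
  data.frame(
    id = c("suggests", "hasLocation", "requires",
           "requiresRoute", "requiresMode", "requiresView"),
    parent = c(NA, NA, NA, "requires", "requires", "requires"),
    stringsAsFactors = FALSE
  )
}

# reflexive ancestor set of a property id (p, parent(p), ...)
property_ancestors <- function(properties, p) {
  anc <- character(0)
  cur <- p
  while (!is.na(cur) && !(cur %in% anc)) {
    anc <- c(anc, cur)
    i <- match(cur, properties$id)
    if (is.na(i)) break
    cur <- properties$parent[i]
  }
  anc
}

# --- concepts ----------------------------------------------------------------

#' Create a concept
#'
#' @param id Compact identifier (`prefix:local`, e.g. `"epo:OPPIO_0000189"`).
#' @param pref_labels Preferred labels: a named character vector (names are
#'   language tags, at most one label per language) or a
#'   `data.frame(text, lang)`.
#' @param alt_labels,definitions Alternative labels / textual definitions in
#'   the same forms (several per language allowed for `alt_labels`).
#' @param hidden_label Optional hidden (machine) label.
#' @param fma_id Optional Foundational Model of Anatomy class identifier.
#' @param pmids Character vector of PubMed identifiers for reference articles.
#' @param image_paths Character vector of reference-image paths.
#' @return An object of class `epo_concept`.
#' @export
epo_concept <- function(id, pref_labels, alt_labels = NULL, definitions = NULL,
                        hidden_label = NULL, fma_id = NULL,
                        pmids = character(0), image_paths = character(0)) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    epokb_stop("concept id must be a non-empty string", "epokb_type_error")
  structure(list(
    id = id,
    pref_labels = lang_df(pref_labels),
    alt_labels = lang_df(alt_labels),
    definitions = lang_df(definitions),
    hidden_label = hidden_label,
    fma_id = fma_id,
    pmids = as.character(pmids),
    image_paths = as.character(image_paths)
  ), class = "epo_concept")
}

# --- axioms ------------------------------------------------------------------

#' Axiom constructors
#'
#' `ax_subclass()` asserts `child` is-a `parent`; `ax_restriction()` asserts
#' `child` is-a `(property some filler)`; `ax_defined()` declares a defined
#' class equivalent to its genus intersected with one or more existential
#' restrictions; `ax_disjoint()` declares a set of classes pairwise disjoint.
#'
#' @param child,parent,class,genus Concept identifiers.
#' @param property Property identifier from the property hierarchy.
#' @param filler Concept identifier (existential filler).
#' @param restrictions A list of `list(property =, filler =)` pairs.
#' @param classes Character vector of >= 2 concept identifiers.
#' @return A list describing the axiom, with a `kind` field.
#' @export
ax_subclass <- function(child, parent) {
  list(kind = "subclass_of", child = child, parent = parent)
}

#' @rdname ax_subclass
#' @export
ax_restriction <- function(child, property, filler) {
  list(kind = "subclass_of_restriction", child = child,
       property = property, filler = filler)
}

#' @rdname ax_subclass
#' @export
ax_defined <- function(class, genus, restrictions) {
  list(kind = "equivalent_to_definition", class = class, genus = genus,
       restrictions = restrictions)
}

#' @rdname ax_subclass
#' @export
ax_disjoint <- function(classes) {
  list(kind = "disjoint", classes = as.character(classes))
}

# --- knowledge base ----------------------------------------------------------

#' Create a knowledge base
#'
#' Assembles concepts, axioms and designated category roots into a knowledge
#' base. Construction does not validate; call [validate_kb()] (or load via
#' [load_kb()], which validates) before reasoning.
#'
#' @param concepts List of [epo_concept()] objects.
#' @param axioms List of axioms built with the `ax_*()` constructors.
#' @param sign_root,disorder_root,anatomy_root Concept identifiers of the
#'   imaging-sign, ectopic-pregnancy-type and anatomical-structure roots.
#' @param technical_roots Character vector of the three technical roots
#'   (examination route, examination mode, echographic view).
#' @param languages Configured language tags; English is mandatory.
#' @param properties Property hierarchy, normally [default_properties()].
#' @return An object of class `epo_kb`.
#' @export
epo_kb <- function(concepts, axioms, sign_root, disorder_root, anatomy_root,
                   technical_roots, languages = c("en", "fr"),
                   properties = default_properties()) {
  ids <- vapply(concepts, function(co) co$id, character(1))
  if (anyDuplicated(ids))
    epokb_stop(paste0("duplicate concept ids: ",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "epokb_validation_error")
  names(concepts) <- ids
  structure(list(
    languages = languages,
    concepts = concepts,
    properties = properties,
    axioms = axioms,
    roots = list(sign = sign_root, disorder = disorder_root,
                 anatomy = anatomy_root, technical = as.character(technical_roots))
  ), class = "epo_kb")
}

#' @export
print.epo_kb <- function(x, ...) {
  cat(sprintf("<epo_kb> %d concepts, %d axioms, languages: %s\n",
              length(x$concepts), length(x$axioms),
              paste(x$languages, collapse = ", ")))
  invisible(x)
}

kb_concept_ids <- function(kb) names(kb$concepts)

all_roots <- function(kb) {
  c(kb$roots$sign, kb$roots$disorder, kb$roots$anatomy, kb$roots$technical)
}

# asserted subclass edges as data.frame(child, parent); a defined class
# contributes the edge to its genus (necessary side of the equivalence)
subclass_edges <- function(kb) {
  ch <- character(0); pa <- character(0)
  for (ax in kb$axioms) {
    if (ax$kind == "subclass_of") {
      ch <- c(ch, ax$child); pa <- c(pa, ax$parent)
    } else if (ax$kind == "equivalent_to_definition") {
      ch <- c(ch, ax$class); pa <- c(pa, ax$genus)
    }
  }
  df <- data.frame(child = ch, parent = pa, stringsAsFactors = FALSE)
  unique(df)
}

# asserted existential restrictions carried by classes, as
# data.frame(class, property, filler, origin); a defined class carries its
# definition restrictions as necessary conditions
asserted_restrictions <- function(kb) {
  cl <- character(0); pr <- character(0); fi <- character(0); or <- character(0)
  for (ax in kb$axioms) {
    if (ax$kind == "subclass_of_restriction") {
      cl <- c(cl, ax$child); pr <- c(pr, ax$property); fi <- c(fi, ax$filler)
      or <- c(or, "asserted")
    } else if (ax$kind == "equivalent_to_definition") {
      for (r in ax$restrictions) {
        cl <- c(cl, ax$class); pr <- c(pr, r$property); fi <- c(fi, r$filler)
        or <- c(or, "definition")
      }
    }
  }
  unique(data.frame(class = cl, property = pr, filler = fi, origin = or,
                    stringsAsFactors = FALSE))
}

defined_class_axioms <- function(kb) {
  Filter(function(ax) ax$kind == "equivalent_to_definition", kb$axioms)
}

disjoint_axioms <- function(kb) {
  Filter(function(ax) ax$kind == "disjoint", kb$axioms)
}

# topological sort of ids given a child -> parents adjacency (edges df);
# returns list(order = ids leaves-last NULL on cycle, cycle = ids on a cycle)
topo_sort_kb <- function(ids, edges) {
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  indeg <- vapply(parents, length, integer(1)) # number of parents not yet emitted
  children <- split(edges$child, factor(edges$parent, levels = ids))
  queue <- ids[indeg == 0]  # concepts with no parents (roots) first
  order <- character(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    order <- c(order, v)
    for (c in children[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order) < length(ids)) {
    list(order = NULL, cycle = sort_c(setdiff(ids, order)))
  } else {
    list(order = order, cycle = character(0))
  }
}

#' Preferred label lookup
#'
#' Returns the preferred label of a concept in the requested language, falling
#' back to English when absent (the knowledge base guarantees English labels
#' for signs, so the fallback only triggers for optional languages).
#'
#' @param kb A knowledge base.
#' @param id Concept identifier.
#' @param lang Language tag.
#' @param fallback Fall back to English when the language is missing?
#' @return A character scalar, or `NA_character_` when no label exists.
#' @export
kb_pref_label <- function(kb, id, lang = "en", fallback = TRUE) {
  co <- kb$concepts[[id]]
  if (is.null(co)) epokb_stop(paste0("unknown concept: ", id), "epokb_lookup_error")
  pl <- co$pref_labels
  hit <- pl$text[pl$lang == lang]
  if (length(hit)) return(hit[[1]])
  if (fallback && lang != "en") {
    hit <- pl$text[pl$lang == "en"]
    if (length(hit)) return(hit[[1]])
  }
  NA_character_
}

#' Find a concept by its preferred label
#'
#' Exact (case-sensitive) match on the preferred label in the given language;
#' convenient for referring to fixture concepts symbolically.
#'
#' @inheritParams kb_pref_label
#' @param label Label text.
#' @return The concept identifier.
#' @export
kb_concept_by_label <- function(kb, label, lang = "en") {
  for (co in kb$concepts) {
    if (any(co$pref_labels$text == label & co$pref_labels$lang == lang))
      return(co$id)
  }
  epokb_stop(paste0("no concept pref-labelled ", shQuote(label), " [", lang, "]"),
             "epokb_lookup_error")
}

#' Concept categories
#'
#' Derives each concept's category (`sign`, `disorder`, `anatomy`,
#' `technical`, `other`) from its ancestry under the designated roots in the
#' asserted subsumption closure.
#'
#' @param kb A knowledge base.
#' @return Named character vector, one entry per concept.
#' @export
kb_categories <- function(kb) {
  anc <- asserted_ancestors(kb)
  vapply(kb_concept_ids(kb), function(id) {
    a <- anc[[id]]
    if (kb$roots$sign %in% a) "sign"
    else if (kb$roots$disorder %in% a) "disorder"
    else if (kb$roots$anatomy %in% a) "anatomy"
    else if (any(kb$roots$technical %in% a)) "technical"
    else "other"
  }, character(1))
}

# reflexive-transitive closure of asserted edges only (no defined-class
# classification); named list id -> character vector of ancestors
asserted_ancestors <- function(kb) {
  ids <- kb_concept_ids(kb)
  edges <- subclass_edges(kb)
  ts <- topo_sort_kb(ids, edges)
  if (is.null(ts$order))
    epokb_stop(paste0("subsumption cycle involving: ",
                      paste(ts$cycle, collapse = ", ")),
               "epokb_cycle_error", cycle = ts$cycle)
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  anc <- vector("list", length(ids)); names(anc) <- ids
  for (id in ts$order) {
    a <- id
    for (p in parents[[id]]) a <- c(a, anc[[p]])
    anc[[id]] <- unique(a)
  }
  anc
}

#' Structural equality of knowledge bases
#'
#' Field-by-field comparison after normalizing ordering (concepts by id,
#' axioms by a canonical key, label rows by language then text). Used to state
#' round-trip identities.
#'
#' @param a,b Knowledge bases.
#' @return `TRUE` or `FALSE`.
#' @export
kb_equal <- function(a, b) {
  isTRUE(all.equal(kb_normalize(a), kb_normalize(b)))
}

axiom_key <- function(ax) {
  switch(ax$kind,
    subclass_of = paste("1", ax$child, ax$parent),
    subclass_of_restriction = paste("2", ax$child, ax$property, ax$filler),
    equivalent_to_definition = {
      rs <- vapply(ax$restrictions, function(r) paste(r$property, r$filler),
                   character(1))
      paste("3", ax$class, ax$genus, paste(sort_c(rs), collapse = "|"))
    },
    disjoint = paste("4", paste(sort_c(ax$classes), collapse = "|")),
    epokb_stop(paste0("unknown axiom kind: ", ax$kind), "epokb_type_error")
  )
}

kb_normalize <- function(kb) {
  concepts <- kb$concepts[sort_c(kb_concept_ids(kb))]
  concepts <- lapply(concepts, function(co) {
    norm <- function(df) {
      df <- df[order(df$lang, df$text, method = "radix"), , drop = FALSE]
      rownames(df) <- NULL
      df
    }
    co$pref_labels <- norm(co$pref_labels)
    co$alt_labels <- norm(co$alt_labels)
    co$definitions <- norm(co$definitions)
    co$pmids <- sort_c(co$pmids)
    co$image_paths <- sort_c(co$image_paths)
    co$hidden_label <- co$hidden_label %||% NA_character_
    co$fma_id <- co$fma_id %||% NA_character_
    co
  })
  axioms <- kb$axioms
  keys <- vapply(axioms, axiom_key, character(1))
  axioms <- axioms[order(keys, method = "radix")]
  axioms <- lapply(axioms, function(ax) {
    if (ax$kind == "disjoint") ax$classes <- sort_c(ax$classes)
    if (ax$kind == "equivalent_to_definition") {
      rk <- vapply(ax$restrictions, function(r) paste(r$property, r$filler),
                   character(1))
      ax$restrictions <- ax$restrictions[order(rk, method = "radix")]
    }
    ax
  })
  props <- kb$properties[order(kb$properties$id, method = "radix"), , drop = FALSE]
  rownames(props) <- NULL
  list(languages = kb$languages, concepts = concepts, properties = props,
       axioms = axioms, roots = kb$roots)
}
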