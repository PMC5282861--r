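#' @title Turtle subset import/export
#' @description The knowledge base can be exchanged as Turtle restricted to a
#'   documented subset: `rdfs:subClassOf` with a named class or an
#'   `owl:Restriction` node (`owl:onProperty` + `owl:someValuesFrom`),
#'   `owl:equivalentClass` with `owl:intersectionOf` (exactly one named genus
#'   plus one or more restrictions), `owl:disjointWith`, the SKOS annotation
#'   predicates (`prefLabel`, `altLabel`, `definition`, `hiddenLabel`) and the
#'   plain annotation triples `epo:PMID`, `epo:ImagePath`, `epo:FMAID`.
#'   Object properties are declared with `rdfs:subPropertyOf`, and an
#'   `owl:Ontology` header node carries the designated roots
#'   (`epo:signRoot`, `epo:disorderRoot`, `epo:anatomyRoot`,
#'   `epo:technicalRoot`) and configured languages (`epo:language`).
#'   Constructs outside the subset are skipped with a warning on import.
#'   Export ordering is deterministic (concepts by identifier), and a
#'   disjoint set is exported as pairwise `owl:disjointWith` triples, so the
#'   round-trip preserves the deductive closure rather than axiom grouping.
#' @name kb-turtle
NULL

epokb_namespaces <- c(
  epo  = "http://www.semanticweb.org/ontologies/epo.owl#",
  syn  = "urn:epokb:synthetic#",
  skos = "http://www.w3.org/2004/02/skos/core#",
  owl  = "http://www.w3.org/2002/07/owl#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#"
)

KB_HEADER_IRI <- "urn:epokb:kb"

ttl_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  gsub("\r", "\\\\r", x)
}

ttl_lit <- function(text, lang = NULL) {
  s <- paste0("\"", ttl_escape(text), "\"")
  if (!is.null(lang) && !is.na(lang)) s <- paste0(s, "@", lang)
  s
}

# namespace table needed for a KB: canonical prefixes plus a urn fallback for
# any other prefix appearing in identifiers
ttl_prefixes_for <- function(kb) {
  used <- unique(sub(":.*$", "", c(kb_concept_ids(kb)))) # ids are prefix:local
  ns <- epokb_namespaces
  extra <- setdiff(used, names(ns))
  if (length(extra)) {
    more <- paste0("urn:epokb:ns:", extra, "#")
    names(more) <- extra
    ns <- c(ns, more)
  }
  ns
}

ttl_restriction_node <- function(property, filler) {
  paste0("[ a owl:Restriction ; owl:onProperty epo:", property,
         " ; owl:someValuesFrom ", filler, " ]")
}

# --- writer ------------------------------------------------------------------

write_kb_turtle <- function(kb, path) {
  nk <- kb_normalize(kb)
  ns <- ttl_prefixes_for(kb)
  out <- c(paste0("@prefix ", names(ns), ": <", ns, "> ."), "")

  out <- c(out,
    paste0("<", KB_HEADER_IRI, "> a owl:Ontology ;"),
    paste0("    epo:signRoot ", nk$roots$sign, " ;"),
    paste0("    epo:disorderRoot ", nk$roots$disorder, " ;"),
    paste0("    epo:anatomyRoot ", nk$roots$anatomy, " ;"),
    paste0("    epo:technicalRoot ", paste(nk$roots$technical, collapse = ", "), " ;"),
    paste0("    epo:language ", paste(vapply(nk$languages, ttl_lit, character(1)),
                                      collapse = ", "), " ."),
    "")

  props <- nk$properties
  for (i in seq_len(nrow(props))) {
    line <- paste0("epo:", props$id[i], " a owl:ObjectProperty")
    if (!is.na(props$parent[i]))
      line <- paste0(line, " ; rdfs:subPropertyOf epo:", props$parent[i])
    out <- c(out, paste0(line, " ."))
  }
  out <- c(out, "")

  # index axioms by subject concept
  by_subj <- list()
  addline <- function(subj, line) {
    by_subj[[subj]] <<- c(by_subj[[subj]], line)
  }
  for (ax in nk$axioms) {
    switch(ax$kind,
      subclass_of = addline(ax$child, paste0("rdfs:subClassOf ", ax$parent)),
      subclass_of_restriction = addline(
        ax$child, paste0("rdfs:subClassOf ",
                         ttl_restriction_node(ax$property, ax$filler))),
      equivalent_to_definition = {
        parts <- c(ax$genus, vapply(ax$restrictions, function(r)
          ttl_restriction_node(r$property, r$filler), character(1)))
        addline(ax$class,
                paste0("owl:equivalentClass [ a owl:Class ; owl:intersectionOf ( ",
                       paste(parts, collapse = " "), " ) ]"))
      },
      disjoint = {
        cls <- sort_c(ax$classes)
        for (i in seq_along(cls)) for (j in seq_along(cls)) {
          if (i < j) addline(cls[i], paste0("owl:disjointWith ", cls[j]))
        }
      })
  }

  for (co in nk$concepts) {
    lines <- "a owl:Class"
    for (i in seq_len(nrow(co$pref_labels)))
      lines <- c(lines, paste0("skos:prefLabel ",
                               ttl_lit(co$pref_labels$text[i], co$pref_labels$lang[i])))
    for (i in seq_len(nrow(co$alt_labels)))
      lines <- c(lines, paste0("skos:altLabel ",
                               ttl_lit(co$alt_labels$text[i], co$alt_labels$lang[i])))
    for (i in seq_len(nrow(co$definitions)))
      lines <- c(lines, paste0("skos:definition ",
                               ttl_lit(co$definitions$text[i], co$definitions$lang[i])))
    if (!is.na(co$hidden_label))
      lines <- c(lines, paste0("skos:hiddenLabel ", ttl_lit(co$hidden_label)))
    if (!is.na(co$fma_id))
      lines <- c(lines, paste0("epo:FMAID ", ttl_lit(co$fma_id)))
    for (p in co$pmids) lines <- c(lines, paste0("epo:PMID ", ttl_lit(p)))
    for (p in co$image_paths) lines <- c(lines, paste0("epo:ImagePath ", ttl_lit(p)))
    lines <- c(lines, by_subj[[co$id]])
    out <- c(out,
             paste0(co$id, " ", lines[1], " ;"),
             paste0("    ", lines[-1], c(rep(" ;", length(lines) - 2), " .")),
             "")
    if (length(lines) == 1) {
      # concept with no annotations or axioms: terminate the single line
      out[length(out) - 1] <- paste0(co$id, " ", lines[1], " .")
    }
  }

  writeLines(out, path, useBytes = TRUE)
  invisible(NULL)
}

# --- tokenizer ---------------------------------------------------------------

# token: list(type, value, lang, line); types: pname, iri, literal, punct
ttl_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", 0L)
  i <- 1L; line <- 1L
  push <- function(type, value, lang = NA_character_) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value,
                                       lang = lang, line = line)
  }
  name_char <- function(ch) grepl("[A-Za-z0-9_.:%-]", ch)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push("punct", ch); i <- i + 1L; next
    }
    if (ch == "<") {
      j <- i + 1L; buf <- character(0)
      while (j <= n && chars[j] != ">") { buf <- c(buf, chars[j]); j <- j + 1L }
      if (j > n) epokb_stop(paste0("unterminated IRI at line ", line),
                            "epokb_format_error")
      push("iri", paste(buf, collapse = "")); i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L; buf <- character(0)
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\\" && j < n) {
          esc <- chars[j + 1L]
          buf <- c(buf, switch(esc, n = "\n", r = "\r", t = "\t",
                               "\"" = "\"", "\\" = "\\", esc))
          j <- j + 2L
        } else {
          if (chars[j] == "\n") line <- line + 1L
          buf <- c(buf, chars[j]); j <- j + 1L
        }
      }
      if (j > n) epokb_stop(paste0("unterminated string at line ", line),
                            "epokb_format_error")
      i <- j + 1L
      lang <- NA_character_
      if (i <= n && chars[i] == "@") {
        j <- i + 1L; lb <- character(0)
        while (j <= n && grepl("[A-Za-z-]", chars[j])) { lb <- c(lb, chars[j]); j <- j + 1L }
        lang <- paste(lb, collapse = ""); i <- j
      } else if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
        # typed literal: consume the datatype, keep the lexical form
        i <- i + 2L
        if (i <= n && chars[i] == "<") { while (i <= n && chars[i] != ">") i <- i + 1L; i <- i + 1L }
        else { while (i <= n && name_char(chars[i])) i <- i + 1L }
      }
      push("literal", paste(buf, collapse = ""), lang); next
    }
    if (ch == "@") { # @prefix / @base directive keyword
      j <- i + 1L; buf <- character(0)
      while (j <= n && grepl("[a-z]", chars[j])) { buf <- c(buf, chars[j]); j <- j + 1L }
      push("directive", paste(buf, collapse = "")); i <- j; next
    }
    if (name_char(ch)) {
      j <- i; buf <- character(0)
      while (j <= n && name_char(chars[j])) { buf <- c(buf, chars[j]); j <- j + 1L }
      word <- paste(buf, collapse = "")
      if (identical(word, "a")) push("pname", "rdf:type") else push("pname", word)
      i <- j; next
    }
    epokb_stop(paste0("unexpected character ", shQuote(ch), " at line ", line),
               "epokb_format_error")
  }
  toks
}

# --- parser ------------------------------------------------------------------

read_kb_turtle <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  toks <- ttl_tokenize(text)
  pos <- 1L
  eof <- list(type = "eof", value = "", lang = NA_character_, line = NA_integer_)
  peek <- function() if (pos <= length(toks)) toks[[pos]] else eof
  advance <- function() {
    t <- peek()
    if (t$type == "eof")
      epokb_stop("unexpected end of file (missing '.'?)", "epokb_format_error")
    pos <<- pos + 1L
    t
  }
  expect_punct <- function(p) {
    t <- peek()
    if (t$type != "punct" || t$value != p)
      epokb_stop(paste0("expected ", shQuote(p), " at line ",
                        if (t$type == "eof") "<eof>" else t$line),
                 "epokb_format_error")
    advance()
  }

  prefixes <- character(0)    # prefix name -> namespace IRI
  # resolve an iri/pname token to a compact identifier
  compact <- function(t) {
    if (t$type == "pname") {
      p <- sub(":.*$", "", t$value)
      if (grepl(":", t$value, fixed = TRUE) && (p %in% names(prefixes))) {
        full <- paste0(prefixes[[p]], sub("^[^:]*:", "", t$value))
        return(recompact(full))
      }
      return(t$value)
    }
    if (t$type == "iri") return(recompact(t$value))
    epokb_stop(paste0("expected a resource at line ", t$line), "epokb_format_error")
  }
  # re-compact a full IRI against the canonical namespaces, else keep as-is
  recompact <- function(iri) {
    for (p in names(epokb_namespaces)) {
      nsiri <- epokb_namespaces[[p]]
      if (startsWith(iri, nsiri))
        return(paste0(p, ":", substring(iri, nchar(nsiri) + 1L)))
    }
    for (p in names(prefixes)) {
      if (startsWith(iri, prefixes[[p]]))
        return(paste0(p, ":", substring(iri, nchar(prefixes[[p]]) + 1L)))
    }
    iri
  }

  # object := resource | literal | bnode property list | collection
  parse_object <- function() {
    t <- peek()
    if (t$type == "literal") { advance(); return(list(kind = "literal", text = t$value, lang = t$lang)) }
    if (t$type == "punct" && t$value == "[") {
      advance()
      po <- list()
      while (!(peek()$type == "punct" && peek()$value == "]")) {
        pred <- compact(advance())
        objs <- list(parse_object())
        while (peek()$type == "punct" && peek()$value == ",") {
          advance(); objs[[length(objs) + 1L]] <- parse_object()
        }
        po[[length(po) + 1L]] <- list(pred = pred, objects = objs)
        if (peek()$type == "punct" && peek()$value == ";") advance()
      }
      expect_punct("]")
      return(list(kind = "bnode", po = po))
    }
    if (t$type == "punct" && t$value == "(") {
      advance()
      items <- list()
      while (!(peek()$type == "punct" && peek()$value == ")"))
        items[[length(items) + 1L]] <- parse_object()
      expect_punct(")")
      return(list(kind = "collection", items = items))
    }
    list(kind = "name", id = compact(advance()))
  }

  statements <- list()   # list of (subject, pred, object)
  while (peek()$type != "eof") {
    t <- peek()
    if (t$type == "directive") {
      advance()
      if (t$value == "prefix") {
        ptok <- advance()  # "p:"
        iritok <- advance()
        pname <- sub(":$", "", ptok$value)
        prefixes[[pname]] <- iritok$value
        expect_punct(".")
      } else if (t$value == "base") {
        advance(); expect_punct(".")
      } else {
        epokb_stop(paste0("unsupported directive @", t$value, " at line ", t$line),
                   "epokb_format_error")
      }
      next
    }
    subj <- compact(advance())
    repeat {
      pred <- compact(advance())
      repeat {
        obj <- parse_object()
        statements[[length(statements) + 1L]] <-
          list(subject = subj, pred = pred, object = obj)
        if (peek()$type == "punct" && peek()$value == ",") { advance(); next }
        break
      }
      t2 <- peek()
      if (t2$type == "punct" && t2$value == ";") {
        advance()
        # tolerate trailing ';' before '.'
        t3 <- peek()
        if (t3$type == "punct" && t3$value == ".") { advance(); break }
        next
      }
      expect_punct(".")
      break
    }
  }

  build_kb_from_statements(statements)
}

# interpret the restriction bnode of the subset; NULL when not a restriction
as_restriction <- function(obj) {
  if (obj$kind != "bnode") return(NULL)
  prop <- NULL; filler <- NULL; is_restr <- FALSE
  for (po in obj$po) {
    if (po$pred == "rdf:type" &&
        any(vapply(po$objects, function(o) identical(o$id, "owl:Restriction"),
                   logical(1)))) is_restr <- TRUE
    if (po$pred == "owl:onProperty") prop <- po$objects[[1]]$id
    if (po$pred == "owl:someValuesFrom") filler <- po$objects[[1]]$id
  }
  if (!is_restr || is.null(prop) || is.null(filler)) return(NULL)
  list(property = sub("^epo:", "", prop), filler = filler)
}

build_kb_from_statements <- function(statements) {
  concepts <- list()        # id -> list of annotation accumulators
  axioms <- list()
  props <- list()           # id -> parent
  roots <- list(sign = NULL, disorder = NULL, anatomy = NULL,
                technical = character(0))
  languages <- character(0)
  header_subjects <- character(0)
  prop_subjects <- character(0)
  skipped <- character(0)

  ensure_concept <- function(id) {
    if (is.null(concepts[[id]]))
      concepts[[id]] <<- list(pref = list(), alt = list(), def = list(),
                              hidden = NULL, fma = NULL,
                              pmids = character(0), paths = character(0),
                              declared = FALSE)
  }

  # first pass: find header / property subjects from rdf:type
  for (st in statements) {
    if (st$pred == "rdf:type" && st$object$kind == "name") {
      if (st$object$id == "owl:Ontology")
        header_subjects <- c(header_subjects, st$subject)
      if (st$object$id == "owl:ObjectProperty")
        prop_subjects <- c(prop_subjects, st$subject)
    }
  }

  lit_or_skip <- function(st) {
    if (st$object$kind == "literal") return(st$object)
    skipped <<- c(skipped, paste0(st$pred, " with non-literal object"))
    NULL
  }

  for (st in statements) {
    s <- st$subject
    if (s %in% header_subjects) {
      if (st$pred == "epo:signRoot") roots$sign <- st$object$id
      else if (st$pred == "epo:disorderRoot") roots$disorder <- st$object$id
      else if (st$pred == "epo:anatomyRoot") roots$anatomy <- st$object$id
      else if (st$pred == "epo:technicalRoot")
        roots$technical <- c(roots$technical, st$object$id)
      else if (st$pred == "epo:language") languages <- c(languages, st$object$text)
      else if (st$pred != "rdf:type")
        skipped <- c(skipped, paste0("header ", st$pred))
      next
    }
    if (s %in% prop_subjects) {
      pid <- sub("^epo:", "", s)
      if (is.null(props[[pid]])) props[[pid]] <- NA_character_
      if (st$pred == "rdfs:subPropertyOf")
        props[[pid]] <- sub("^epo:", "", st$object$id)
      else if (st$pred != "rdf:type")
        skipped <- c(skipped, paste0("property ", st$pred))
      next
    }

    switch(st$pred,
      "rdf:type" = {
        if (st$object$kind == "name" && st$object$id == "owl:Class") {
          ensure_concept(s); concepts[[s]]$declared <- TRUE
        } else skipped <- c(skipped, paste0("type ", st$object$id %||% "<node>"))
      },
      "rdfs:subClassOf" = {
        ensure_concept(s)
        if (st$object$kind == "name") {
          axioms[[length(axioms) + 1L]] <- ax_subclass(s, st$object$id)
        } else {
          r <- as_restriction(st$object)
          if (is.null(r)) skipped <- c(skipped, "rdfs:subClassOf with unsupported node")
          else axioms[[length(axioms) + 1L]] <- ax_restriction(s, r$property, r$filler)
        }
      },
      "owl:equivalentClass" = {
        ensure_concept(s)
        ok <- FALSE
        if (st$object$kind == "bnode") {
          for (po in st$object$po) {
            if (po$pred == "owl:intersectionOf" &&
                po$objects[[1]]$kind == "collection") {
              items <- po$objects[[1]]$items
              genus <- NULL; restrictions <- list()
              for (it in items) {
                if (it$kind == "name" && is.null(genus)) genus <- it$id
                else {
                  r <- as_restriction(it)
                  if (!is.null(r)) restrictions[[length(restrictions) + 1L]] <- r
                  else if (it$kind == "name")
                    skipped <- c(skipped, "intersection with more than one named class")
                }
              }
              if (!is.null(genus) && length(restrictions)) {
                axioms[[length(axioms) + 1L]] <- ax_defined(s, genus, restrictions)
                ok <- TRUE
              }
            }
          }
        }
        if (!ok) skipped <- c(skipped, "owl:equivalentClass outside subset")
      },
      "owl:disjointWith" = {
        ensure_concept(s)
        if (st$object$kind == "name")
          axioms[[length(axioms) + 1L]] <- ax_disjoint(c(s, st$object$id))
        else skipped <- c(skipped, "owl:disjointWith with non-named object")
      },
      "skos:prefLabel" = { ensure_concept(s); l <- lit_or_skip(st)
        if (!is.null(l)) concepts[[s]]$pref[[length(concepts[[s]]$pref) + 1L]] <-
          list(text = l$text, lang = l$lang %||% "en") },
      "skos:altLabel" = { ensure_concept(s); l <- lit_or_skip(st)
        if (!is.null(l)) concepts[[s]]$alt[[length(concepts[[s]]$alt) + 1L]] <-
          list(text = l$text, lang = l$lang %||% "en") },
      "skos:definition" = { ensure_concept(s); l <- lit_or_skip(st)
        if (!is.null(l)) concepts[[s]]$def[[length(concepts[[s]]$def) + 1L]] <-
          list(text = l$text, lang = l$lang %||% "en") },
      "skos:hiddenLabel" = { ensure_concept(s); l <- lit_or_skip(st)
        if (!is.null(l)) concepts[[s]]$hidden <- l$text },
      "epo:FMAID" = { ensure_concept(s); l <- lit_or_skip(st)
        if (!is.null(l)) concepts[[s]]$fma <- l$text },
      "epo:PMID" = { ensure_concept(s); l <- lit_or_skip(st)
        if (!is.null(l)) concepts[[s]]$pmids <- c(concepts[[s]]$pmids, l$text) },
      "epo:ImagePath" = { ensure_concept(s); l <- lit_or_skip(st)
        if (!is.null(l)) concepts[[s]]$paths <- c(concepts[[s]]$paths, l$text) },
      skipped <- c(skipped, st$pred)
    )
  }

  if (length(skipped))
    warning("skipped constructs outside the Turtle subset: ",
            paste(unique(skipped), collapse = "; "), call. = FALSE)

  if (is.null(roots$sign) || is.null(roots$disorder) || is.null(roots$anatomy) ||
      length(roots$technical) == 0)
    epokb_stop("Turtle file lacks the ontology header declaring the roots",
               "epokb_format_error")

  lang_from_acc <- function(l) {
    if (!length(l)) return(lang_df(NULL))
    lang <- vapply(l, function(x) if (is.na(x$lang)) "en" else x$lang, character(1))
    data.frame(text = vapply(l, `[[`, character(1), "text"), lang = lang,
               stringsAsFactors = FALSE)
  }
  concept_objs <- lapply(names(concepts), function(id) {
    acc <- concepts[[id]]
    epo_concept(id,
                pref_labels = lang_from_acc(acc$pref),
                alt_labels = lang_from_acc(acc$alt),
                definitions = lang_from_acc(acc$def),
                hidden_label = acc$hidden, fma_id = acc$fma,
                pmids = acc$pmids, image_paths = acc$paths)
  })

  properties <- if (length(props)) {
    data.frame(id = names(props), parent = unlist(props, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else default_properties()

  epo_kb(concept_objs, axioms,
         sign_root = roots$sign, disorder_root = roots$disorder,
         anatomy_root = roots$anatomy, technical_roots = roots$technical,
         languages = if (length(languages)) unique(languages) else c("en", "fr"),
         properties = properties)
}
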