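# Brute-force oracles, independent of the package's reasoner code path:
# reachability by boolean matrix powers, classification by exhaustive
# per-concept checks with full matrix recomputation, materialization and
# suggestion by nested-loop enumeration.

# reflexive-transitive closure of edges (data.frame child, parent) over ids,
# via repeated squaring of the boolean adjacency matrix
oracle_closure_matrix <- function(ids, edges) {
  n <- length(ids)
  M <- diag(TRUE, n)
  dimnames(M) <- list(ids, ids)
  if (nrow(edges)) M[cbind(edges$child, edges$parent)] <- TRUE
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M > 0)) break
    M <- M2
  }
  M > 0
}

oracle_prop_anc <- function(props, p) {
  anc <- character(0); cur <- p
  while (!is.na(cur)) {
    anc <- c(anc, cur)
    cur <- props$parent[match(cur, props$id)]
  }
  anc
}

# all asserted restriction rows (subclass-of-restriction axioms plus the
# necessary side of defined-class axioms)
oracle_restrictions <- function(kb) {
  rows <- list()
  for (ax in kb$axioms) {
    if (ax$kind == "subclass_of_restriction") {
      rows[[length(rows) + 1L]] <- c(ax$child, ax$property, ax$filler)
    } else if (ax$kind == "equivalent_to_definition") {
      for (r in ax$restrictions)
        rows[[length(rows) + 1L]] <- c(ax$class, r$property, r$filler)
    }
  }
  if (!length(rows)) {
    return(data.frame(class = character(0), property = character(0),
                      filler = character(0)))
  }
  m <- do.call(rbind, rows)
  unique(data.frame(class = m[, 1], property = m[, 2], filler = m[, 3],
                    stringsAsFactors = FALSE))
}

oracle_subclass_edges <- function(kb) {
  ch <- character(0); pa <- character(0)
  for (ax in kb$axioms) {
    if (ax$kind == "subclass_of") { ch <- c(ch, ax$child); pa <- c(pa, ax$parent) }
    if (ax$kind == "equivalent_to_definition") { ch <- c(ch, ax$class); pa <- c(pa, ax$genus) }
  }
  unique(data.frame(child = ch, parent = pa, stringsAsFactors = FALSE))
}

# full inference oracle: returns the closure matrix (after classification)
# and the defined-membership edge list, by adding one satisfying membership
# at a time and recomputing the matrix closure from scratch
oracle_infer <- function(kb) {
  ids <- names(kb$concepts)
  edges <- oracle_subclass_edges(kb)
  restr <- oracle_restrictions(kb)
  defs <- Filter(function(a) a$kind == "equivalent_to_definition", kb$axioms)
  M0 <- oracle_closure_matrix(ids, edges)
  M <- M0
  repeat {
    added <- FALSE
    for (ax in defs) {
      for (s in ids) {
        if (s == ax$class || M[s, ax$class]) next
        if (!M[s, ax$genus]) next
        ok <- TRUE
        for (r in ax$restrictions) {
          sat <- FALSE
          for (i in seq_len(nrow(restr))) {
            if (M[s, restr$class[i]] &&
                r$property %in% oracle_prop_anc(kb$properties, restr$property[i]) &&
                M[restr$filler[i], r$filler]) { sat <- TRUE; break }
          }
          if (!sat) { ok <- FALSE; break }
        }
        if (ok) {
          edges <- rbind(edges, data.frame(child = s, parent = ax$class,
                                           stringsAsFactors = FALSE))
          M <- oracle_closure_matrix(ids, edges)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  mem <- data.frame(child = character(0), parent = character(0),
                    stringsAsFactors = FALSE)
  for (ax in defs) {
    m <- ids[M[, ax$class] & !M0[, ax$class] & ids != ax$class]
    if (length(m))
      mem <- rbind(mem, data.frame(child = m, parent = ax$class,
                                   stringsAsFactors = FALSE))
  }
  mem <- mem[order(mem$child, mem$parent, method = "radix"), , drop = FALSE]
  rownames(mem) <- NULL
  list(M = M, members = mem)
}

# exhaustive enumeration of (sign, ancestor, restriction, filler-ancestor)
oracle_materialize <- function(kb, M) {
  ids <- rownames(M)
  restr <- oracle_restrictions(kb)
  signs <- ids[M[, kb$roots$sign]]
  root_for <- function(p) {
    if (p == "suggests") kb$roots$disorder
    else if (p == "hasLocation") kb$roots$anatomy
    else kb$roots$technical
  }
  out <- character(0)
  for (s in signs) {
    for (i in seq_len(nrow(restr))) {
      if (!M[s, restr$class[i]]) next
      for (p in oracle_prop_anc(kb$properties, restr$property[i])) {
        roots <- root_for(p)
        for (c in ids[M[restr$filler[i], ]]) {
          if (c %in% roots) next
          if (any(M[c, roots])) out <- c(out, paste(s, p, c))
        }
      }
    }
  }
  sort(unique(out))
}

# direct nested-loop evaluation of the type-suggestion query semantics
oracle_suggest_types <- function(kb, selected, M, lang = "en") {
  edges <- oracle_subclass_edges(kb)
  restr <- oracle_restrictions(kb)
  # direct children of the disorder root in the inferred graph: asserted
  # edge or entailed defined membership one step under the root
  inf <- oracle_infer(kb)
  one_step <- unique(c(edges$child[edges$parent == kb$roots$disorder],
                       inf$members$child[inf$members$parent == kb$roots$disorder]))
  hits <- character(0)
  for (D in one_step) {
    found <- FALSE
    for (s in selected) {
      for (i in seq_len(nrow(restr))) {
        if (restr$property[i] == "suggests" && M[s, restr$class[i]] &&
            M[restr$filler[i], D]) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, D)
  }
  labs <- vapply(hits, function(i) kb_pref_label(kb, i, lang), character(1))
  hits[order(tolower(labs), hits, method = "radix")]
}

# small random KB wrapper with common defaults for property tests
random_kb_case <- function(seed, n = NULL) {
  if (is.null(n)) n <- 10 + (seed * 7L) %% 71L
  generate_random_kb(n_concepts = n,
                     max_parents = 1 + seed %% 3L,
                     n_defined = seed %% 5L,
                     restriction_density = 0.2 + (seed %% 4L) * 0.15,
                     seed = seed)
}

# a tiny hand-built KB: sign root S, disorder root D, anatomy root A and
# technical roots R1 R2 R3, plus optional extra concepts/axioms
tiny_kb <- function(extra_concepts = list(), extra_axioms = list()) {
  roots <- list(
    epo_concept("t:S", c(en = "sign root"), definitions = c(en = "root")),
    epo_concept("t:D", c(en = "disorder root")),
    epo_concept("t:A", c(en = "anatomy root")),
    epo_concept("t:R1", c(en = "route root")),
    epo_concept("t:R2", c(en = "mode root")),
    epo_concept("t:R3", c(en = "view root")))
  epo_kb(c(roots, extra_concepts), extra_axioms,
         sign_root = "t:S", disorder_root = "t:D", anatomy_root = "t:A",
         technical_roots = c("t:R1", "t:R2", "t:R3"))
}

sign_concept <- function(id, label) {
  epo_concept(id, c(en = label), definitions = c(en = paste("def of", label)))
}
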