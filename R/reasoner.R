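#' @title Subsumption reasoner
#' @description A native replacement for the OWL-DL reasoner used to maintain
#'   the knowledge base, restricted to the EL-style fragment the knowledge
#'   base actually uses: conjunction, existential restriction and subproperty
#'   expansion. Classification of defined classes and propagation of sign
#'   relations both run to fixpoint and are deterministic.
#' @name reasoner
NULL

# invert an ancestors map into a descendants map (both reflexive)
descendants_map <- function(anc) {
  ids <- names(anc)
  child <- rep(ids, lengths(anc))
  parent <- unlist(anc, use.names = FALSE)
  split(child, factor(parent, levels = ids))
}

# the inference core: asserted closure + defined-class classification to
# fixpoint; returns ancestors, the asserted edge list and defined edges
infer_kb <- function(kb) {
  ids <- kb_concept_ids(kb)
  asserted <- subclass_edges(kb)
  edges <- asserted
  anc <- asserted_ancestors(kb)
  defs <- defined_class_axioms(kb)
  restr <- asserted_restrictions(kb)
  prop_anc <- lapply(stats::setNames(kb$properties$id, kb$properties$id),
                     function(p) property_ancestors(kb$properties, p))
  defined_edges <- data.frame(child = character(0), parent = character(0),
                              stringsAsFactors = FALSE)
  if (!length(defs)) {
    return(list(ancestors = anc, asserted_edges = asserted,
                defined_edges = defined_edges))
  }

  repeat {
    desc <- descendants_map(anc)
    new_child <- character(0); new_parent <- character(0)
    for (ax in defs) {
      # concepts satisfying every required existential of the definition:
      # start from descendants of the genus, intersect per requirement with
      # the concepts inheriting a compatible restriction
      members <- desc[[ax$genus]]
      for (r in ax$restrictions) {
        ok <- vapply(seq_len(nrow(restr)), function(i) {
          (r$property %in% prop_anc[[restr$property[i]]]) &&
            (r$filler %in% anc[[restr$filler[i]]])
        }, logical(1))
        carriers <- unique(unlist(desc[restr$class[ok]], use.names = FALSE))
        members <- intersect(members, carriers)
        if (!length(members)) break
      }
      members <- setdiff(members, ax$class)
      members <- members[!vapply(members, function(s) ax$class %in% anc[[s]],
                                 logical(1))]
      if (length(members)) {
        up <- members[vapply(members, function(s) s %in% anc[[ax$class]],
                             logical(1))]
        if (length(up))
          epokb_stop(paste0("classification would create a subsumption cycle: ",
                            paste(up, collapse = ", "), " <-> ", ax$class),
                     "epokb_cycle_error", cycle = c(up, ax$class))
        new_child <- c(new_child, members)
        new_parent <- c(new_parent, rep(ax$class, length(members)))
      }
    }
    if (!length(new_child)) break
    defined_edges <- unique(rbind(defined_edges,
      data.frame(child = new_child, parent = new_parent,
                 stringsAsFactors = FALSE)))
    edges <- unique(rbind(asserted, defined_edges))
    ts <- topo_sort_kb(ids, edges)
    if (is.null(ts$order))
      epokb_stop(paste0("subsumption cycle after classification: ",
                        paste(ts$cycle, collapse = ", ")),
                 "epokb_cycle_error", cycle = ts$cycle)
    parents <- split(edges$parent, factor(edges$child, levels = ids))
    anc <- stats::setNames(vector("list", length(ids)), ids)
    for (id in ts$order) {
      a <- id
      for (p in parents[[id]]) a <- c(a, anc[[p]])
      anc[[id]] <- unique(a)
    }
  }
  # report every entailed-but-not-asserted membership in a defined class,
  # independent of the order in which the fixpoint discovered it (a
  # descendant of a member is itself a member)
  anc0 <- asserted_ancestors(kb)
  ch <- character(0); pa <- character(0)
  for (ax in defs) {
    mem <- names(anc)[vapply(names(anc), function(s)
      s != ax$class && (ax$class %in% anc[[s]]) && !(ax$class %in% anc0[[s]]),
      logical(1))]
    ch <- c(ch, mem); pa <- c(pa, rep(ax$class, length(mem)))
  }
  defined_edges <- data.frame(child = ch, parent = pa, stringsAsFactors = FALSE)
  defined_edges <- defined_edges[order(defined_edges$child, defined_edges$parent,
                                       method = "radix"), , drop = FALSE]
  rownames(defined_edges) <- NULL
  list(ancestors = anc, asserted_edges = asserted, defined_edges = defined_edges)
}

#' Compute the subsumption closure
#'
#' Reflexive-transitive closure of the asserted subclass edges together with
#' the edges contributed by defined-class classification (see
#' [classify_defined()]), computed to fixpoint. The result is a partial
#' order; a cycle (asserted or created by classification) raises an error
#' naming the concepts involved.
#'
#' @param kb A knowledge base; must pass [validate_kb()].
#' @param validate Validate `kb` first (default `TRUE`).
#' @return An object of class `epo_closure`: list with `ancestors` (named
#'   list, concept -> reflexive ancestor set) and `edges` (data.frame
#'   `child`, `parent`, `provenance` in `{asserted, defined_class}`).
#' @export
compute_closure <- function(kb, validate = TRUE) {
  if (validate) assert_valid_kb(kb)
  inf <- infer_kb(kb)
  edges <- rbind(
    cbind(inf$asserted_edges, provenance = "asserted"),
    if (nrow(inf$defined_edges))
      cbind(inf$defined_edges, provenance = "defined_class")
  )
  edges <- edges[order(edges$child, edges$parent, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(ancestors = inf$ancestors, edges = edges),
            class = "epo_closure")
}

#' @export
print.epo_closure <- function(x, ...) {
  cat(sprintf("<epo_closure> %d concepts, %d edges (%d from defined classes)\n",
              length(x$ancestors), nrow(x$edges),
              sum(x$edges$provenance == "defined_class")))
  invisible(x)
}

#' Classify defined classes
#'
#' A concept `S` is placed under a defined class `D` (equivalent to a genus
#' `G` intersected with existential restrictions) exactly when `S` is
#' subsumed by `G` and, for every required restriction `p some C`, `S`
#' carries an asserted or inherited restriction `p' some C'` with `p'` equal
#' to or below `p` in the property hierarchy and `C'` subsumed by `C`.
#' Iterated to fixpoint, since new memberships (and the restrictions a
#' defined-class parent carries) can enable further ones. Monotone in the
#' asserted restrictions. The returned edge list contains every entailed
#' membership that is not asserted — in particular, descendants of a member
#' are members — so the result is independent of discovery order.
#'
#' @inheritParams compute_closure
#' @return A data.frame of inferred edges `child`, `parent`, `provenance`
#'   (always `"defined_class"`), sorted.
#' @export
classify_defined <- function(kb, validate = TRUE) {
  if (validate) assert_valid_kb(kb)
  inf <- infer_kb(kb)
  out <- inf$defined_edges
  out$provenance <- rep("defined_class", nrow(out))
  out
}

# root set against which objects of a property are reported
roots_for_property <- function(kb, p) {
  if (p == "suggests") kb$roots$disorder
  else if (p == "hasLocation") kb$roots$anatomy
  else kb$roots$technical   # requires and its children
}

#' Materialize inferred sign relations
#'
#' Propagates the sign-centric relations through the subsumption hierarchies:
#' the result contains `(s, p, c)` exactly when some ancestor `s'` of a sign
#' `s` carries an asserted restriction `p' some c'` with `p'` at or below `p`
#' in the property hierarchy, and `c` is a named ancestor of `c'` lying
#' strictly under the root appropriate for `p` (ectopic-pregnancy types for
#' `suggests`, anatomy for `hasLocation`, the technical hierarchies for
#' `requires` and its children). Provenance records how each triple arose:
#' `asserted`, `inherited_from:<ancestor>` or `filler_generalized:<filler>`.
#'
#' @param kb A knowledge base.
#' @param closure The [compute_closure()] result for `kb`.
#' @return A data.frame `subject`, `property`, `object`, `provenance`,
#'   sorted by subject, property, object; duplicate-free.
#' @export
materialize_relations <- function(kb, closure) {
  anc <- closure$ancestors
  desc <- descendants_map(anc)
  signs <- desc[[kb$roots$sign]]
  restr <- asserted_restrictions(kb)
  subj <- character(0); prop <- character(0); obj <- character(0)
  from_cls <- character(0); from_fil <- character(0)
  for (i in seq_len(nrow(restr))) {
    ss <- intersect(desc[[restr$class[i]]], signs)
    if (!length(ss)) next
    for (p in property_ancestors(kb$properties, restr$property[i])) {
      roots <- roots_for_property(kb, p)
      objs <- anc[[restr$filler[i]]]
      objs <- objs[vapply(objs, function(c)
        any(roots %in% anc[[c]]) && !(c %in% roots), logical(1))]
      if (!length(objs)) next
      grid_s <- rep(ss, each = length(objs))
      grid_o <- rep(objs, times = length(ss))
      subj <- c(subj, grid_s); obj <- c(obj, grid_o)
      prop <- c(prop, rep(p, length(grid_s)))
      from_cls <- c(from_cls, rep(restr$class[i], length(grid_s)))
      from_fil <- c(from_fil, rep(restr$filler[i], length(grid_s)))
    }
  }
  if (!length(subj)) {
    return(data.frame(subject = character(0), property = character(0),
                      object = character(0), provenance = character(0),
                      stringsAsFactors = FALSE))
  }
  provenance <- ifelse(subj != from_cls, paste0("inherited_from:", from_cls),
                ifelse(obj != from_fil, paste0("filler_generalized:", from_fil),
                       "asserted"))
  rank <- ifelse(provenance == "asserted", 0L,
          ifelse(startsWith(provenance, "inherited_from"), 1L, 2L))
  df <- data.frame(subject = subj, property = prop, object = obj,
                   provenance = provenance, rank = rank,
                   stringsAsFactors = FALSE)
  df <- df[order(df$subject, df$property, df$object, df$rank, df$provenance,
                 method = "radix"), , drop = FALSE]
  key <- paste(df$subject, df$property, df$object)
  df <- df[!duplicated(key), c("subject", "property", "object", "provenance")]
  rownames(df) <- NULL
  df
}

#' Check disjointness consistency
#'
#' Reports every concept whose ancestor set (after classification) contains
#' two classes declared disjoint.
#'
#' @inheritParams materialize_relations
#' @return A data.frame `concept`, `disjoint_a`, `disjoint_b`; zero rows when
#'   consistent.
#' @export
check_consistency <- function(kb, closure) {
  out <- list()
  for (ax in disjoint_axioms(kb)) {
    cls <- sort_c(ax$classes)
    for (id in names(closure$ancestors)) {
      hit <- cls[cls %in% closure$ancestors[[id]]]
      if (length(hit) >= 2) {
        pairs <- utils::combn(hit, 2)
        out[[length(out) + 1L]] <- data.frame(
          concept = id, disjoint_a = pairs[1, ], disjoint_b = pairs[2, ],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(concept = character(0), disjoint_a = character(0),
                      disjoint_b = character(0), stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, out))
  df <- df[order(df$concept, df$disjoint_a, df$disjoint_b, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
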