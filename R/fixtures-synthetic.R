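#' @title Synthetic generators
#' @description Seeded generators for random knowledge bases (with planted
#'   ground truth for the reasoner) and annotation sessions (with a known
#'   observer error model), used for property-style testing at scales the
#'   published fixture cannot provide. All generators are pure functions of
#'   their parameters and seed and do not disturb the caller's RNG state.
#' @name synthetic
NULL

# evaluate expr under a local RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random knowledge base with planted ground truth
#'
#' Builds a DAG taxonomy top-down under six synthetic roots (sign, type,
#' anatomy, route, mode, view), plants existential restrictions on sign
#' concepts and appends defined sign classes whose genus may be another
#' defined class (so classification must iterate). Alongside the knowledge
#' base, returns ground truth recorded during generation: the planted
#' ancestor sets of the asserted taxonomy and the defined-class memberships
#' obtained by direct set evaluation in a naive fixpoint, independent of the
#' reasoner's code path.
#'
#' @param n_concepts Total concepts including the six roots (>= 6).
#' @param max_parents Maximum parents drawn per concept (>= 1).
#' @param n_defined Number of defined sign classes appended.
#' @param restriction_density Mean number of planted restrictions per sign
#'   concept (binomial on 3 trials).
#' @param seed RNG seed.
#' @return A list with `kb`, `ground_truth` (list `ancestors`,
#'   `defined_members`) and `params`.
#' @export
generate_random_kb <- function(n_concepts = 60, max_parents = 2, n_defined = 3,
                               restriction_density = 0.3, seed = 1) {
  if (n_concepts < 6)
    epokb_stop("n_concepts must be >= 6 (the roots)", "epokb_domain_error")
  if (max_parents < 1)
    epokb_stop("max_parents must be >= 1", "epokb_domain_error")
  # a drawn world is rejected (deterministically re-drawn from a derived
  # seed) only when two defined classes turn out mutually subsuming, which
  # the data model forbids as a cycle
  for (attempt in 0:49) {
    out <- with_seed((seed + attempt * 10007L) %% 2147483647L,
                     generate_kb_once(n_concepts, max_parents, n_defined,
                                      restriction_density))
    if (!is.null(out)) {
      out$params <- list(n_concepts = n_concepts, max_parents = max_parents,
                         n_defined = n_defined,
                         restriction_density = restriction_density, seed = seed)
      return(out)
    }
  }
  epokb_stop("could not draw a non-degenerate knowledge base", "epokb_internal")
}

generate_kb_once <- function(n_concepts, max_parents, n_defined,
                             restriction_density) {
  {
    cats <- c("sign", "disorder", "anatomy", "route", "mode", "view")
    root_of <- stats::setNames(paste0("syn:C", 1:6), cats)
    cid <- function(i) paste0("syn:C", i)
    concepts <- list(); cat_of <- character(0)
    anc <- list()                         # planted reflexive ancestor sets
    mk <- function(i, cat, defn = "synthetic concept") {
      concepts[[length(concepts) + 1L]] <<- epo_concept(
        cid(i), pref_labels = c(en = paste("concept", i)),
        definitions = c(en = paste(defn, i)))
      cat_of[cid(i)] <<- cat
    }
    for (i in 1:6) { mk(i, cats[i]); anc[[cid(i)]] <- cid(i) }
    axioms <- list()
    n_plain <- n_concepts - 6L - n_defined
    if (n_plain < 0)
      epokb_stop("n_defined exceeds the available concepts", "epokb_domain_error")
    cat_draw <- sample(cats, n_plain, replace = TRUE,
                       prob = c(0.4, 0.15, 0.15, 0.1, 0.1, 0.1))
    for (j in seq_len(n_plain)) {
      i <- 6L + j
      cat <- cat_draw[j]
      pool <- names(cat_of)[cat_of == cat]
      np <- min(length(pool), 1L + stats::rbinom(1, max_parents - 1L, 0.3))
      parents <- sample(pool, np)
      mk(i, cat)
      for (p in parents) axioms[[length(axioms) + 1L]] <- ax_subclass(cid(i), p)
      anc[[cid(i)]] <- unique(c(cid(i), unlist(anc[parents], use.names = FALSE)))
    }
    # planted restrictions on primitive sign concepts
    props <- c("suggests", "hasLocation", "requiresRoute", "requiresMode",
               "requiresView")
    prop_cat <- c(suggests = "disorder", hasLocation = "anatomy",
                  requiresRoute = "route", requiresMode = "mode",
                  requiresView = "view")
    p_dens <- min(1, restriction_density)
    signs <- setdiff(names(cat_of)[cat_of == "sign"], root_of[["sign"]])
    for (s in signs) {
      nr <- stats::rbinom(1, 3, p_dens)
      for (r in seq_len(nr)) {
        p <- sample(props, 1)
        pool <- names(cat_of)[cat_of == prop_cat[[p]]]
        axioms[[length(axioms) + 1L]] <- ax_restriction(s, p, sample(pool, 1))
      }
    }
    # defined sign classes; genus is the sign root or an earlier defined class
    def_ax <- list()
    for (j in seq_len(n_defined)) {
      i <- 6L + n_plain + j
      mk(i, "sign", "synthetic defined class")
      genus <- root_of[["sign"]]
      if (length(def_ax) && stats::runif(1) < 0.3)
        genus <- def_ax[[sample(length(def_ax), 1)]]$class
      nreq <- sample(1:2, 1)
      reqs <- lapply(seq_len(nreq), function(q) {
        p <- if (stats::runif(1) < 0.2) "requires" else sample(props, 1)
        pool_cat <- if (p == "requires") c("route", "mode", "view")
                    else prop_cat[[p]]
        pool <- names(cat_of)[cat_of %in% pool_cat]
        list(property = p, filler = sample(pool, 1))
      })
      ax <- ax_defined(cid(i), genus, reqs)
      def_ax[[length(def_ax) + 1L]] <- ax
      axioms[[length(axioms) + 1L]] <- ax
      anc[[cid(i)]] <- unique(c(cid(i), anc[[genus]]))
    }
    kb <- epo_kb(concepts, axioms,
                 sign_root = root_of[["sign"]],
                 disorder_root = root_of[["disorder"]],
                 anatomy_root = root_of[["anatomy"]],
                 technical_roots = unname(root_of[c("route", "mode", "view")]),
                 languages = "en")
    ev <- naive_defined_eval(kb, anc)
    if (ev$degenerate) return(NULL)
    list(kb = kb,
         ground_truth = list(ancestors = anc, defined_members = ev$members,
                             closure_ancestors = ev$ancestors))
  }
}

# direct set evaluation of defined-class membership: order-free fixpoint over
# per-concept loops, kept structurally apart from the reasoner's vectorized
# descendant intersection; returns the final ancestor map and, per defined
# class, every concept it newly subsumes
naive_defined_eval <- function(kb, planted_anc) {
  anc <- planted_anc
  restr <- asserted_restrictions(kb)
  defs <- defined_class_axioms(kb)
  def_ids <- vapply(defs, `[[`, character(1), "class")
  if (length(defs)) {
    repeat {
      changed <- FALSE
      for (ax in defs) {
        for (s in names(anc)) {
          if (s == ax$class || ax$class %in% anc[[s]]) next
          if (!(ax$genus %in% anc[[s]])) next
          ok <- TRUE
          for (r in ax$restrictions) {
            sat <- FALSE
            for (i in seq_len(nrow(restr))) {
              if (!(restr$class[i] %in% anc[[s]])) next
              if (!(r$property %in% property_ancestors(kb$properties,
                                                       restr$property[i]))) next
              if (r$filler %in% anc[[restr$filler[i]]]) { sat <- TRUE; break }
            }
            if (!sat) { ok <- FALSE; break }
          }
          if (ok) {
            # s and all its descendants gain the defined class and its
            # ancestors; later sweeps propagate further consequences
            for (t in names(anc)) {
              if (s %in% anc[[t]] && !(ax$class %in% anc[[t]]))
                anc[[t]] <- unique(c(anc[[t]], anc[[ax$class]]))
            }
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  members <- stats::setNames(vector("list", length(def_ids)), def_ids)
  degenerate <- FALSE
  for (d in def_ids) {
    mem <- names(anc)[vapply(names(anc), function(s)
      s != d && (d %in% anc[[s]]) && !(d %in% planted_anc[[s]]), logical(1))]
    if (any(vapply(mem, function(s) s %in% anc[[d]], logical(1))))
      degenerate <- TRUE                 # mutual subsumption (equivalence)
    members[[d]] <- sort_c(mem)
  }
  list(ancestors = anc, members = members, degenerate = degenerate)
}

#' Generate a synthetic annotation session
#'
#' Emulates the panel design of the evaluation: a gold standard drawn per
#' image (each primitive sign present with probability `prevalence`), and
#' independent observers who mark a present sign with probability
#' `sensitivity` and an absent sign with probability `fp_rate`. Errors are
#' independent across observers, images and signs.
#'
#' @param kb Knowledge base providing the sign inventory (primitive sign
#'   concepts, i.e. under the sign root and not defined classes).
#' @param n_images Number of images (grouped five per case, all `common`).
#' @param n_observers Panel size x (>= 2); grades follow the 3/2/1
#'   senior / senior-registrar / registrar pattern, recycled.
#' @param sensitivity,fp_rate,prevalence Probabilities in \[0, 1\].
#' @param seed RNG seed.
#' @return An `epo_session` with a gold standard.
#' @export
generate_session <- function(kb, n_images = 200, n_observers = 6,
                             sensitivity = 0.9, fp_rate = 0.05,
                             prevalence = 0.3, seed = 13) {
  for (p in c(sensitivity, fp_rate, prevalence)) {
    if (is.na(p) || p < 0 || p > 1)
      epokb_stop("probabilities must lie in [0, 1]", "epokb_domain_error")
  }
  if (n_observers < 2)
    epokb_stop("n_observers must be >= 2", "epokb_domain_error")
  cats <- kb_categories(kb)
  defined <- vapply(defined_class_axioms(kb), `[[`, character(1), "class")
  signs <- setdiff(names(cats)[cats == "sign"], c(kb$roots$sign, defined))
  if (!length(signs))
    epokb_stop("kb has no primitive sign concepts", "epokb_domain_error")
  signs <- sort_c(signs)
  with_seed(seed, {
    images <- data.frame(
      image_id = sprintf("img_%04d", seq_len(n_images)),
      case_id = sprintf("case_%03d", ceiling(seq_len(n_images) / 5)),
      cohort = "common", stringsAsFactors = FALSE)
    grades <- rep(c("senior", "senior", "senior", "senior_registrar",
                    "senior_registrar", "registrar"),
                  length.out = n_observers)
    observers <- data.frame(id = sprintf("obs%d", seq_len(n_observers)),
                            grade = grades, stringsAsFactors = FALSE)
    ns <- length(signs)
    present <- matrix(stats::runif(n_images * ns) < prevalence,
                      nrow = n_images)   # images x signs
    gold <- lapply(seq_len(n_images), function(i) signs[present[i, ]])
    names(gold) <- images$image_id
    rows <- vector("list", n_observers)
    for (o in seq_len(n_observers)) {
      pmark <- ifelse(present, sensitivity, fp_rate)
      marked <- matrix(stats::runif(n_images * ns) < pmark, nrow = n_images)
      idx <- which(marked, arr.ind = TRUE)
      rows[[o]] <- data.frame(image_id = images$image_id[idx[, 1]],
                              observer = observers$id[o],
                              concept = signs[idx[, 2]],
                              stringsAsFactors = FALSE)
    }
    epo_session(images = images, observers = observers,
                annotations = do.call(rbind, rows), gold = gold, kb = kb)
  })
}
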