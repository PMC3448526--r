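# Fixture builders and independent brute-force oracles.
# The oracles deliberately share no code with the package internals: path
# enumeration for ancestors, Floyd-Warshall-style matrix closure for merged
# reachability, all-pairs string comparison for lexical matching, exhaustive
# conjunct assignment for EQ subsumption, and Mann-Whitney concordance for
# the AUC.

# -- OBO text builder -------------------------------------------------------

oboTerm <- function(id, name = id, parents = character(0),
                    synonyms = character(0), obsolete = FALSE,
                    eq = NULL) {
  lines <- c("[Term]", paste0("id: ", id), paste0("name: ", name))
  for (s in synonyms) lines <- c(lines, sprintf('synonym: "%s" EXACT []', s))
  if (!is.null(eq)) {
    for (i in seq_len(nrow(eq))) {
      lines <- c(lines,
                 paste0("intersection_of: ", eq$quality[i]),
                 paste0("intersection_of: inheres_in ", eq$entity[i]))
    }
  }
  for (p in parents) lines <- c(lines, paste0("is_a: ", p))
  if (obsolete) lines <- c(lines, "is_obsolete: true")
  c(lines, "")
}

oboDoc <- function(...) paste(c("format-version: 1.2", "", ...), collapse = "\n")

# Quick in-code ontology: edges as a named list id -> parent ids.
makeOntology <- function(edges, prefix = NULL, labels = NULL, synonyms = NULL,
                         obsolete = NULL) {
  ids <- names(edges)
  PhenoOntology(prefix = prefix, ids = ids,
                labels = labels %||% ids,
                synonyms = synonyms,
                parents = unname(edges),
                obsolete = obsolete %||% logical(length(ids)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random DAG over n nodes: edges only from later to earlier ids, so
# acyclicity holds by construction.
randomDag <- function(n, prefix = "X", pEdge = 0.15) {
  ids <- sprintf("%s:%03d", prefix, seq_len(n))
  parents <- lapply(seq_len(n), function(i) {
    if (i == 1L) return(character(0))
    cand <- ids[seq_len(i - 1L)]
    cand[runif(i - 1L) < pEdge]
  })
  names(parents) <- ids
  makeOntology(parents, prefix = prefix)
}

# -- oracle: ancestors by exhaustive path enumeration -----------------------

oracleAncestors <- function(ont, id, includeSelf = FALSE) {
  parents <- ont@parents
  seen <- character(0)
  walk <- function(x) {
    for (p in parents[[x]]) {
      if (!(p %in% seen)) {
        seen <<- c(seen, p)
        walk(p)
      }
    }
  }
  walk(id)
  if (includeSelf) seen <- union(id, seen)
  sort(seen)
}

# -- oracle: reachability closure by boolean matrix powering ----------------

# nodes: character vector; edges: 2-column matrix (from, to).
oracleClosure <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  if (NROW(edges)) {
    A[cbind(match(edges[, 1], nodes), match(edges[, 2], nodes))] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  dimnames(A) <- list(nodes, nodes)
  A
}

# Directed edge list of the merged graph, derived from first principles.
mergedEdges <- function(o1, o2, axioms) {
  edges <- NULL
  for (o in list(o1, o2)) {
    keep <- o@ids[!o@obsolete]
    for (id in keep) {
      for (p in o@parents[[id]]) {
        if (p %in% keep) edges <- rbind(edges, c(id, p))
      }
    }
  }
  if (NROW(axioms)) {
    if (all(c("left", "right") %in% names(axioms))) {
      axioms <- data.frame(sub = axioms$left, kind = "equivalent",
                           super = axioms$right)
    }
    for (i in seq_len(nrow(axioms))) {
      edges <- rbind(edges, c(axioms$sub[i], axioms$super[i]))
      if (axioms$kind[i] == "equivalent") {
        edges <- rbind(edges, c(axioms$super[i], axioms$sub[i]))
      }
    }
  }
  edges
}

# -- oracle: lexical matching by all-pairs comparison -----------------------

oracleSeedPairs <- function(o1, o2) {
  strs <- function(o, id) {
    i <- match(id, o@ids)
    c(normalizeLabel(o@labels[i]),
      if (NROW(o@synonyms[[i]])) normalizeLabel(o@synonyms[[i]]$text))
  }
  out <- NULL
  for (a in o1@ids[!o1@obsolete]) {
    sa <- strs(o1, a)
    for (b in o2@ids[!o2@obsolete]) {
      sb <- strs(o2, b)
      if (length(intersect(sa[nzchar(sa)], sb[nzchar(sb)]))) {
        out <- rbind(out, data.frame(left = a, right = b,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) data.frame(left = character(), right = character()) else out
}

# -- oracle: EQ subsumption by exhaustive conjunct assignment ---------------

oracleEqSubsumes <- function(d1, d2, qualities, entities) {
  all(vapply(seq_len(nrow(d2)), function(j) {
    any(vapply(seq_len(nrow(d1)), function(i) {
      conjunctSubsumes(d1[i, ], d2[j, ], qualities, entities)
    }, TRUE))
  }, TRUE))
}

oracleFormalAxioms <- function(defs1, defs2, qualities, entities) {
  out <- NULL
  for (a in names(defs1@definitions)) {
    for (b in names(defs2@definitions)) {
      s12 <- oracleEqSubsumes(defs1@definitions[[a]], defs2@definitions[[b]],
                              qualities, entities)
      s21 <- oracleEqSubsumes(defs2@definitions[[b]], defs1@definitions[[a]],
                              qualities, entities)
      if (s12 && s21) {
        out <- rbind(out, data.frame(sub = a, kind = "equivalent", super = b))
      } else if (s12) {
        out <- rbind(out, data.frame(sub = a, kind = "subclass", super = b))
      } else if (s21) {
        out <- rbind(out, data.frame(sub = b, kind = "subclass", super = a))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(sub = character(), kind = character(), super = character())
  }
  out <- out[order(out$sub, out$super), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- oracle: AUC as Mann-Whitney concordance --------------------------------

oracleAuc <- function(scores, labels) {
  sp <- scores[labels]
  sn <- scores[!labels]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# -- tiny support-ontology pair used across formal-alignment tests ----------
#
#   entities:  ENT:organ <- ENT:heart <- ENT:left-ventricle
#                        \_ ENT:ear
#   qualities: QUA:quality <- QUA:size <- QUA:increased-size
#                          \_ QUA:color

toySupports <- function() {
  list(
    entities = makeOntology(list(
      "ENT:organ" = character(0),
      "ENT:heart" = "ENT:organ",
      "ENT:left-ventricle" = "ENT:heart",
      "ENT:ear" = "ENT:organ"
    )),
    qualities = makeOntology(list(
      "QUA:quality" = character(0),
      "QUA:size" = "QUA:quality",
      "QUA:increased-size" = "QUA:size",
      "QUA:color" = "QUA:quality"
    ))
  )
}

eqdef <- function(quality, entity) {
  data.frame(quality = quality, entity = entity, stringsAsFactors = FALSE)
}

# Random single/multi-conjunct definition sets over the toy supports.
randomDefs <- function(nDefs, prefix, supports, maxConjuncts = 2) {
  ents <- supports$entities@ids
  quas <- supports$qualities@ids
  defs <- lapply(seq_len(nDefs), function(i) {
    k <- sample.int(maxConjuncts, 1)
    unique(data.frame(quality = sample(quas, k, replace = TRUE),
                      entity = sample(ents, k, replace = TRUE),
                      stringsAsFactors = FALSE))
  })
  names(defs) <- sprintf("%s:%04d", prefix, seq_len(nDefs))
  EQDefinitionSet(defs, conceptPrefix = prefix)
}
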