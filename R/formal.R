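# Structural EQ subsumption over shared support ontologies.
#
# A phenotype definition is a conjunction of (quality, entity) pairs. A
# conjunct (q1, e1) is subsumed by (q2, e2) iff q2 is an ancestor-or-self of
# q1 and e2 an ancestor-or-self of e1 in the support ontologies; a definition
# d1 is subsumed by d2 iff every conjunct of d2 generalizes some conjunct of
# d1. This decision procedure is sound and complete for the flat
# conjunction-of-pairs fragment used here; EQ modifiers, relational
# qualities and nested entity expressions are out of scope.

.asConjunct <- function(cj) {
  cj <- as.list(cj)
  if (is.null(cj$quality) || is.null(cj$entity)) {
    stop("a conjunct must have 'quality' and 'entity' components")
  }
  cj
}

#' Structural subsumption between two EQ conjuncts
#'
#' `TRUE` iff `c2` generalizes (or equals) `c1`: `c2$quality` is an
#' ancestor-or-self of `c1$quality` in the quality support ontology and
#' `c2$entity` an ancestor-or-self of `c1$entity` in the entity support
#' ontology.
#'
#' @param c1,c2 Conjuncts: lists or named vectors with `quality` and `entity`.
#' @param qualities,entities Support [PhenoOntology-class] objects.
#' @return Logical scalar.
#' @export
conjunctSubsumes <- function(c1, c2, qualities, entities) {
  c1 <- .asConjunct(c1); c2 <- .asConjunct(c2)
  for (q in c(c1$quality, c2$quality)) {
    if (!q %in% qualities@ids) stop("unknown quality concept: ", q)
  }
  for (e in c(c1$entity, c2$entity)) {
    if (!e %in% entities@ids) stop("unknown entity concept: ", e)
  }
  c2$quality %in% conceptAncestors(qualities, c1$quality, includeSelf = TRUE) &&
    c2$entity %in% conceptAncestors(entities, c1$entity, includeSelf = TRUE)
}

# Shared inner loop with precomputed ancestor-or-self indexes.
.eqSubsumesIdx <- function(d1, d2, qAnc, eAnc) {
  for (j in seq_len(nrow(d2))) {
    hit <- FALSE
    for (i in seq_len(nrow(d1))) {
      if (d2$quality[j] %in% qAnc[[d1$quality[i]]] &&
          d2$entity[j] %in% eAnc[[d1$entity[i]]]) {
        hit <- TRUE
        break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Structural subsumption between two EQ definitions
#'
#' `TRUE` iff `d2` subsumes `d1`: every conjunct of `d2` generalizes some
#' conjunct of `d1` (standard structural subsumption for conjunctions).
#' Reflexive and transitive.
#'
#' @param d1,d2 Data frames with columns `quality`, `entity` (one conjunct
#'   per row).
#' @param qualities,entities Support [PhenoOntology-class] objects.
#' @return Logical scalar.
#' @export
eqSubsumes <- function(d1, d2, qualities, entities) {
  stopifnot(nrow(d1) >= 1, nrow(d2) >= 1)
  badQ <- setdiff(unique(c(d1$quality, d2$quality)), qualities@ids)
  badE <- setdiff(unique(c(d1$entity, d2$entity)), entities@ids)
  if (length(badQ) || length(badE)) {
    stop("unknown support concept(s): ", paste(c(badQ, badE), collapse = ", "))
  }
  qAnc <- .ancestorIndex(qualities, includeSelf = TRUE)
  eAnc <- .ancestorIndex(entities, includeSelf = TRUE)
  .eqSubsumesIdx(d1, d2, qAnc, eAnc)
}

.emptyAxioms <- function() {
  data.frame(sub = character(), kind = character(), super = character(),
             stringsAsFactors = FALSE)
}

#' Cross-ontology mapping axioms from EQ definitions
#'
#' For every pair of defined concepts `(a, b)` with `a` from `defs1` and `b`
#' from `defs2`, emits `a SubClassOf b` iff `b`'s definition subsumes `a`'s,
#' `b SubClassOf a` iff the converse, and a single `equivalent` axiom
#' (oriented `defs1`-first) iff both hold. The result is exactly the union
#' over all pairs and both directions.
#'
#' @param defs1,defs2 [EQDefinitionSet-class] objects with distinct concept
#'   prefixes.
#' @param qualities,entities Support [PhenoOntology-class] objects.
#' @return Data frame with columns `sub`, `kind` (`"subclass"` or
#'   `"equivalent"`), `super`.
#' @export
formalAxioms <- function(defs1, defs2, qualities, entities) {
  stopifnot(is(defs1, "EQDefinitionSet"), is(defs2, "EQDefinitionSet"))
  if (length(defs1@definitions) == 0L || length(defs2@definitions) == 0L) {
    return(.emptyAxioms())
  }
  if (identical(defs1@conceptPrefix, defs2@conceptPrefix)) {
    stop("definition sets must reference distinct concept prefixes")
  }
  d1 <- defs1@definitions; d2 <- defs2@definitions
  allQ <- unique(unlist(lapply(c(d1, d2), `[[`, "quality")))
  allE <- unique(unlist(lapply(c(d1, d2), `[[`, "entity")))
  badQ <- setdiff(allQ, qualities@ids); badE <- setdiff(allE, entities@ids)
  if (length(badQ) || length(badE)) {
    stop("unknown support concept(s): ", paste(c(badQ, badE), collapse = ", "))
  }
  qAnc <- .ancestorIndex(qualities, includeSelf = TRUE)
  eAnc <- .ancestorIndex(entities, includeSelf = TRUE)

  allSingle <- all(vapply(d1, nrow, 0L) == 1L) && all(vapply(d2, nrow, 0L) == 1L)
  if (allSingle) {
    # fast path: a <= b iff b's (q, e) lies in ancSelf(a.q) x ancSelf(a.e)
    key <- function(q, e) paste(q, e, sep = "\r")
    subsumersOf <- function(defs) {
      lapply(defs, function(d) {
        as.vector(outer(qAnc[[d$quality]], eAnc[[d$entity]], key))
      })
    }
    keyOf <- function(defs) vapply(defs, function(d) key(d$quality, d$entity), "")
    k1 <- keyOf(d1); k2 <- keyOf(d2)
    lookup2 <- split(names(d2), k2)
    lookup1 <- split(names(d1), k1)
    f12 <- lapply(subsumersOf(d1), function(ks)
      sort(unique(unlist(lookup2[intersect(ks, names(lookup2))], use.names = FALSE))))
    f21 <- lapply(subsumersOf(d2), function(ks)
      sort(unique(unlist(lookup1[intersect(ks, names(lookup1))], use.names = FALSE))))
    pair12 <- data.frame(
      a = rep(names(f12), lengths(f12)),
      b = unlist(f12, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    pair21 <- data.frame(
      a = unlist(f21, use.names = FALSE),
      b = rep(names(f21), lengths(f21)),
      stringsAsFactors = FALSE
    )
  } else {
    ids1 <- names(d1); ids2 <- names(d2)
    a12 <- list(); a21 <- list()
    for (a in ids1) for (b in ids2) {
      if (.eqSubsumesIdx(d1[[a]], d2[[b]], qAnc, eAnc)) {
        a12[[length(a12) + 1L]] <- c(a, b)
      }
      if (.eqSubsumesIdx(d2[[b]], d1[[a]], qAnc, eAnc)) {
        a21[[length(a21) + 1L]] <- c(a, b)
      }
    }
    toDf <- function(l) {
      if (!length(l)) return(data.frame(a = character(), b = character(),
                                        stringsAsFactors = FALSE))
      m <- do.call(rbind, l)
      data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
    }
    pair12 <- toDf(a12); pair21 <- toDf(a21)
  }
  k12 <- paste(pair12$a, pair12$b)
  k21 <- paste(pair21$a, pair21$b)
  eq <- intersect(k12, k21)
  out <- rbind(
    if (length(eq)) {
      p <- pair12[match(eq, k12), , drop = FALSE]
      data.frame(sub = p$a, kind = "equivalent", super = p$b, stringsAsFactors = FALSE)
    } else .emptyAxioms(),
    {
      p <- pair12[!(k12 %in% eq), , drop = FALSE]
      data.frame(sub = p$a, kind = rep("subclass", nrow(p)), super = p$b,
                 stringsAsFactors = FALSE)
    },
    {
      p <- pair21[!(k21 %in% eq), , drop = FALSE]
      data.frame(sub = p$b, kind = rep("subclass", nrow(p)), super = p$a,
                 stringsAsFactors = FALSE)
    }
  )
  out <- out[order(out$sub, out$super), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpret lexical seed pairs as equivalence axioms
#'
#' @param seeds Data frame from [lexicalSeedPairs()] (columns `left`, `right`).
#' @return Axiom data frame (`sub`, `kind`, `super`) with kind `"equivalent"`.
#' @export
seedsAsAxioms <- function(seeds) {
  if (!NROW(seeds)) return(.emptyAxioms())
  data.frame(sub = seeds$left, kind = "equivalent", super = seeds$right,
             stringsAsFactors = FALSE)
}

#' Read / write mapping axioms
#'
#' TSV format `sub_id<TAB>kind<TAB>super_id` with kind in
#' `{subclass, equivalent}`.
#'
#' @param x File path, single string, or character vector of lines.
#' @return Axiom data frame (`sub`, `kind`, `super`).
#' @export
readAxioms <- function(x) {
  lines <- .oboLines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.emptyAxioms())
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(toks) != 3L)
  if (length(bad)) stop(sprintf("line %d: expected 3 tab-separated fields", bad[1]))
  out <- data.frame(
    sub = vapply(toks, `[`, "", 1L),
    kind = vapply(toks, `[`, "", 2L),
    super = vapply(toks, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  badKind <- setdiff(unique(out$kind), c("subclass", "equivalent"))
  if (length(badKind)) stop("unknown axiom kind(s): ", paste(badKind, collapse = ", "))
  out
}

#' @rdname readAxioms
#' @param axioms Axiom data frame.
#' @param file Output path.
#' @export
writeAxioms <- function(axioms, file) {
  write.table(axioms[c("sub", "kind", "super")], file,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
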