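# Merged-taxonomy closure and mapping construction.
#
# Both ontologies are imported into one directed graph: child -> parent for
# every is_a edge, sub -> super for every subclass axiom, and both directions
# for every equivalence (including lexical seed pairs). The mapping for a
# source concept is everything reachable from it that belongs to the target
# ontology — its "equivalent and super concepts" across the bridge.

#' MergedClosure: reachability oracle over two merged ontologies
#'
#' @slot graph The merged directed igraph.
#' @slot ids All (non-obsolete) concept ids in the graph.
#' @exportClass MergedClosure
setClass("MergedClosure", slots = c(graph = "ANY", ids = "character"))

setMethod("show", "MergedClosure", function(object) {
  cat(sprintf("MergedClosure: %d concepts, %d directed edges\n",
              length(object@ids), igraph::ecount(object@graph)))
})

.normalizeAxioms <- function(axioms) {
  if (!NROW(axioms)) return(.emptyAxioms())
  if (all(c("left", "right") %in% names(axioms))) return(seedsAsAxioms(axioms))
  stopifnot(all(c("sub", "kind", "super") %in% names(axioms)))
  axioms
}

#' Merge two ontologies with bridging axioms and close reachability
#'
#' Builds the merged directed graph over the non-obsolete concepts of both
#' ontologies: is_a edges (child to parent), subclass axioms (sub to super)
#' and equivalence axioms (both directions). Lexical seed-pair data frames
#' are accepted directly and treated as equivalence axioms.
#'
#' @param o1,o2 [PhenoOntology-class] objects with distinct prefixes.
#' @param axioms Axiom data frame (`sub`, `kind`, `super`) or seed-pair data
#'   frame (`left`, `right`, ...). Endpoints must be non-obsolete concepts of
#'   `o1` or `o2`.
#' @return A [MergedClosure-class] reachability oracle.
#' @seealso [reachableFrom()], [buildMapping()]
#' @export
mergeAndClose <- function(o1, o2, axioms = NULL) {
  stopifnot(is(o1, "PhenoOntology"), is(o2, "PhenoOntology"))
  axioms <- .normalizeAxioms(axioms)
  ids <- c(o1@ids[!o1@obsolete], o2@ids[!o2@obsolete])
  edge <- function(o) {
    keep <- o@ids[!o@obsolete]
    from <- rep(keep, lengths(o@parents[keep]))
    to <- unlist(o@parents[keep], use.names = FALSE)
    ok <- to %in% ids
    cbind(from[ok], to[ok])
  }
  dangling <- setdiff(unique(c(axioms$sub, axioms$super)), ids)
  if (length(dangling)) {
    stop("axiom references unknown or obsolete concept(s): ",
         paste(dangling, collapse = ", "))
  }
  eq <- axioms$kind == "equivalent"
  edges <- rbind(
    edge(o1), edge(o2),
    cbind(axioms$sub, axioms$super),
    cbind(axioms$super[eq], axioms$sub[eq])
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  new("MergedClosure", graph = g, ids = ids)
}

#' Concepts reachable from a concept in a merged closure
#'
#' Reflexive-transitive reachability over the merged graph's directed edges;
#' always includes the concept itself.
#'
#' @param closure A [MergedClosure-class].
#' @param id A concept id in the closure.
#' @return Character vector of reachable concept ids.
#' @export
reachableFrom <- function(closure, id) {
  stopifnot(is(closure, "MergedClosure"))
  if (!id %in% closure@ids) stop("unknown concept: ", id)
  names(igraph::subcomponent(closure@graph, id, mode = "out"))
}

#' Build a direction-specific concept mapping
#'
#' For every non-obsolete source concept with a non-empty result, the entry
#' is the set of target-ontology concepts reachable from it in the merged
#' closure — its equivalent and super concepts across the bridge. Concepts
#' with an empty intersection are omitted ("not mapped"). Root concepts of
#' the target ontology are retained in entry sets by default; `dropRoots`
#' removes them.
#'
#' @param o1,o2 [PhenoOntology-class] objects.
#' @param axioms Bridging axioms or seed pairs (see [mergeAndClose()]).
#' @param direction `"1to2"` (map `o1` concepts into `o2`) or `"2to1"`.
#' @param method `"lexical"` or `"formal"` (recorded on the mapping).
#' @param dropRoots Drop target-ontology root concepts from entry sets.
#' @param closure Optional precomputed [MergedClosure-class] for these
#'   inputs (saves rebuilding the graph when both directions are needed).
#' @return A [PhenoMapping-class].
#' @export
buildMapping <- function(o1, o2, axioms = NULL, direction = c("1to2", "2to1"),
                         method = c("lexical", "formal"), dropRoots = FALSE,
                         closure = NULL) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  mc <- closure %||% mergeAndClose(o1, o2, axioms)
  if (direction == "1to2") { src <- o1; tgt <- o2 } else { src <- o2; tgt <- o1 }
  srcIds <- src@ids[!src@obsolete]
  tgtIds <- tgt@ids[!tgt@obsolete]
  if (dropRoots) tgtIds <- setdiff(tgtIds, ontologyRoots(tgt))
  entries <- list()
  if (length(srcIds) && length(tgtIds)) {
    d <- igraph::distances(mc@graph, v = srcIds, to = tgtIds, mode = "out")
    for (i in seq_along(srcIds)) {
      hits <- tgtIds[is.finite(d[i, ])]
      if (length(hits)) entries[[srcIds[i]]] <- sort(hits)
    }
  }
  PhenoMapping(sourcePrefix = src@prefix, targetPrefix = tgt@prefix,
               method = method, entries = entries)
}

#' Read / write concept mappings
#'
#' One record per source concept: whitespace-separated ids, source first,
#' targets in lexicographic order — e.g.
#' `HP:0007062 MP:0000001 MP:0002106 MP:0004142 MP:0004143 MP:0005369`.
#' Writing then re-reading is the identity on entries (targets are
#' canonicalized to sorted order).
#'
#' @param x File path, single string, or character vector of lines.
#' @param method Mapping method to record (`"lexical"` or `"formal"`).
#' @param sourcePrefix,targetPrefix Prefixes; inferred from the records when
#'   omitted (required for an empty document).
#' @return A [PhenoMapping-class].
#' @export
readMapping <- function(x, method = c("lexical", "formal"),
                        sourcePrefix = NULL, targetPrefix = NULL) {
  method <- match.arg(method)
  lines <- .oboLines(x)
  lines <- lines[nzchar(trimws(lines))]
  entries <- list()
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(toks) < 2L) {
      stop(sprintf("line %d: expected a source id and at least one target id", i))
    }
    entries[[toks[1]]] <- sort(unique(c(entries[[toks[1]]], toks[-1])))
  }
  if (is.null(sourcePrefix)) {
    if (!length(entries)) stop("cannot infer prefixes from an empty mapping document")
    sourcePrefix <- idPrefix(names(entries)[1])
  }
  if (is.null(targetPrefix)) {
    if (!length(entries)) stop("cannot infer prefixes from an empty mapping document")
    targetPrefix <- idPrefix(entries[[1]][1])
  }
  PhenoMapping(sourcePrefix, targetPrefix, method, entries)
}

#' @rdname readMapping
#' @param mapping A [PhenoMapping-class].
#' @param file Optional output path; when `NULL` the lines are returned
#'   invisibly.
#' @export
writeMapping <- function(mapping, file = NULL) {
  stopifnot(is(mapping, "PhenoMapping"))
  keys <- sort(names(mapping@entries))
  out <- vapply(keys, function(k) {
    paste(c(k, sort(mapping@entries[[k]])), collapse = " ")
  }, "")
  if (!is.null(file)) writeLines(out, file)
  invisible(unname(out))
}
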