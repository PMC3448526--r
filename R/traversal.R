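# is_a traversal: reflexive/strict transitive ancestor closure.

#' Ancestors of a concept over is_a
#'
#' Transitive closure of the `is_a` relation within one ontology: the strict
#' closure by default, the reflexive-transitive closure with
#' `includeSelf = TRUE`. Only `is_a` edges are traversed.
#'
#' @param ontology A [PhenoOntology-class].
#' @param id A concept id present in the ontology.
#' @param includeSelf Include the concept itself?
#' @return Character vector of ancestor concept ids (unordered set).
#' @examples
#' o <- parseOBO(c("[Term]", "id: X:2", "name: b", "is_a: X:1", "",
#'                 "[Term]", "id: X:1", "name: a"))
#' conceptAncestors(o, "X:2")
#' @export
conceptAncestors <- function(ontology, id, includeSelf = FALSE) {
  stopifnot(is(ontology, "PhenoOntology"))
  if (!id %in% ontology@ids) stop("unknown concept: ", id)
  res <- character(0)
  frontier <- ontology@parents[[id]]
  while (length(frontier)) {
    new <- setdiff(frontier, res)
    res <- c(res, new)
    frontier <- unique(unlist(ontology@parents[new], use.names = FALSE))
  }
  if (includeSelf) res <- union(id, res)
  res
}

# Ancestor sets for every concept at once (memoised bottom-up), used by the
# structural subsumption and generator code paths.
.ancestorIndex <- function(ontology, includeSelf = FALSE) {
  ids <- ontology@ids
  parents <- ontology@parents
  anc <- vector("list", length(ids))
  names(anc) <- ids
  done <- setNames(logical(length(ids)), ids)
  for (start in ids) {
    if (done[[start]]) next
    # iterative post-order to avoid deep recursion
    stack <- start
    while (length(stack)) {
      id <- stack[length(stack)]
      ps <- parents[[id]]
      todo <- ps[!done[ps]]
      if (length(todo)) {
        stack <- c(stack, todo[1])
      } else {
        anc[[id]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
        done[[id]] <- TRUE
        stack <- stack[-length(stack)]
      }
    }
  }
  if (includeSelf) anc <- mapply(function(a, s) c(s, a), anc, ids, SIMPLIFY = FALSE)
  anc
}

#' Root concepts of an ontology
#'
#' Non-obsolete concepts with no `is_a` parents.
#'
#' @param ontology A [PhenoOntology-class].
#' @return Character vector of root concept ids.
#' @export
ontologyRoots <- function(ontology) {
  stopifnot(is(ontology, "PhenoOntology"))
  ontology@ids[lengths(ontology@parents) == 0 & !ontology@obsolete]
}
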