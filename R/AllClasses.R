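# S4 containers for ontologies, EQ definition sets and concept mappings.

.findCycle <- function(ids, parents) {
  # DFS with colouring; returns NULL or one cycle as a character vector.
  color <- setNames(integer(length(ids)), ids)  # 0 white, 1 grey, 2 black
  stack <- character(0)
  cycle <- NULL
  visit <- function(id) {
    if (!is.null(cycle)) return(invisible())
    color[[id]] <<- 1L
    stack <<- c(stack, id)
    for (p in parents[[id]]) {
      if (is.null(cycle) && !is.na(color[p])) {
        if (color[[p]] == 1L) {
          i <- match(p, stack)
          cycle <<- c(stack[i:length(stack)], p)
        } else if (color[[p]] == 0L) {
          visit(p)
        }
      }
    }
    color[[id]] <<- 2L
    stack <<- stack[-length(stack)]
    invisible()
  }
  for (id in ids) if (color[[id]] == 0L) visit(id)
  cycle
}

#' PhenoOntology: a DAG of phenotype (or support) concepts
#'
#' Holds a single ontology: concept identifiers, primary labels, synonyms
#' (with their scope), `is_a` parents and obsolescence flags. The `is_a`
#' graph restricted to the ontology's own concepts must be acyclic; obsolete
#' concepts carry no parents and are excluded from matching, mapping and
#' annotation translation.
#'
#' @slot prefix Identifier prefix shared by the concepts (e.g. `"HP"`).
#' @slot name Human-readable ontology name.
#' @slot ids Character vector of concept identifiers.
#' @slot labels Character vector of primary names, parallel to `ids`.
#' @slot synonyms List (named by id) of data frames with columns `text`, `scope`.
#' @slot parents List (named by id) of character vectors of `is_a` parent ids.
#' @slot obsolete Logical vector parallel to `ids`.
#' @exportClass PhenoOntology
setClass("PhenoOntology",
  slots = c(
    prefix = "character", name = "character",
    ids = "character", labels = "character",
    synonyms = "list", parents = "list", obsolete = "logical"
  )
)

setValidity("PhenoOntology", function(object) {
  n <- length(object@ids)
  if (length(object@labels) != n || length(object@synonyms) != n ||
      length(object@parents) != n || length(object@obsolete) != n) {
    return("ids, labels, synonyms, parents and obsolete must have equal length")
  }
  if (anyDuplicated(object@ids)) return("duplicate concept ids")
  own <- object@parents
  bad <- unlist(lapply(seq_len(n), function(i) {
    p <- own[[i]]
    p[idPrefix(p) == object@prefix & !(p %in% object@ids)]
  }))
  if (length(bad)) {
    return(paste0("unresolved same-prefix parent id(s): ",
                  paste(unique(bad), collapse = ", ")))
  }
  if (any(object@obsolete & lengths(object@parents) > 0)) {
    return("obsolete concepts must not carry is_a parents")
  }
  inOnt <- lapply(own, function(p) p[p %in% object@ids])
  names(inOnt) <- object@ids
  cyc <- .findCycle(object@ids, inOnt)
  if (!is.null(cyc)) {
    return(paste0("is_a cycle detected: ", paste(cyc, collapse = " -> ")))
  }
  TRUE
})

#' Construct a PhenoOntology
#'
#' @param prefix Identifier prefix (e.g. `"HP"`); inferred from `ids` when missing.
#' @param ids Concept identifiers of the form `PREFIX:local`.
#' @param labels Primary concept names (defaults to the ids).
#' @param synonyms List of per-concept synonym tables (`text`, `scope`), or a
#'   list of character vectors (scope then defaults to `""`).
#' @param parents List of per-concept character vectors of `is_a` parent ids.
#' @param obsolete Logical vector; obsolete concepts have their parents dropped.
#' @param name Ontology name.
#' @return A validated [PhenoOntology-class] object.
#' @export
PhenoOntology <- function(prefix = NULL, ids = character(), labels = ids,
                          synonyms = NULL, parents = NULL,
                          obsolete = logical(length(ids)), name = NULL) {
  .checkConceptIDs(ids)
  if (is.null(prefix)) {
    prefix <- if (length(ids)) names(sort(table(idPrefix(ids)), decreasing = TRUE))[1]
              else NA_character_
  }
  emptySyn <- data.frame(text = character(), scope = character(),
                         stringsAsFactors = FALSE)
  if (is.null(synonyms)) synonyms <- rep(list(emptySyn), length(ids))
  synonyms <- lapply(synonyms, function(s) {
    if (is.character(s)) {
      data.frame(text = s, scope = rep("", length(s)), stringsAsFactors = FALSE)
    } else if (is.null(s)) emptySyn else s
  })
  if (is.null(parents)) parents <- rep(list(character(0)), length(ids))
  parents <- lapply(parents, function(p) unique(as.character(p)))
  parents[obsolete] <- list(character(0))
  names(synonyms) <- ids
  names(parents) <- ids
  new("PhenoOntology",
      prefix = prefix, name = as.character(name %||% prefix),
      ids = ids, labels = as.character(labels),
      synonyms = synonyms, parents = parents,
      obsolete = as.logical(obsolete))
}

#' EQDefinitionSet: entity-quality logical definitions for phenotype concepts
#'
#' Each definition grounds one phenotype concept as a conjunction of
#' (quality, entity) pairs drawn from two shared support ontologies (the
#' PATO and cross-species-anatomy roles). Concepts without a definition are
#' simply absent from the set.
#'
#' @slot conceptPrefix Prefix of the defined phenotype concepts.
#' @slot definitions List, named by concept id, of data frames with columns
#'   `quality` and `entity` (one row per conjunct, no duplicate rows).
#' @exportClass EQDefinitionSet
setClass("EQDefinitionSet",
  slots = c(conceptPrefix = "character", definitions = "list")
)

setValidity("EQDefinitionSet", function(object) {
  defs <- object@definitions
  if (length(defs) && is.null(names(defs))) return("definitions must be named by concept id")
  for (id in names(defs)) {
    d <- defs[[id]]
    if (!is.data.frame(d) || !all(c("quality", "entity") %in% names(d))) {
      return(paste0(id, ": definition must be a data frame with quality and entity"))
    }
    if (nrow(d) < 1) return(paste0(id, ": definition must have at least one conjunct"))
    if (anyDuplicated(paste(d$quality, d$entity))) {
      return(paste0(id, ": duplicate (quality, entity) conjunct"))
    }
  }
  TRUE
})

#' Construct an EQDefinitionSet
#'
#' @param definitions Named list of data frames (`quality`, `entity`).
#' @param conceptPrefix Prefix of the defined concepts; inferred when missing.
#' @return A validated [EQDefinitionSet-class] object.
#' @export
EQDefinitionSet <- function(definitions = list(), conceptPrefix = NULL) {
  if (is.null(conceptPrefix)) {
    conceptPrefix <- if (length(definitions)) idPrefix(names(definitions)[1])
                     else NA_character_
  }
  new("EQDefinitionSet", conceptPrefix = conceptPrefix, definitions = definitions)
}

#' PhenoMapping: direction-specific concept mapping between two ontologies
#'
#' For each mapped source concept, the set of equivalent-or-super concepts in
#' the target ontology, as produced by taxonomic closure over a merged graph.
#' Concepts with no mapped targets are absent from `entries` ("not mapped").
#' Mappings are direction-specific and need not be symmetric.
#'
#' @slot sourcePrefix Prefix of the source ontology.
#' @slot targetPrefix Prefix of the target ontology.
#' @slot method Either `"lexical"` or `"formal"`.
#' @slot entries List, named by source concept id, of non-empty sorted
#'   character vectors of target concept ids.
#' @exportClass PhenoMapping
setClass("PhenoMapping",
  slots = c(sourcePrefix = "character", targetPrefix = "character",
            method = "character", entries = "list")
)

setValidity("PhenoMapping", function(object) {
  if (!object@method %in% c("lexical", "formal")) {
    return("method must be 'lexical' or 'formal'")
  }
  e <- object@entries
  if (length(e)) {
    if (is.null(names(e))) return("entries must be named by source concept id")
    if (any(idPrefix(names(e)) != object@sourcePrefix)) {
      return("entry keys must carry the source prefix")
    }
    if (any(lengths(e) == 0)) return("empty entry sets are not allowed")
    tp <- unique(idPrefix(unlist(e, use.names = FALSE)))
    if (length(tp) && any(tp != object@targetPrefix)) {
      return("entry values must carry the target prefix")
    }
  }
  TRUE
})

#' Construct a PhenoMapping
#'
#' @param sourcePrefix,targetPrefix Identifier prefixes of the two ontologies.
#' @param method `"lexical"` or `"formal"`.
#' @param entries Named list of character vectors of target concept ids.
#' @return A validated [PhenoMapping-class] object.
#' @export
PhenoMapping <- function(sourcePrefix, targetPrefix, method, entries = list()) {
  entries <- lapply(entries, function(v) sort(unique(as.character(v))))
  new("PhenoMapping", sourcePrefix = sourcePrefix, targetPrefix = targetPrefix,
      method = method, entries = entries)
}
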