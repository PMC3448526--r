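# Accessor generics and show methods.

#' @rdname PhenoOntology-class
#' @param x,object A `PhenoOntology`.
#' @export
setGeneric("conceptIDs", function(x) standardGeneric("conceptIDs"))

#' @rdname PhenoOntology-class
#' @export
setGeneric("conceptLabels", function(x) standardGeneric("conceptLabels"))

#' @rdname PhenoOntology-class
#' @export
setGeneric("ontologyPrefix", function(x) standardGeneric("ontologyPrefix"))

#' @rdname PhenoOntology-class
#' @export
setGeneric("isObsolete", function(x) standardGeneric("isObsolete"))

#' @rdname PhenoOntology-class
#' @export
setGeneric("nConcepts", function(x) standardGeneric("nConcepts"))

#' @rdname PhenoOntology-class
#' @export
setMethod("conceptIDs", "PhenoOntology", function(x) x@ids)

#' @rdname PhenoOntology-class
#' @export
setMethod("conceptLabels", "PhenoOntology",
          function(x) setNames(x@labels, x@ids))

#' @rdname PhenoOntology-class
#' @export
setMethod("ontologyPrefix", "PhenoOntology", function(x) x@prefix)

#' @rdname PhenoOntology-class
#' @export
setMethod("isObsolete", "PhenoOntology", function(x) setNames(x@obsolete, x@ids))

#' @rdname PhenoOntology-class
#' @export
setMethod("nConcepts", "PhenoOntology", function(x) length(x@ids))

#' @rdname PhenoOntology-class
#' @param id A concept id in `x`.
#' @export
conceptParents <- function(x, id) {
  stopifnot(is(x, "PhenoOntology"))
  if (!id %in% x@ids) stop("unknown concept: ", id)
  x@parents[[id]]
}

#' @rdname PhenoOntology-class
#' @export
conceptSynonyms <- function(x, id) {
  stopifnot(is(x, "PhenoOntology"))
  if (!id %in% x@ids) stop("unknown concept: ", id)
  x@synonyms[[id]]
}

setMethod("show", "PhenoOntology", function(object) {
  nEdge <- sum(lengths(object@parents))
  cat(sprintf("PhenoOntology '%s' (%s): %d concepts (%d obsolete), %d is_a edges\n",
              object@prefix, object@name, length(object@ids),
              sum(object@obsolete), nEdge))
})

#' @rdname EQDefinitionSet-class
#' @param x,object An `EQDefinitionSet`.
#' @export
definedConcepts <- function(x) {
  stopifnot(is(x, "EQDefinitionSet"))
  names(x@definitions)
}

#' @rdname EQDefinitionSet-class
#' @param id A defined concept id.
#' @export
getDefinition <- function(x, id) {
  stopifnot(is(x, "EQDefinitionSet"))
  d <- x@definitions[[id]]
  if (is.null(d)) stop("no formal definition for concept: ", id)
  d
}

setMethod("length", "EQDefinitionSet", function(x) length(x@definitions))

setMethod("show", "EQDefinitionSet", function(object) {
  cat(sprintf("EQDefinitionSet: %d %s concepts with formal definitions\n",
              length(object@definitions), object@conceptPrefix))
})

#' @rdname PhenoMapping-class
#' @param x,object A `PhenoMapping`.
#' @export
mappingEntries <- function(x) {
  stopifnot(is(x, "PhenoMapping"))
  x@entries
}

#' @rdname PhenoMapping-class
#' @export
mappedConcepts <- function(x) {
  stopifnot(is(x, "PhenoMapping"))
  names(x@entries)
}

#' @rdname PhenoMapping-class
#' @export
mappingMethod <- function(x) {
  stopifnot(is(x, "PhenoMapping"))
  x@method
}

#' @rdname PhenoMapping-class
#' @export
mappingDirection <- function(x) {
  stopifnot(is(x, "PhenoMapping"))
  paste0(x@sourcePrefix, "->", x@targetPrefix)
}

setMethod("length", "PhenoMapping", function(x) length(x@entries))

setMethod("show", "PhenoMapping", function(object) {
  sizes <- lengths(object@entries)
  cat(sprintf("PhenoMapping %s -> %s (%s): %d mapped concepts, mean set size %.2f\n",
              object@sourcePrefix, object@targetPrefix, object@method,
              length(sizes), if (length(sizes)) mean(sizes) else NA_real_))
})
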