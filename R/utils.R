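#' @importFrom methods new validObject setClass setGeneric setMethod show is slot
#' @importFrom stats setNames runif
#' @importFrom utils head tail read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the prefix of an ontology concept identifier
#'
#' Concept identifiers have the form `PREFIX:local` (e.g. `"HP:0000365"`).
#' The prefix is everything before the first colon; comparison of identifiers
#' is case-sensitive throughout the package.
#'
#' @param x Character vector of concept identifiers.
#' @return Character vector of prefixes.
#' @examples
#' idPrefix(c("HP:0000365", "MP:0006325"))
#' @export
idPrefix <- function(x) sub(":.*$", "", x)

.checkConceptIDs <- function(x) {
  bad <- x[!grepl("^[^:[:space:]]+:[^:[:space:]]+$", x)]
  if (length(bad)) {
    stop("malformed concept identifier(s): ", paste(unique(bad), collapse = ", "))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Presentation rounding used for coverage percentages and mean mapped-set
#' sizes: ties round up (0.125 -> 0.13 at 2 digits), unlike base R's
#' round-half-even.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Coverage percentage of mapped concepts
#'
#' `100 * mapped / total`, rounded half-up to two decimals — the convention
#' used in the mapping-content summary table.
#'
#' @param mapped Number of mapped (or defined) concepts.
#' @param total Total number of concepts in the ontology.
#' @return Percentage on the 0-100 scale, two decimals.
#' @examples
#' coveragePct(2740, 10104)
#' @export
coveragePct <- function(mapped, total) {
  stopifnot(total > 0, mapped >= 0)
  roundHalfUp(100 * mapped / total, 2)
}
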