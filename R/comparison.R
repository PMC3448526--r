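# Five-way overlap classification of the two methods' mapping sets.

#' The five overlap categories
#'
#' Order used in all tabulations: exact, lexical_subset_of_formal,
#' formal_subset_of_lexical, overlap, nothing.
#'
#' @export
overlapCategories <- c("exact", "lexical_subset_of_formal",
                       "formal_subset_of_lexical", "overlap", "nothing")

#' Classify the overlap between two mapped-target sets
#'
#' For one concept mapped by both methods, compares the lexical target set
#' `L` with the formal target set `F`:
#' * `exact` — identical sets;
#' * `formal_subset_of_lexical` — `F` a proper subset of `L`;
#' * `lexical_subset_of_formal` — `L` a proper subset of `F`;
#' * `overlap` — non-empty intersection, neither containment;
#' * `nothing` — disjoint sets.
#' The five categories partition all possible pairs of non-empty sets.
#'
#' @param L,F Non-empty character vectors (sets) of target concept ids.
#' @return One of [overlapCategories].
#' @examples
#' classifyOverlap(c("a", "b"), "a")
#' @export
classifyOverlap <- function(L, F) {
  L <- unique(L); F <- unique(F)
  if (!length(L) || !length(F)) {
    stop("both target sets must be non-empty; pre-filter to doubly-mapped concepts")
  }
  linf <- all(L %in% F)
  finl <- all(F %in% L)
  if (linf && finl) return("exact")
  if (finl) return("formal_subset_of_lexical")
  if (linf) return("lexical_subset_of_formal")
  if (length(intersect(L, F))) return("overlap") else return("nothing")
}

#' Compare a lexical and a formal mapping concept by concept
#'
#' Restricted to concepts mapped by *both* methods (the doubly-mapped
#' intersection); concepts mapped by only one method are reported in the
#' `coverageOnly` counts. Returns per-concept overlap records and the
#' category count table; the five categories always partition the compared
#' concepts, so the counts sum to the total.
#'
#' @param mL Lexical [PhenoMapping-class].
#' @param mF Formal [PhenoMapping-class]; must share `mL`'s direction.
#' @return List with elements `direction`, `counts` (named integer over
#'   [overlapCategories]), `total`, `records` (data frame: `concept`,
#'   `category`, `lexical_size`, `formal_size`, `intersection_size`) and
#'   `coverageOnly` (concepts mapped by exactly one method).
#' @export
compareMappings <- function(mL, mF) {
  stopifnot(is(mL, "PhenoMapping"), is(mF, "PhenoMapping"))
  if (mL@sourcePrefix != mF@sourcePrefix || mL@targetPrefix != mF@targetPrefix) {
    stop("mappings must share the same direction (",
         mappingDirection(mL), " vs ", mappingDirection(mF), ")")
  }
  both <- sort(intersect(names(mL@entries), names(mF@entries)))
  records <- data.frame(
    concept = both,
    category = vapply(both, function(c)
      classifyOverlap(mL@entries[[c]], mF@entries[[c]]), ""),
    lexical_size = vapply(both, function(c) length(mL@entries[[c]]), 0L),
    formal_size = vapply(both, function(c) length(mF@entries[[c]]), 0L),
    intersection_size = vapply(both, function(c)
      length(intersect(mL@entries[[c]], mF@entries[[c]])), 0L),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  counts <- table(factor(records$category, levels = overlapCategories))
  list(
    direction = mappingDirection(mL),
    counts = setNames(as.integer(counts), overlapCategories),
    total = length(both),
    records = records,
    coverageOnly = c(
      lexical_only = length(setdiff(names(mL@entries), names(mF@entries))),
      formal_only = length(setdiff(names(mF@entries), names(mL@entries)))
    )
  )
}

#' Write an overlap report table
#'
#' One TSV with rows = the five categories plus the total and columns = the
#' supplied directions.
#'
#' @param comparisons Named list of results from [compareMappings()].
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
writeOverlapReport <- function(comparisons, file) {
  tab <- data.frame(
    category = c(overlapCategories, "total"),
    stringsAsFactors = FALSE
  )
  for (cmp in comparisons) {
    tab[[cmp$direction]] <- unname(c(cmp$counts, cmp$total))
  }
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
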