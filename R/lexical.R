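# Lexical seed matching: exact equality of normalized names/synonyms.

#' Normalize a concept label for lexical matching
#'
#' Lowercases, replaces Unicode punctuation (including hyphens) with spaces,
#' collapses whitespace runs and strips leading/trailing space. Exact string
#' equality of normalized labels is the whole matching criterion: no
#' stemming, no edit distance.
#'
#' @param s Character vector of labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalizeLabel("Ataxia--gait")
#' @export
normalizeLabel <- function(s) {
  s <- tolower(s)
  s <- gsub("\\p{P}+", " ", s, perl = TRUE)
  s <- gsub("[ \t\r\n]+", " ", s)
  trimws(s)
}

.matchKinds <- c("name-name", "name-synonym", "synonym-name", "synonym-synonym")

# One row per (concept, normalized string, kind); obsolete concepts and empty
# normalized strings excluded.
.lexicalPool <- function(o, exactSynonymsOnly = FALSE) {
  keep <- o@ids[!o@obsolete]
  nm <- data.frame(id = keep,
                   norm = normalizeLabel(o@labels[match(keep, o@ids)]),
                   kind = "name", stringsAsFactors = FALSE)
  syn <- lapply(keep, function(id) {
    s <- o@synonyms[[id]]
    if (!NROW(s)) return(NULL)
    if (exactSynonymsOnly) s <- s[s$scope == "EXACT", , drop = FALSE]
    if (!nrow(s)) return(NULL)
    data.frame(id = id, norm = normalizeLabel(s$text), kind = "synonym",
               stringsAsFactors = FALSE)
  })
  pool <- rbind(nm, do.call(rbind, syn))
  unique(pool[nzchar(pool$norm), , drop = FALSE])
}

#' Lexical equivalence seed pairs between two ontologies
#'
#' Emits a pair `(a, b)` whenever some normalized name-or-synonym of a
#' concept `a` in `o1` equals some normalized name-or-synonym of a concept
#' `b` in `o2`. Each pair appears at most once; `matched_on` records the
#' strongest evidence, in the priority order name-name > name-synonym >
#' synonym-name > synonym-synonym. Obsolete concepts never match. Pairs are
#' interpreted downstream as equivalence axioms before taxonomic closure.
#' Many-to-many seeds are allowed.
#'
#' @param o1,o2 Two [PhenoOntology-class] objects with distinct prefixes.
#' @param exactSynonymsOnly Restrict the synonym pool to EXACT-scope synonyms.
#' @return Data frame with columns `left` (o1 concept), `right` (o2 concept)
#'   and `matched_on`, sorted by (left, right).
#' @export
lexicalSeedPairs <- function(o1, o2, exactSynonymsOnly = FALSE) {
  stopifnot(is(o1, "PhenoOntology"), is(o2, "PhenoOntology"))
  if (identical(o1@prefix, o2@prefix)) {
    stop("the two ontologies must have distinct prefixes")
  }
  if (!length(o1@ids) || !length(o2@ids)) stop("both ontologies must be non-empty")
  p1 <- .lexicalPool(o1, exactSynonymsOnly)
  p2 <- .lexicalPool(o2, exactSynonymsOnly)
  m <- merge(p1, p2, by = "norm", suffixes = c(".l", ".r"))
  if (!nrow(m)) {
    return(data.frame(left = character(), right = character(),
                      matched_on = character(), stringsAsFactors = FALSE))
  }
  pri <- match(paste(m$kind.l, m$kind.r, sep = "-"), .matchKinds)
  key <- paste(m$id.l, m$id.r)
  best <- tapply(pri, key, min)
  parts <- strsplit(names(best), " ", fixed = TRUE)
  out <- data.frame(
    left = vapply(parts, `[`, "", 1L),
    right = vapply(parts, `[`, "", 2L),
    matched_on = .matchKinds[as.integer(best)],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$left, out$right), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write lexical seed pairs
#'
#' The native format is a three-column TSV `left<TAB>right<TAB>matched_on`;
#' the reader also accepts the plain two-column whitespace-separated record
#' form `HP:0002249 MP:0003292` (matched_on then defaults to `name-name`).
#'
#' @param x File path, single string, or character vector of lines.
#' @return Data frame with columns `left`, `right`, `matched_on`.
#' @export
readSeedPairs <- function(x) {
  lines <- .oboLines(x)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) stop(sprintf("line %d: expected at least 2 fields", bad[1]))
  data.frame(
    left = vapply(toks, `[`, "", 1L),
    right = vapply(toks, `[`, "", 2L),
    matched_on = vapply(toks, function(t) if (length(t) >= 3L) t[3] else "name-name", ""),
    stringsAsFactors = FALSE
  )
}

#' @rdname readSeedPairs
#' @param pairs Data frame as returned by [lexicalSeedPairs()].
#' @param file Output path.
#' @export
writeSeedPairs <- function(pairs, file) {
  write.table(pairs[c("left", "right", "matched_on")], file,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
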