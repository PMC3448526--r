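# OBO 1.2 subset reader/writer.
#
# Supported tags: id, name, synonym: "text" SCOPE [], is_a: ID ! label,
# is_obsolete, intersection_of (EQ dialect, see parseEQDefinitions).
# Other relationship types are ignored with a warning; header lines beyond
# format-version/ontology are skipped.

.oboLines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}

# Split an OBO document into [Term] stanzas; each stanza is a data frame of
# (tag, value) rows plus its ordinal among [Term] stanzas.
.oboStanzas <- function(lines) {
  lines <- sub("[ \t]+$", "", lines)
  hdr <- grep("^\\[", lines)
  termStarts <- grep("^\\[Term\\]$", lines)
  out <- vector("list", length(termStarts))
  for (k in seq_along(termStarts)) {
    s <- termStarts[k]
    after <- hdr[hdr > s]
    e <- if (length(after)) min(after) - 1L else length(lines)
    body <- if (e >= s + 1L) lines[(s + 1L):e] else character(0)
    body <- body[nzchar(body) & !grepl("^!", body)]
    m <- regmatches(body, regexec("^([A-Za-z_][A-Za-z0-9_-]*):[ \t]*(.*)$", body))
    ok <- lengths(m) == 3L
    out[[k]] <- list(
      ordinal = k,
      tags = data.frame(
        tag = vapply(m[ok], `[`, "", 2L),
        value = vapply(m[ok], `[`, "", 3L),
        stringsAsFactors = FALSE
      )
    )
  }
  out
}

.stripComment <- function(v) trimws(sub("!.*$", "", v))

.parseSynonym <- function(v) {
  m <- regmatches(v, regexec('^"(.*)"[ \t]*([A-Za-z_]*)', v))[[1]]
  if (length(m) < 2L) return(NULL)
  data.frame(text = m[2], scope = if (length(m) >= 3L) m[3] else "",
             stringsAsFactors = FALSE)
}

#' Parse an OBO-format ontology document
#'
#' Reads the OBO 1.2 subset used throughout the package: `[Term]` stanzas
#' with `id`, `name`, `synonym`, `is_a` and `is_obsolete` tags. Synonym
#' scope annotations (EXACT, RELATED, ...) are retained on the concept but
#' all synonyms enter the lexical pool by default. Obsolete terms are parsed
#' and flagged; their `is_a` parents are dropped so they never take part in
#' traversal, matching or mapping. Relationship tags other than `is_a`
#' trigger a single summary warning and are ignored. Parents pointing to a
#' different identifier prefix are dropped with a warning; same-prefix
#' parents must resolve within the document.
#'
#' @param x File path, single string, or character vector of lines.
#' @param name Optional ontology name; defaults to the `ontology:` header
#'   line, then to the identifier prefix.
#' @return A [PhenoOntology-class] object.
#' @seealso [writeOBO()], [parseEQDefinitions()]
#' @examples
#' ont <- parseOBO(c("[Term]", "id: HP:0000001", "name: All"))
#' nConcepts(ont)
#' @export
parseOBO <- function(x, name = NULL) {
  lines <- .oboLines(x)
  if (is.null(name)) {
    h <- grep("^ontology:", lines, value = TRUE)
    if (length(h)) name <- trimws(sub("^ontology:", "", h[1]))
  }
  stanzas <- .oboStanzas(lines)
  n <- length(stanzas)
  ids <- character(n); labels <- character(n); obsolete <- logical(n)
  synonyms <- vector("list", n); parents <- vector("list", n)
  nRel <- 0L
  for (st in stanzas) {
    tg <- st$tags
    id <- tg$value[tg$tag == "id"]
    if (length(id) == 0L || !nzchar(id[1])) {
      stop(sprintf("term stanza %d: missing 'id' tag", st$ordinal))
    }
    i <- st$ordinal
    ids[i] <- trimws(id[1])
    nm <- tg$value[tg$tag == "name"]
    labels[i] <- if (length(nm)) trimws(nm[1]) else trimws(id[1])
    syn <- tg$value[tg$tag == "synonym"]
    synonyms[[i]] <- do.call(rbind, c(list(
      data.frame(text = character(), scope = character(), stringsAsFactors = FALSE)),
      lapply(syn, .parseSynonym)))
    parents[[i]] <- unique(.stripComment(tg$value[tg$tag == "is_a"]))
    ob <- tg$value[tg$tag == "is_obsolete"]
    obsolete[i] <- length(ob) > 0L && tolower(trimws(ob[1])) == "true"
    nRel <- nRel + sum(tg$tag == "relationship")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (nRel > 0L) {
    warning(sprintf("ignored %d relationship tag(s); only is_a is traversed", nRel))
  }
  .checkConceptIDs(ids)
  prefix <- if (n) names(sort(table(idPrefix(ids)), decreasing = TRUE))[1] else NA_character_
  foreign <- unlist(lapply(parents, function(p) p[idPrefix(p) != prefix]))
  if (length(foreign)) {
    warning(sprintf("dropped %d is_a parent(s) outside prefix '%s': %s",
                    length(foreign), prefix,
                    paste(unique(foreign), collapse = ", ")))
    parents <- lapply(parents, function(p) p[idPrefix(p) == prefix])
  }
  PhenoOntology(prefix = prefix, ids = ids, labels = labels,
                synonyms = synonyms, parents = parents,
                obsolete = obsolete, name = name)
}

#' Serialize a PhenoOntology to OBO format
#'
#' Emits the same OBO 1.2 subset that [parseOBO()] reads, so that
#' `parseOBO(writeOBO(x))` is the identity on ids, labels, synonyms and
#' `is_a` edges. When `defs` is supplied, `intersection_of` lines encoding
#' the EQ definitions are included in the corresponding term stanzas.
#'
#' @param x A [PhenoOntology-class].
#' @param file Optional path; when `NULL` the lines are returned invisibly.
#' @param defs Optional [EQDefinitionSet-class] to embed.
#' @return Character vector of OBO lines, invisibly.
#' @export
writeOBO <- function(x, file = NULL, defs = NULL) {
  stopifnot(is(x, "PhenoOntology"))
  out <- c("format-version: 1.2", paste0("ontology: ", x@name), "")
  for (i in seq_along(x@ids)) {
    id <- x@ids[i]
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: ", x@labels[i]))
    syn <- x@synonyms[[i]]
    if (NROW(syn)) {
      out <- c(out, sprintf('synonym: "%s"%s []', syn$text,
                            ifelse(nzchar(syn$scope), paste0(" ", syn$scope), "")))
    }
    if (!is.null(defs) && id %in% names(defs@definitions)) {
      d <- defs@definitions[[id]]
      for (j in seq_len(nrow(d))) {
        out <- c(out,
                 paste0("intersection_of: ", d$quality[j]),
                 paste0("intersection_of: inheres_in ", d$entity[j]))
      }
    }
    if (length(x@parents[[i]])) {
      out <- c(out, paste0("is_a: ", x@parents[[i]]))
    }
    if (x@obsolete[i]) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Parse EQ logical definitions from OBO intersection_of tags
#'
#' Reads the entity-quality definition dialect: within a `[Term]` stanza,
#' a bare `intersection_of: QUALITY_ID` line is a genus (quality class) and
#' each following `intersection_of: inheres_in ENTITY_ID` line contributes
#' one (quality, entity) conjunct with that genus; a repeated genus line
#' starts a new block. Terms without `intersection_of` tags are absent from
#' the result. All referenced quality and entity identifiers must resolve
#' in the supplied support ontologies.
#'
#' @param x File path, single string, or character vector of OBO lines.
#' @param qualities Support [PhenoOntology-class] for the quality (PATO) role.
#' @param entities Support [PhenoOntology-class] for the entity (anatomy) role.
#' @return An [EQDefinitionSet-class] mapping concept id to its conjuncts.
#' @export
parseEQDefinitions <- function(x, qualities, entities) {
  stopifnot(is(qualities, "PhenoOntology"), is(entities, "PhenoOntology"))
  stanzas <- .oboStanzas(.oboLines(x))
  defs <- list()
  for (st in stanzas) {
    tg <- st$tags
    iv <- tg$value[tg$tag == "intersection_of"]
    if (length(iv) == 0L) next
    id <- tg$value[tg$tag == "id"]
    if (length(id) == 0L) {
      stop(sprintf("term stanza %d: missing 'id' tag", st$ordinal))
    }
    id <- trimws(id[1])
    iv <- .stripComment(iv)
    quality <- NA_character_
    qs <- character(0); es <- character(0)
    pendingGenus <- FALSE
    for (v in iv) {
      if (grepl("^inheres_in[ \t]+", v)) {
        if (is.na(quality)) {
          stop(sprintf("stanza %d (%s): differentia line before any genus line",
                       st$ordinal, id))
        }
        ent <- trimws(sub("^inheres_in[ \t]+", "", v))
        qs <- c(qs, quality); es <- c(es, ent)
        pendingGenus <- FALSE
      } else {
        if (pendingGenus) {
          stop(sprintf("stanza %d (%s): genus line without differentia", st$ordinal, id))
        }
        quality <- v
        pendingGenus <- TRUE
      }
    }
    if (pendingGenus || length(qs) == 0L) {
      stop(sprintf("stanza %d (%s): genus line without differentia", st$ordinal, id))
    }
    d <- unique(data.frame(quality = qs, entity = es, stringsAsFactors = FALSE))
    defs[[id]] <- d
  }
  badQ <- setdiff(unique(unlist(lapply(defs, `[[`, "quality"))), qualities@ids)
  badE <- setdiff(unique(unlist(lapply(defs, `[[`, "entity"))), entities@ids)
  if (length(badQ) || length(badE)) {
    stop("unresolvable IDs in formal definitions: ",
         paste(c(badQ, badE), collapse = ", "))
  }
  EQDefinitionSet(defs)
}
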