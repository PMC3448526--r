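# Annotation translation, cosine phenotype similarity, ranking and pooled
# ROC/AUC for the gene-disease prioritization use case.

#' Translate an annotation set through a mapping
#'
#' Union of the mapped target sets over the annotated concepts; concepts
#' without a mapping entry contribute nothing, so the result may be empty.
#'
#' @param concepts Character vector of annotated concept ids, all carrying
#'   the mapping's source prefix.
#' @param mapping A [PhenoMapping-class].
#' @return Sorted character vector of target concept ids (possibly empty).
#' @export
translateAnnotations <- function(concepts, mapping) {
  stopifnot(is(mapping, "PhenoMapping"))
  concepts <- unique(concepts)
  if (length(concepts) && any(idPrefix(concepts) != mapping@sourcePrefix)) {
    stop("annotation prefix does not match the mapping's source prefix (",
         mapping@sourcePrefix, ")")
  }
  hit <- intersect(concepts, names(mapping@entries))
  sort(unique(as.character(unlist(mapping@entries[hit], use.names = FALSE))))
}

#' Cosine similarity between two binary annotation vectors
#'
#' Annotation sets are presence/absence vectors over the concepts of one
#' ontology, so the cosine reduces to
#' `|a intersect b| / (sqrt(|a|) * sqrt(|b|))`. Returns 0 when either set is
#' empty (the zero vector has no direction). Always in `[0, 1]`.
#'
#' @param a,b Character vectors (sets) of concept ids in the same ontology.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' cosineSimilarity(c("MP:1", "MP:2"), c("MP:2", "MP:3"))
#' @export
cosineSimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) return(0)
  pa <- unique(idPrefix(a)); pb <- unique(idPrefix(b))
  if (length(pa) == 1L && length(pb) == 1L && pa != pb) {
    stop("annotation sets live in different ontologies (", pa, " vs ", pb, ")")
  }
  length(intersect(a, b)) / (sqrt(length(a)) * sqrt(length(b)))
}

#' Score and rank all disease-model pairs
#'
#' Computes the cosine phenotype similarity for every (disease, model)
#' combination after translating the side dictated by the scenario:
#' * `disease_to_model_space` — disease annotations are translated into the
#'   model ontology's concept space (mapping source must be the disease
#'   ontology);
#' * `model_to_disease_space` — model annotations are translated into the
#'   disease ontology's space.
#' Each mouse model carries exactly one gene; a pair is labeled positive iff
#' the human ortholog of that gene is associated with the disease in the
#' gold standard. Genes without an ortholog yield negative pairs. An empty
#' translated set scores 0 and stays in the ranking. Pairs are sorted by
#' similarity descending with deterministic (disease, model) tie-breaking.
#'
#' @param diseases Data frame `disease_id`, `concept_id` (one row per
#'   annotation).
#' @param models Data frame `model_id`, `gene_id`, `concept_id`.
#' @param mapping A [PhenoMapping-class] for the translated side.
#' @param scenario `"disease_to_model_space"` or `"model_to_disease_space"`.
#' @param orthology Data frame `mouse_gene`, `human_gene` (1:1).
#' @param gold Data frame `human_gene`, `disease_id` of known associations.
#' @return Data frame `disease`, `model`, `gene`, `similarity`, `positive`,
#'   sorted by descending similarity.
#' @export
rankPairs <- function(diseases, models, mapping,
                      scenario = c("disease_to_model_space", "model_to_disease_space"),
                      orthology, gold) {
  scenario <- match.arg(scenario)
  stopifnot(is(mapping, "PhenoMapping"))
  dsets <- split(diseases$concept_id, diseases$disease_id)
  msets <- split(models$concept_id, models$model_id)
  geneTab <- unique(models[c("model_id", "gene_id")])
  if (anyDuplicated(geneTab$model_id)) {
    stop("each mouse model must be associated with exactly one gene")
  }
  geneOf <- setNames(geneTab$gene_id, geneTab$model_id)
  dPrefix <- unique(idPrefix(unlist(dsets, use.names = FALSE)))
  mPrefix <- unique(idPrefix(unlist(msets, use.names = FALSE)))
  if (length(dPrefix) != 1L || length(mPrefix) != 1L) {
    stop("disease and model annotations must each use a single ontology prefix")
  }
  if (scenario == "disease_to_model_space") {
    if (mapping@sourcePrefix != dPrefix || mapping@targetPrefix != mPrefix) {
      stop("scenario disease_to_model_space needs a ", dPrefix, " -> ", mPrefix,
           " mapping, got ", mappingDirection(mapping))
    }
    dsets <- lapply(dsets, translateAnnotations, mapping = mapping)
  } else {
    if (mapping@sourcePrefix != mPrefix || mapping@targetPrefix != dPrefix) {
      stop("scenario model_to_disease_space needs a ", mPrefix, " -> ", dPrefix,
           " mapping, got ", mappingDirection(mapping))
    }
    msets <- lapply(msets, translateAnnotations, mapping = mapping)
  }
  orth <- setNames(orthology$human_gene, orthology$mouse_gene)
  goldKey <- paste(gold$human_gene, gold$disease_id)
  grid <- expand.grid(disease = names(dsets), model = names(msets),
                      stringsAsFactors = FALSE)
  grid$gene <- unname(geneOf[grid$model])
  grid$similarity <- mapply(function(d, m) cosineSimilarity(dsets[[d]], msets[[m]]),
                            grid$disease, grid$model)
  hg <- orth[grid$gene]
  grid$positive <- !is.na(hg) & paste(hg, grid$disease) %in% goldKey
  grid <- grid[order(-grid$similarity, grid$disease, grid$model), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Pooled ROC curve and AUC
#'
#' Single pooled ranking of all pairs across all diseases. Tied similarity
#' scores advance as one threshold step (block ties), the standard
#' convention; the curve starts at (0, 0), ends at (1, 1) and is
#' non-decreasing in both coordinates. The AUC is the trapezoidal area, so a
#' single all-tied block yields the diagonal and AUC 0.5.
#'
#' @param pairs Data frame with columns `similarity` and `positive`
#'   (as from [rankPairs()]); needs at least one positive and one negative.
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
rocAndAuc <- function(pairs) {
  pos <- as.logical(pairs$positive)
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) {
    stop("ROC evaluation needs at least one positive and one negative pair")
  }
  o <- order(-pairs$similarity)
  s <- pairs$similarity[o]
  p <- pos[o]
  newBlock <- c(TRUE, s[-1] != s[-length(s)])
  blockId <- cumsum(newBlock)
  tpB <- tapply(p, blockId, sum)
  fpB <- tapply(!p, blockId, sum)
  tpr <- c(0, cumsum(tpB) / P)
  fpr <- c(0, cumsum(fpB) / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = unname(fpr), tpr = unname(tpr)),
       auc = unname(auc))
}

# --- annotation corpus TSV interfaces -------------------------------------

#' Read / write the annotation corpus tables
#'
#' Plain TSVs with headers:
#' * model annotations: `model_id`, `gene_id`, `concept_id` (one row per
#'   annotation; the MGI_GenePheno.rpt role);
#' * disease annotations: `disease_id`, `concept_id` (the OMIM
#'   disease-to-HP-annotation role);
#' * orthology: `mouse_gene`, `human_gene` (the HMD_Human5.rpt role);
#' * gold associations: `human_gene`, `disease_id` (the MorbidMap role).
#'
#' @param file Path to the TSV.
#' @return The corresponding data frame.
#' @name annotation-io
NULL

#' @rdname annotation-io
#' @export
readModelAnnotations <- function(file) {
  read.delim(file, colClasses = "character")
}

#' @rdname annotation-io
#' @export
readDiseaseAnnotations <- function(file) {
  read.delim(file, colClasses = "character")
}

#' @rdname annotation-io
#' @export
readOrthology <- function(file) {
  read.delim(file, colClasses = "character")
}

#' @rdname annotation-io
#' @export
readGoldAssociations <- function(file) {
  read.delim(file, colClasses = "character")
}

#' @rdname annotation-io
#' @param x Data frame to write.
#' @export
writeAnnotationTable <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
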