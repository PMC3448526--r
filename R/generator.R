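# Seeded synthetic-data generator.
#
# Emulates the complete input bundle: two support ontologies (the anatomy
# and quality roles), a pair of species phenotype ontologies whose is_a
# structure is derived from EQ subsumption over the supports, EQ definition
# sets with controllable coverage, lexical labels with controllable
# cross-species sharing, model/disease annotation corpora with planted
# gene-disease associations, an orthology map and a gold standard.
#
# Both species draw their (entity, quality) pairs from one common pool with
# a controllable overlap (fracSharedEQ), so "identical-EQ counterparts"
# exist by construction and the formal aligner's output is predictable.
# Shared lexical labels are placed on counterpart pairs with probability
# proportional to concept depth: specific phenotypes are the ones most
# likely to carry the same wording in both species, which is what makes the
# lexical method's mapped sets concentrate on deep concepts.

#' Generator configuration
#'
#' @param seed Integer seed; the entire bundle is a pure function of the
#'   configuration.
#' @param entityDepth,entityBranching Shape of the entity (anatomy-role)
#'   support tree: a complete tree with `(b^(d+1)-1)/(b-1)` nodes.
#' @param qualityDepth,qualityBranching Shape of the quality (PATO-role) tree.
#' @param nConcepts Phenotype concepts per species ontology (excluding the
#'   species root).
#' @param fracDefined1,fracDefined2 Fraction of each species' concepts that
#'   retain their EQ definition (emulating partial definition coverage).
#' @param fracSharedEQ Fraction of each species' concepts whose EQ pair is
#'   shared with the other species (identical-EQ counterparts).
#' @param fracSharedLabels Fraction of counterpart pairs that also share an
#'   identical label or synonym (controls lexical matchability); assignment
#'   is depth-weighted towards specific concepts.
#' @param nGenes,nModels,nDiseases Corpus sizes; each model carries one gene.
#' @param annotationsPerModel Length-2 integer range of annotations per
#'   model (and per non-associated disease).
#' @param nTrueAssociations Number of planted (gene, disease) associations;
#'   must not exceed `nGenes` or `nDiseases`.
#' @param annotationNoise Fraction of a planted disease's annotations
#'   replaced by uniformly random concepts.
#' @param prefix1,prefix2 Identifier prefixes of the two species ontologies.
#' @return A validated configuration (class `GeneratorConfig`).
#' @seealso [presetConfig()], [generateBundle()]
#' @export
generatorConfig <- function(seed = 1L,
                            entityDepth = 3L, entityBranching = 4L,
                            qualityDepth = 2L, qualityBranching = 3L,
                            nConcepts = 150L,
                            fracDefined1 = 1, fracDefined2 = 1,
                            fracSharedEQ = 0.7, fracSharedLabels = 1,
                            nGenes = 15L, nModels = 15L, nDiseases = 12L,
                            annotationsPerModel = c(4L, 6L),
                            nTrueAssociations = 8L,
                            annotationNoise = 0,
                            prefix1 = "HP", prefix2 = "MP") {
  cfg <- list(seed = as.integer(seed),
              entityDepth = as.integer(entityDepth),
              entityBranching = as.integer(entityBranching),
              qualityDepth = as.integer(qualityDepth),
              qualityBranching = as.integer(qualityBranching),
              nConcepts = as.integer(nConcepts),
              fracDefined1 = fracDefined1, fracDefined2 = fracDefined2,
              fracSharedEQ = fracSharedEQ, fracSharedLabels = fracSharedLabels,
              nGenes = as.integer(nGenes), nModels = as.integer(nModels),
              nDiseases = as.integer(nDiseases),
              annotationsPerModel = as.integer(annotationsPerModel),
              nTrueAssociations = as.integer(nTrueAssociations),
              annotationNoise = annotationNoise,
              prefix1 = prefix1, prefix2 = prefix2)
  for (p in c("fracDefined1", "fracDefined2", "fracSharedEQ",
              "fracSharedLabels", "annotationNoise")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  for (p in c("entityDepth", "entityBranching", "qualityDepth",
              "qualityBranching", "nConcepts", "nGenes", "nModels",
              "nDiseases")) {
    if (cfg[[p]] < 1L) stop(p, " must be at least 1")
  }
  if (length(cfg$annotationsPerModel) != 2L ||
      cfg$annotationsPerModel[1] > cfg$annotationsPerModel[2] ||
      cfg$annotationsPerModel[1] < 1L) {
    stop("annotationsPerModel must be an increasing range of counts >= 1")
  }
  if (cfg$nTrueAssociations > cfg$nDiseases || cfg$nTrueAssociations > cfg$nGenes) {
    stop("nTrueAssociations must not exceed nDiseases or nGenes")
  }
  treeSize <- function(d, b) if (b == 1L) d + 1L else (b^(d + 1L) - 1L) %/% (b - 1L)
  poolSize <- (treeSize(cfg$entityDepth, cfg$entityBranching) - 1L) *
              (treeSize(cfg$qualityDepth, cfg$qualityBranching) - 1L)
  nShared <- round(cfg$fracSharedEQ * cfg$nConcepts)
  needed <- nShared + 2L * (cfg$nConcepts - nShared)
  if (poolSize < needed) {
    stop(sprintf("support trees yield only %d distinct (entity, quality) pairs; %d needed",
                 poolSize, needed))
  }
  nShared0 <- max(nShared, 0L)
  if (cfg$nTrueAssociations > 0L && nShared0 < cfg$annotationsPerModel[2]) {
    stop("fracSharedEQ too small: planted models need at least ",
         cfg$annotationsPerModel[2], " shared-EQ concepts to annotate from")
  }
  structure(cfg, class = "GeneratorConfig")
}

#' Preset generator configurations
#'
#' * `"small"` — the fully-shared, noise-free condition: complete definition
#'   coverage and label sharing on both sides, sparse deep support trees;
#'   under it the planted associations are recoverable with AUC 1 by both
#'   methods.
#' * `"paper-shaped"` — partial definition coverage near 48% / 63%, partial
#'   (depth-weighted) label sharing, bushier support trees and 25%
#'   annotation noise, reproducing the qualitative regime in which the
#'   formal method maps more concepts while the lexical method's mapped
#'   sets are larger and more specific.
#'
#' @param preset `"small"` or `"paper-shaped"`.
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [generatorConfig()].
#' @return A `GeneratorConfig`.
#' @export
presetConfig <- function(preset = c("small", "paper-shaped"), seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "small" = list(
      entityDepth = 3L, entityBranching = 4L,
      qualityDepth = 2L, qualityBranching = 3L,
      nConcepts = 150L, fracDefined1 = 1, fracDefined2 = 1,
      fracSharedEQ = 0.7, fracSharedLabels = 1,
      nGenes = 15L, nModels = 15L, nDiseases = 12L,
      annotationsPerModel = c(4L, 6L), nTrueAssociations = 8L,
      annotationNoise = 0
    ),
    "paper-shaped" = list(
      entityDepth = 2L, entityBranching = 6L,
      qualityDepth = 2L, qualityBranching = 2L,
      nConcepts = 150L, fracDefined1 = 0.48, fracDefined2 = 0.63,
      fracSharedEQ = 0.7, fracSharedLabels = 0.3,
      nGenes = 20L, nModels = 20L, nDiseases = 15L,
      annotationsPerModel = c(4L, 6L), nTrueAssociations = 10L,
      annotationNoise = 0.25
    )
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(generatorConfig, c(list(seed = seed), args))
}

.makeTree <- function(prefix, rootLabel, depth, branching) {
  ids <- sprintf("%s:%07d", prefix, 1L)
  labels <- rootLabel
  parents <- list(character(0))
  level <- 1L  # indices of current level
  counter <- 1L
  for (d in seq_len(depth)) {
    nxt <- integer(0)
    for (i in level) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        ids <- c(ids, sprintf("%s:%07d", prefix, counter))
        labels <- c(labels, paste(labels[i], b))
        parents[[counter]] <- ids[i]
        nxt <- c(nxt, counter)
      }
    }
    level <- nxt
  }
  PhenoOntology(prefix = prefix, ids = ids, labels = labels,
                parents = parents, name = rootLabel)
}

#' Generate the two support ontologies
#'
#' Complete rooted trees of the configured depth and branching for the
#' entity (anatomy) and quality (PATO) roles, shared between the two
#' species. Deterministic given the configuration.
#'
#' @param cfg A `GeneratorConfig`.
#' @return List with elements `entities` and `qualities`.
#' @export
generateSupportOntologies <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  list(
    entities = .makeTree("ENT", "entity", cfg$entityDepth, cfg$entityBranching),
    qualities = .makeTree("QUA", "quality", cfg$qualityDepth, cfg$qualityBranching)
  )
}

# Build one species ontology from an ordered list of EQ pairs: is_a edges
# are the transitive reduction of the EQ subsumption order among the
# sampled pairs; concepts with no subsumer attach to a species root.
.buildSpecies <- function(prefix, eqs, eAncSelf, qAncSelf) {
  n <- nrow(eqs)
  rootId <- sprintf("%s:%07d", prefix, 1L)
  ids <- sprintf("%s:%07d", prefix, seq_len(n) + 1L)
  sub <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    sub[i, ] <- (eqs$quality %in% qAncSelf[[eqs$quality[i]]]) &
                (eqs$entity %in% eAncSelf[[eqs$entity[i]]])
  }
  diag(sub) <- FALSE
  red <- sub & !((sub %*% sub) > 0)
  parents <- lapply(seq_len(n), function(i) {
    p <- ids[red[i, ]]
    if (length(p)) p else rootId
  })
  depth <- rowSums(sub)  # number of strict sampled subsumers = specificity
  PhenoOntology(
    prefix = prefix,
    ids = c(rootId, ids),
    labels = c(sprintf("%s phenotype root", tolower(prefix)),
               sprintf("%s phenotype %04d", tolower(prefix), seq_len(n))),
    parents = c(list(character(0)), parents),
    name = sprintf("synthetic %s", prefix)
  ) -> ont
  list(ontology = ont, ids = ids, depth = depth)
}

#' Generate the species ontology pair with EQ definitions and labels
#'
#' Samples `nConcepts` distinct (entity, quality) pairs per species from a
#' common pool, with `fracSharedEQ` of them shared between species
#' (identical-EQ counterparts). is_a edges are asserted exactly where EQ
#' subsumption holds among the sampled definitions (transitive reduction),
#' plus a species root, so each species ontology is logically coherent with
#' its definitions. `fracDefined1`/`fracDefined2` of the concepts retain
#' their definition; `fracSharedLabels` of counterpart pairs receive an
#' identical shared label (depth-weighted towards specific concepts; on the
#' second species the shared string lands on the name or on an EXACT
#' synonym). All other labels are species-distinct.
#'
#' @param cfg A `GeneratorConfig`.
#' @param supports Result of [generateSupportOntologies()].
#' @return List with `o1`, `defs1`, `o2`, `defs2`, plus generator
#'   bookkeeping: `counterparts` (data frame of identical-EQ id pairs) and
#'   `sharedLabelled` (the subset that also shares a label).
#' @export
generateSpeciesPair <- function(cfg, supports = generateSupportOntologies(cfg)) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  entities <- supports$entities; qualities <- supports$qualities
  eAncSelf <- .ancestorIndex(entities, includeSelf = TRUE)
  qAncSelf <- .ancestorIndex(qualities, includeSelf = TRUE)
  entsNR <- setdiff(entities@ids, ontologyRoots(entities))
  quasNR <- setdiff(qualities@ids, ontologyRoots(qualities))
  nE <- length(entsNR)
  poolSize <- nE * length(quasNR)
  n <- cfg$nConcepts
  nShared <- round(cfg$fracSharedEQ * n)
  nExtra <- n - nShared
  withr::with_seed(cfg$seed, {
    pick <- sample.int(poolSize, nShared + 2L * nExtra)
    pairOf <- function(i) data.frame(
      entity = entsNR[((i - 1L) %% nE) + 1L],
      quality = quasNR[((i - 1L) %/% nE) + 1L],
      stringsAsFactors = FALSE
    )
    shared <- pick[seq_len(nShared)]
    extra1 <- pick[nShared + seq_len(nExtra)]
    extra2 <- pick[nShared + nExtra + seq_len(nExtra)]
    ord1 <- sample.int(n); ord2 <- sample.int(n)
    pool1 <- c(shared, extra1)[ord1]
    pool2 <- c(shared, extra2)[ord2]
    eqs1 <- pairOf(pool1); eqs2 <- pairOf(pool2)
    sp1 <- .buildSpecies(cfg$prefix1, eqs1, eAncSelf, qAncSelf)
    sp2 <- .buildSpecies(cfg$prefix2, eqs2, eAncSelf, qAncSelf)
    pos1 <- match(shared, pool1)  # concept positions of the shared pairs
    pos2 <- match(shared, pool2)
    counterparts <- data.frame(o1 = sp1$ids[pos1], o2 = sp2$ids[pos2],
                               stringsAsFactors = FALSE)
    o1 <- sp1$ontology; o2 <- sp2$ontology
    # shared labels: depth-weighted choice among counterpart pairs
    nLab <- round(cfg$fracSharedLabels * nShared)
    chosen <- integer(0)
    if (nLab > 0L && nShared > 0L) {
      w <- sp1$depth[pos1] + 1
      chosen <- sample.int(nShared, nLab, prob = w)
      eLab <- setNames(entities@labels, entities@ids)
      qLab <- setNames(qualities@labels, qualities@ids)
      for (k in chosen) {
        sharedEq <- pairOf(shared[k])
        lab <- paste("abnormal", eLab[[sharedEq$entity]], qLab[[sharedEq$quality]])
        i1 <- match(counterparts$o1[k], o1@ids)
        o1@labels[i1] <- lab
        i2 <- match(counterparts$o2[k], o2@ids)
        if (runif(1) < 0.5) {
          o2@labels[i2] <- lab
        } else {
          o2@synonyms[[i2]] <- rbind(
            o2@synonyms[[i2]],
            data.frame(text = lab, scope = "EXACT", stringsAsFactors = FALSE))
        }
      }
    }
    # Definition coverage is correlated across species on shared-EQ pairs:
    # both real phenotype ontologies draw their EQ definitions from the same
    # shared curation effort, so a phenotype defined in one species tends to
    # be defined in the other. Species 2 samples freely; species 1 fills its
    # budget first from concepts whose counterpart is defined in species 2.
    defIdx2 <- sort(sample.int(n, round(cfg$fracDefined2 * n)))
    k1 <- round(cfg$fracDefined1 * n)
    cpDefined <- pos1[pos2 %in% defIdx2]
    if (length(cpDefined) >= k1) {
      defIdx1 <- sort(cpDefined[sample.int(length(cpDefined), k1)])
    } else {
      rest <- setdiff(seq_len(n), cpDefined)
      defIdx1 <- sort(c(cpDefined,
                        rest[sample.int(length(rest), k1 - length(cpDefined))]))
    }
  })
  mkDefs <- function(sp, eqs, idx) {
    defs <- lapply(idx, function(i) eqs[i, c("quality", "entity"), drop = FALSE])
    names(defs) <- sp$ids[idx]
    EQDefinitionSet(defs, conceptPrefix = idPrefix(sp$ids[1]))
  }
  list(
    o1 = o1, defs1 = mkDefs(sp1, eqs1, defIdx1),
    o2 = o2, defs2 = mkDefs(sp2, eqs2, defIdx2),
    counterparts = counterparts,
    sharedLabelled = counterparts[sort(chosen), , drop = FALSE]
  )
}

#' Generate the annotation corpus, orthology and gold standard
#'
#' Each model receives one mouse gene and a set of species-2 concept
#' annotations; models of planted genes annotate from the shared-EQ
#' (counterpart-bearing) concepts. The orthology is a 1:1 mouse-to-human
#' gene map. For each planted (gene, disease) association, the disease's
#' species-1 annotations are the identical-EQ counterparts of that gene's
#' (first) model's annotations, with an `annotationNoise` fraction
#' resampled uniformly; non-associated diseases are annotated uniformly at
#' random. The gold standard is exactly the planted set, expressed in human
#' gene ids.
#'
#' @param cfg A `GeneratorConfig`.
#' @param pair Result of [generateSpeciesPair()].
#' @return List with data frames `models` (`model_id`, `gene_id`,
#'   `concept_id`), `diseases` (`disease_id`, `concept_id`), `orthology`
#'   (`mouse_gene`, `human_gene`), `gold` (`human_gene`, `disease_id`) and
#'   the planted associations in mouse-gene terms (`planted`).
#' @export
generateAnnotationCorpus <- function(cfg, pair) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  o1 <- pair$o1; o2 <- pair$o2
  allHP <- setdiff(o1@ids, ontologyRoots(o1))
  allMP <- setdiff(o2@ids, ontologyRoots(o2))
  toHP <- setNames(pair$counterparts$o1, pair$counterparts$o2)
  mouseGenes <- sprintf("MGI:%07d", seq_len(cfg$nGenes))
  humanGenes <- sprintf("HGNC:%07d", seq_len(cfg$nGenes))
  modelIds <- sprintf("MODEL:%07d", seq_len(cfg$nModels))
  diseaseIds <- sprintf("OMIM:%06d", seq_len(cfg$nDiseases))
  geneOfModel <- mouseGenes[((seq_len(cfg$nModels) - 1L) %% cfg$nGenes) + 1L]
  lo <- cfg$annotationsPerModel[1]; hi <- cfg$annotationsPerModel[2]
  nAnn <- function() if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  withr::with_seed(cfg$seed + 99991L, {
    gIdx <- sample.int(cfg$nGenes, cfg$nTrueAssociations)
    dIdx <- sample.int(cfg$nDiseases, cfg$nTrueAssociations)
    plantedGenes <- mouseGenes[gIdx]
    modelAnn <- vector("list", cfg$nModels)
    for (i in seq_len(cfg$nModels)) {
      k <- nAnn()
      src <- if (geneOfModel[i] %in% plantedGenes) pair$counterparts$o2 else allMP
      modelAnn[[i]] <- sample(src, k)
    }
    firstModelOfGene <- match(mouseGenes, geneOfModel)
    diseaseAnn <- vector("list", cfg$nDiseases)
    for (j in seq_len(cfg$nDiseases)) {
      t <- match(j, dIdx)
      if (!is.na(t)) {
        mAnn <- modelAnn[[firstModelOfGene[gIdx[t]]]]
        base <- unname(toHP[mAnn])
        nNoise <- round(cfg$annotationNoise * length(base))
        if (nNoise > 0L) {
          at <- sample.int(length(base), nNoise)
          base[at] <- sample(setdiff(allHP, base), nNoise)
        }
        diseaseAnn[[j]] <- base
      } else {
        diseaseAnn[[j]] <- sample(allHP, nAnn())
      }
    }
  })
  list(
    models = data.frame(
      model_id = rep(modelIds, lengths(modelAnn)),
      gene_id = rep(geneOfModel, lengths(modelAnn)),
      concept_id = unlist(modelAnn, use.names = FALSE),
      stringsAsFactors = FALSE
    ),
    diseases = data.frame(
      disease_id = rep(diseaseIds, lengths(diseaseAnn)),
      concept_id = unlist(diseaseAnn, use.names = FALSE),
      stringsAsFactors = FALSE
    ),
    orthology = data.frame(mouse_gene = mouseGenes, human_gene = humanGenes,
                           stringsAsFactors = FALSE),
    gold = data.frame(human_gene = humanGenes[gIdx],
                      disease_id = diseaseIds[dIdx],
                      stringsAsFactors = FALSE),
    planted = data.frame(mouse_gene = mouseGenes[gIdx],
                         disease_id = diseaseIds[dIdx],
                         stringsAsFactors = FALSE)
  )
}

#' Generate the complete input bundle
#'
#' Support ontologies, species pair with definitions and labels, annotation
#' corpus, orthology and gold standard — a pure function of the
#' configuration.
#'
#' @param cfg A `GeneratorConfig`.
#' @return List combining the outputs of [generateSupportOntologies()],
#'   [generateSpeciesPair()] and [generateAnnotationCorpus()], plus
#'   `config`.
#' @export
generateBundle <- function(cfg) {
  supports <- generateSupportOntologies(cfg)
  pair <- generateSpeciesPair(cfg, supports)
  corpus <- generateAnnotationCorpus(cfg, pair)
  c(list(config = cfg, entities = supports$entities,
         qualities = supports$qualities), pair, corpus)
}

#' Write / read a bundle on disk
#'
#' Writes the bundle in the package's plain-text formats: OBO files for the
#' support and species ontologies, separate OBO files carrying only the EQ
#' definition stanzas, TSVs for the annotation corpus, and a JSON manifest
#' recording the configuration and per-file MD5 checksums.
#'
#' @param bundle Result of [generateBundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeOBO(bundle$entities, fp("entities.obo"))
  writeOBO(bundle$qualities, fp("qualities.obo"))
  writeOBO(bundle$o1, fp("species1.obo"))
  writeOBO(bundle$o2, fp("species2.obo"))
  defStub <- function(defs) {
    ids <- names(defs@definitions)
    PhenoOntology(prefix = defs@conceptPrefix, ids = ids, labels = ids)
  }
  writeOBO(defStub(bundle$defs1), fp("species1_defs.obo"), defs = bundle$defs1)
  writeOBO(defStub(bundle$defs2), fp("species2_defs.obo"), defs = bundle$defs2)
  writeAnnotationTable(bundle$models, fp("model_annotations.tsv"))
  writeAnnotationTable(bundle$diseases, fp("disease_annotations.tsv"))
  writeAnnotationTable(bundle$orthology, fp("orthology.tsv"))
  writeAnnotationTable(bundle$gold, fp("gold_associations.tsv"))
  files <- c("entities.obo", "qualities.obo", "species1.obo", "species2.obo",
             "species1_defs.obo", "species2_defs.obo", "model_annotations.tsv",
             "disease_annotations.tsv", "orthology.tsv", "gold_associations.tsv")
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  jsonlite::write_json(
    list(config = unclass(bundle$config), checksums = as.list(sums)),
    fp("manifest.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname writeBundle
#' @param dir Directory previously written by [writeBundle()].
#' @export
readBundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  entities <- parseOBO(fp("entities.obo"))
  qualities <- parseOBO(fp("qualities.obo"))
  list(
    entities = entities, qualities = qualities,
    o1 = parseOBO(fp("species1.obo")),
    o2 = parseOBO(fp("species2.obo")),
    defs1 = parseEQDefinitions(fp("species1_defs.obo"), qualities, entities),
    defs2 = parseEQDefinitions(fp("species2_defs.obo"), qualities, entities),
    models = readModelAnnotations(fp("model_annotations.tsv")),
    diseases = readDiseaseAnnotations(fp("disease_annotations.tsv")),
    orthology = readOrthology(fp("orthology.tsv")),
    gold = readGoldAssociations(fp("gold_associations.tsv"))
  )
}
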