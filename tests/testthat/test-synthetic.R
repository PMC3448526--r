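# Synthetic bundle generator: determinism, planted structure, degradation.

tinyCfg <- function(seed, noise = 0, ...) {
  args <- list(seed = seed,
               entityDepth = 2L, entityBranching = 4L,
               qualityDepth = 2L, qualityBranching = 2L,
               nConcepts = 60L, fracDefined1 = 1, fracDefined2 = 1,
               fracSharedEQ = 0.7, fracSharedLabels = 1,
               nGenes = 10L, nModels = 10L, nDiseases = 8L,
               annotationsPerModel = c(3L, 4L), nTrueAssociations = 6L,
               annotationNoise = noise)
  over <- list(...)
  args[names(over)] <- over
  do.call(generatorConfig, args)
}

test_that("support trees have the geometric-series node count", {
  cfg <- generatorConfig(entityDepth = 1L, entityBranching = 2L,
                         qualityDepth = 2L, qualityBranching = 3L,
                         nConcepts = 2L, fracSharedEQ = 1,
                         nTrueAssociations = 1L,
                         annotationsPerModel = c(1L, 1L))
  sup <- generateSupportOntologies(cfg)
  expect_equal(nConcepts(sup$entities), 3L)            # (2^2-1)/(2-1)
  expect_equal(nConcepts(sup$qualities), 13L)          # (3^3-1)/(3-1)
  expect_length(ontologyRoots(sup$entities), 1L)
  # every non-root node has exactly one parent (a tree)
  expect_true(all(lengths(sup$qualities@parents[-1]) == 1L))
})

test_that("configuration constraints are enforced", {
  expect_error(generatorConfig(nTrueAssociations = 20L, nDiseases = 5L),
               "nTrueAssociations")
  expect_error(generatorConfig(annotationNoise = 1.5), "annotationNoise")
  expect_error(generatorConfig(entityDepth = 1L, entityBranching = 1L,
                               qualityDepth = 1L, qualityBranching = 1L,
                               nConcepts = 50L),
               "distinct \\(entity, quality\\) pairs")
})

test_that("the bundle is a pure function of the configuration (byte-identical)", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeBundle(generateBundle(tinyCfg(99)), d1)
  writeBundle(generateBundle(tinyCfg(99)), d2)
  files <- setdiff(list.files(d1), "manifest.json")
  expect_true(length(files) >= 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the content
  d3 <- withr::local_tempdir()
  writeBundle(generateBundle(tinyCfg(100)), d3)
  expect_false(identical(readLines(file.path(d1, "species1.obo")),
                         readLines(file.path(d3, "species1.obo"))))
})

test_that("species is_a edges are exactly the reduction of EQ subsumption", {
  cfg <- tinyCfg(3)
  sup <- generateSupportOntologies(cfg)
  pair <- generateSpeciesPair(cfg, sup)
  o1 <- pair$o1; defs <- pair$defs1
  root <- ontologyRoots(o1)
  ids <- setdiff(conceptIDs(o1), root)
  # parent (non-root) implies strict EQ subsumption of definitions
  for (id in sample(ids, 12)) {
    for (p in setdiff(conceptParents(o1, id), root)) {
      expect_true(eqSubsumes(getDefinition(defs, id), getDefinition(defs, p),
                             sup$qualities, sup$entities))
    }
    # and ancestors are exactly the sampled strict subsumers
    anc <- setdiff(conceptAncestors(o1, id), root)
    subsumers <- ids[vapply(ids, function(j) j != id &&
      eqSubsumes(getDefinition(defs, id), getDefinition(defs, j),
                 sup$qualities, sup$entities), TRUE)]
    expect_setequal(anc, subsumers)
  }
})

test_that("full label sharing makes lexical matching recover the counterpart pairs", {
  cfg <- tinyCfg(5)
  pair <- generateSpeciesPair(cfg)
  seeds <- lexicalSeedPairs(pair$o1, pair$o2)
  expect_equal(nrow(seeds), nrow(pair$counterparts))
  expect_setequal(paste(seeds$left, seeds$right),
                  paste(pair$counterparts$o1, pair$counterparts$o2))
})

test_that("zero label sharing yields no lexical seeds; zero definitions no axioms", {
  cfg <- tinyCfg(6, fracSharedLabels = 0)
  pair <- generateSpeciesPair(cfg)
  expect_equal(nrow(lexicalSeedPairs(pair$o1, pair$o2)), 0L)
  cfg0 <- tinyCfg(6, fracDefined1 = 0)
  pair0 <- generateSpeciesPair(cfg0)
  sup <- generateSupportOntologies(cfg0)
  expect_length(pair0$defs1, 0L)
  expect_equal(nrow(formalAxioms(pair0$defs1, pair0$defs2,
                                 sup$qualities, sup$entities)), 0L)
})

test_that("no planted associations leaves the ROC stage without positives", {
  cfg <- tinyCfg(7, nTrueAssociations = 0L)
  bundle <- generateBundle(cfg)
  expect_equal(nrow(bundle$gold), 0L)
  map <- PhenoMapping("MP", "HP", "lexical",
                      setNames(as.list(bundle$counterparts$o1),
                               bundle$counterparts$o2))
  rp <- rankPairs(bundle$diseases, bundle$models, map,
                  "model_to_disease_space", bundle$orthology, bundle$gold)
  expect_error(rocAndAuc(rp), "at least one positive")
})

test_that("formal mapping coverage is at least the definition coverage", {
  for (s in 1:3) {
    rep <- runAll(presetConfig("paper-shaped", seed = s), evaluate = FALSE)
    t1 <- rep$table1
    expect_gte(t1$HP_count[4], t1$HP_count[2])  # mapped_formal >= defined
    expect_gte(t1$MP_count[4], t1$MP_count[2])
  }
})

test_that("mean AUC degrades monotonically with annotation noise", {
  noises <- c(0, 0.25, 0.5, 0.75, 1.0)
  seeds <- 1:20
  evalAuc <- function(seed, noise) {
    bundle <- generateBundle(tinyCfg(seed, noise = noise))
    seedsL <- lexicalSeedPairs(bundle$o1, bundle$o2)
    m <- buildMapping(bundle$o1, bundle$o2, seedsL, "2to1", "lexical")
    rp <- rankPairs(bundle$diseases, bundle$models, m,
                    "model_to_disease_space", bundle$orthology, bundle$gold)
    rocAndAuc(rp)$auc
  }
  means <- vapply(noises, function(no) {
    mean(vapply(seeds, evalAuc, 0, noise = no))
  }, 0)
  expect_true(all(diff(means) <= 0))
  expect_gte(means[5], 0.4)
  expect_lte(means[5], 0.6)
})

test_that("bundles survive a disk round-trip", {
  cfg <- tinyCfg(8)
  bundle <- generateBundle(cfg)
  d <- withr::local_tempdir()
  writeBundle(bundle, d)
  back <- readBundle(d)
  expect_equal(conceptIDs(back$o1), conceptIDs(bundle$o1))
  expect_equal(conceptLabels(back$o2), conceptLabels(bundle$o2))
  expect_equal(back$o1@parents, bundle$o1@parents)
  expect_equal(back$defs1@definitions, bundle$defs1@definitions,
               ignore_attr = TRUE)
  expect_equal(back$models, bundle$models)
  expect_equal(back$diseases, bundle$diseases)
  expect_equal(back$orthology, bundle$orthology)
  expect_equal(back$gold, bundle$gold)
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(manifest$config$seed, 8L)
  expect_length(manifest$checksums, 10L)
})
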