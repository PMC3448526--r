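# Merged-taxonomy closure, mapping construction and serialization.

twoChains <- function() {
  # o1: HP:c -> HP:b -> HP:a ; o2: MP:z -> MP:y -> MP:x
  list(
    o1 = makeOntology(list("HP:a" = character(0), "HP:b" = "HP:a",
                           "HP:c" = "HP:b")),
    o2 = makeOntology(list("MP:x" = character(0), "MP:y" = "MP:x",
                           "MP:z" = "MP:y"))
  )
}

test_that("reachability without axioms is ancestors-or-self within one ontology", {
  w <- twoChains()
  mc <- mergeAndClose(w$o1, w$o2, NULL)
  expect_setequal(reachableFrom(mc, "HP:c"), c("HP:c", "HP:b", "HP:a"))
  expect_setequal(reachableFrom(mc, "MP:x"), "MP:x")
})

test_that("equivalences bridge the ontologies in both directions", {
  w <- twoChains()
  eq <- data.frame(sub = "HP:b", kind = "equivalent", super = "MP:y")
  mc <- mergeAndClose(w$o1, w$o2, eq)
  expect_true(all(c("MP:y", "MP:x") %in% reachableFrom(mc, "HP:b")))
  # chain: c is_a b, b == y, y is_a x  =>  c reaches x
  expect_true("MP:x" %in% reachableFrom(mc, "HP:c"))
  expect_true("HP:a" %in% reachableFrom(mc, "MP:z"))
  expect_error(
    mergeAndClose(w$o1, w$o2,
                  data.frame(sub = "HP:b", kind = "equivalent", super = "MP:none")),
    "unknown or obsolete")
})

test_that("buildMapping extracts equivalent-and-super target concepts", {
  w <- twoChains()
  expect_length(buildMapping(w$o1, w$o2, NULL, "1to2", "lexical"), 0L)
  seeds <- data.frame(left = "HP:b", right = "MP:y", matched_on = "name-name")
  m <- buildMapping(w$o1, w$o2, seeds, "1to2", "lexical")
  # seeded concept and its descendants inherit the target plus its ancestors
  expect_equal(mappingEntries(m)[["HP:b"]], c("MP:x", "MP:y"))
  expect_equal(mappingEntries(m)[["HP:c"]], c("MP:x", "MP:y"))
  expect_false("HP:a" %in% mappedConcepts(m))
  # target-ontology roots can be dropped on request
  md <- buildMapping(w$o1, w$o2, seeds, "1to2", "lexical", dropRoots = TRUE)
  expect_equal(mappingEntries(md)[["HP:b"]], "MP:y")
})

test_that("mappings are not forced to be symmetric", {
  # HP:deep == MP:mid, so HP:deep maps up in MP, but MP:mid maps to HP:deep's
  # ancestors only through the equivalence - different set sizes by structure
  o1 <- makeOntology(list("HP:a" = character(0), "HP:deep" = "HP:a"))
  o2 <- makeOntology(list("MP:x" = character(0), "MP:mid" = "MP:x",
                          "MP:leaf" = "MP:mid"))
  seeds <- data.frame(left = "HP:deep", right = "MP:mid", matched_on = "name-name")
  m12 <- buildMapping(o1, o2, seeds, "1to2", "lexical")
  m21 <- buildMapping(o1, o2, seeds, "2to1", "lexical")
  expect_setequal(mappingEntries(m12)[["HP:deep"]], c("MP:mid", "MP:x"))
  expect_setequal(mappingEntries(m21)[["MP:mid"]], c("HP:deep", "HP:a"))
  expect_setequal(mappedConcepts(m21), c("MP:mid", "MP:leaf"))
})

test_that("entry sets are ancestor-closed in the target and monotone in axioms", {
  withr::with_seed(23, {
    for (rep in 1:6) {
      o1 <- randomDag(sample(8:25, 1), "HP")
      o2 <- randomDag(sample(8:25, 1), "MP")
      ids1 <- conceptIDs(o1); ids2 <- conceptIDs(o2)
      ax <- data.frame(
        sub = sample(ids1, 3),
        kind = sample(c("subclass", "equivalent"), 3, replace = TRUE),
        super = sample(ids2, 3), stringsAsFactors = FALSE)
      m <- buildMapping(o1, o2, ax, "1to2", "formal")
      for (c in mappedConcepts(m)) {
        ts <- mappingEntries(m)[[c]]
        for (t in ts) {
          expect_true(all(conceptAncestors(o2, t) %in% ts))
        }
      }
      # growing the axiom set never shrinks an entry
      m2 <- buildMapping(o1, o2, rbind(ax, data.frame(
        sub = sample(ids1, 1), kind = "equivalent",
        super = sample(ids2, 1))), "1to2", "formal")
      for (c in mappedConcepts(m)) {
        expect_true(all(mappingEntries(m)[[c]] %in% mappingEntries(m2)[[c]]))
      }
    }
  })
})

test_that("closure agrees with boolean matrix powering on random merged graphs", {
  withr::with_seed(29, {
    for (rep in 1:10) {
      n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
      o1 <- randomDag(n1, "HP"); o2 <- randomDag(n2, "MP")
      nAx <- sample(1:5, 1)
      ax <- data.frame(
        sub = sample(conceptIDs(o1), nAx, replace = TRUE),
        kind = sample(c("subclass", "equivalent"), nAx, replace = TRUE),
        super = sample(conceptIDs(o2), nAx, replace = TRUE),
        stringsAsFactors = FALSE)
      mc <- mergeAndClose(o1, o2, ax)
      nodes <- c(conceptIDs(o1), conceptIDs(o2))
      R <- oracleClosure(nodes, mergedEdges(o1, o2, ax))
      for (x in sample(nodes, 6)) {
        expect_setequal(reachableFrom(mc, x), nodes[R[x, ]])
      }
      m <- buildMapping(o1, o2, ax, "1to2", "formal")
      for (c in conceptIDs(o1)) {
        want <- intersect(nodes[R[c, ]], conceptIDs(o2))
        if (length(want)) {
          expect_equal(mappingEntries(m)[[c]], sort(want))
        } else {
          expect_false(c %in% mappedConcepts(m))
        }
      }
    }
  })
})

test_that("mapping records serialize to the whitespace-separated line format", {
  o1 <- makeOntology(list("HP:0007062" = character(0)))
  o2 <- makeOntology(list(
    "MP:0000001" = character(0), "MP:0002106" = "MP:0000001",
    "MP:0004142" = "MP:0002106", "MP:0004143" = "MP:0002106",
    "MP:0005369" = "MP:0000001"))
  seeds <- data.frame(
    left = "HP:0007062",
    right = c("MP:0004142", "MP:0004143", "MP:0005369"),
    matched_on = "name-name")
  m <- buildMapping(o1, o2, seeds, "1to2", "lexical")
  expect_equal(
    writeMapping(m),
    "HP:0007062 MP:0000001 MP:0002106 MP:0004142 MP:0004143 MP:0005369")
  back <- readMapping(writeMapping(m), method = "lexical")
  expect_equal(mappingEntries(back), mappingEntries(m))
})

test_that("readMapping parses the single-pair record form and flags bad lines", {
  m <- readMapping("HP:0002249 MP:0003292", method = "lexical")
  expect_equal(mappingEntries(m), list("HP:0002249" = "MP:0003292"))
  expect_equal(mappingDirection(m), "HP->MP")
  expect_error(readMapping("HP:0002249", method = "lexical"), "line 1")
  empty <- readMapping(character(0), method = "formal",
                       sourcePrefix = "HP", targetPrefix = "MP")
  expect_length(empty, 0L)
})

test_that("write/parse round-trips canonicalize random mappings", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- sample(3:10, 1)
      entries <- lapply(seq_len(n), function(i)
        sprintf("MP:%04d", sample.int(50, sample(1:6, 1))))
      names(entries) <- sprintf("HP:%04d", sample.int(99, n))
      m <- PhenoMapping("HP", "MP", "lexical", entries)
      f <- withr::local_tempfile()
      writeMapping(m, f)
      back <- readMapping(f, method = "lexical")
      expect_equal(mappingEntries(back),
                   mappingEntries(m)[order(names(mappingEntries(m)))])
    }
  })
})
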