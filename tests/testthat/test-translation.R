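# Annotation translation, cosine similarity, ranking and pooled ROC/AUC.

test_that("translateAnnotations unions entry sets and tolerates unmapped concepts", {
  m <- PhenoMapping("MP", "HP", "lexical",
                    list("MP:1" = c("HP:1", "HP:2"),
                         "MP:2" = c("HP:2", "HP:3")))
  expect_equal(translateAnnotations(c("MP:9", "MP:8"), m), character(0))
  expect_equal(translateAnnotations("MP:1", m), c("HP:1", "HP:2"))
  expect_equal(translateAnnotations(c("MP:1", "MP:2"), m),
               c("HP:1", "HP:2", "HP:3"))
  expect_error(translateAnnotations("HP:1", m), "source prefix")
})

test_that("cosine similarity reduces to the binary-vector form", {
  expect_equal(cosineSimilarity(c("MP:1", "MP:2"), c("MP:1", "MP:2")), 1.0)
  expect_equal(cosineSimilarity(c("MP:1"), c("MP:2")), 0.0)
  expect_equal(cosineSimilarity(c("MP:p", "MP:q"), c("MP:q", "MP:r")), 0.5)
  expect_equal(cosineSimilarity(character(0), c("MP:1")), 0)
  expect_error(cosineSimilarity("HP:1", "MP:1"), "different ontologies")
  # symmetric and bounded
  withr::with_seed(41, {
    u <- sprintf("MP:%03d", 1:12)
    for (rep in 1:20) {
      a <- sample(u, sample(1:8, 1)); b <- sample(u, sample(1:8, 1))
      s <- cosineSimilarity(a, b)
      expect_equal(s, cosineSimilarity(b, a))
      expect_gte(s, 0); expect_lte(s, 1)
      expect_equal(s == 1, setequal(a, b))
      expect_equal(s == 0, length(intersect(a, b)) == 0)
    }
  })
})

mkEvalFixture <- function() {
  list(
    mapping = PhenoMapping("MP", "HP", "lexical",
                           list("MP:1" = "HP:1", "MP:2" = "HP:2",
                                "MP:3" = c("HP:3", "HP:4"))),
    diseases = data.frame(
      disease_id = c("D1", "D1", "D2"),
      concept_id = c("HP:1", "HP:2", "HP:3")),
    models = data.frame(
      model_id = c("M1", "M1", "M2"),
      gene_id = c("G1", "G1", "G2"),
      concept_id = c("MP:1", "MP:2", "MP:3")),
    orthology = data.frame(mouse_gene = "G1", human_gene = "HG1"),
    gold = data.frame(human_gene = "HG1", disease_id = "D1")
  )
}

test_that("rankPairs scores every combination and labels via orthology and gold", {
  fx <- mkEvalFixture()
  rp <- rankPairs(fx$diseases, fx$models, fx$mapping, "model_to_disease_space",
                  fx$orthology, fx$gold)
  expect_equal(nrow(rp), 4L)
  expect_equal(rp$similarity, sort(rp$similarity, decreasing = TRUE))
  # (D1, M1): translated {HP:1, HP:2} vs {HP:1, HP:2} -> 1, positive
  top <- rp[1, ]
  expect_equal(top$disease, "D1"); expect_equal(top$model, "M1")
  expect_equal(top$similarity, 1.0)
  expect_true(top$positive)
  # G2 has no human ortholog: always negative
  expect_false(any(rp$positive[rp$gene == "G2"]))
  # scenario/mapping mismatch is a usage error
  expect_error(rankPairs(fx$diseases, fx$models, fx$mapping,
                         "disease_to_model_space", fx$orthology, fx$gold),
               "needs a HP -> MP mapping")
})

test_that("rank ties break deterministically on (disease, model)", {
  d <- data.frame(disease_id = c("D1", "D2"), concept_id = c("HP:1", "HP:1"))
  m <- data.frame(model_id = c("M1", "M2"), gene_id = c("G1", "G2"),
                  concept_id = c("MP:1", "MP:1"))
  map <- PhenoMapping("MP", "HP", "lexical", list("MP:1" = "HP:1"))
  orth <- data.frame(mouse_gene = "G1", human_gene = "HG1")
  gold <- data.frame(human_gene = "HG1", disease_id = "D1")
  rp <- rankPairs(d, m, map, "model_to_disease_space", orth, gold)
  expect_equal(paste(rp$disease, rp$model),
               c("D1 M1", "D1 M2", "D2 M1", "D2 M2"))
})

test_that("pooled ROC follows the block-tie convention", {
  perfect <- data.frame(similarity = c(0.9, 0.8, 0.2, 0.1),
                        positive = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rocAndAuc(perfect)$auc, 1.0)
  tied <- data.frame(similarity = rep(0.5, 6),
                     positive = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  roc <- rocAndAuc(tied)
  expect_equal(roc$auc, 0.5)
  expect_equal(roc$points, data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  four <- data.frame(similarity = c(0.9, 0.8, 0.7, 0.1),
                     positive = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rocAndAuc(four)$auc, 0.75)
  expect_equal(rocAndAuc(four)$auc,
               oracleAuc(four$similarity, four$positive))
  expect_error(rocAndAuc(data.frame(similarity = 1, positive = TRUE)),
               "at least one positive and one negative")
})

test_that("ROC curves start at (0,0), end at (1,1) and are monotone", {
  withr::with_seed(43, {
    for (rep in 1:15) {
      n <- sample(5:200, 1)
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
      labels <- runif(n) < 0.4
      if (!any(labels) || all(labels)) next
      roc <- rocAndAuc(data.frame(similarity = scores, positive = labels))
      pts <- roc$points
      expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
      expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
      expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
      # trapezoidal AUC equals Mann-Whitney concordance
      expect_equal(roc$auc, oracleAuc(scores, labels))
    }
  })
})

test_that("AUC agrees with pROC on tied and untied rankings", {
  skip_if_not_installed("pROC")
  withr::with_seed(47, {
    for (rep in 1:5) {
      n <- 60
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      labels <- runif(n) < 0.5
      if (!any(labels) || all(labels)) next
      got <- rocAndAuc(data.frame(similarity = scores, positive = labels))$auc
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = labels, predictor = scores,
        direction = "<", quiet = TRUE)))
      expect_equal(got, ref)
    }
  })
})

test_that("growing the mapping entrywise never decreases pair similarity overlap", {
  withr::with_seed(53, {
    hp <- sprintf("HP:%03d", 1:15); mp <- sprintf("MP:%03d", 1:15)
    for (rep in 1:10) {
      e1 <- lapply(1:6, function(i) sample(hp, sample(1:4, 1)))
      names(e1) <- sample(mp, 6)
      m1 <- PhenoMapping("MP", "HP", "lexical", e1)
      # superset mapping: add targets and a new entry
      e2 <- lapply(e1, function(v) union(v, sample(hp, 1)))
      e2[[sample(setdiff(mp, names(e1)), 1)]] <- sample(hp, 2)
      m2 <- PhenoMapping("MP", "HP", "lexical", e2)
      ann <- sample(mp, 5)
      ref <- sample(hp, 6)
      expect_true(all(translateAnnotations(ann, m1) %in%
                      translateAnnotations(ann, m2)))
      expect_lte(length(intersect(translateAnnotations(ann, m1), ref)),
                 length(intersect(translateAnnotations(ann, m2), ref)))
    }
  })
})
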