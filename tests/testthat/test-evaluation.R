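test_that("confusion counts partition samples and give the stated rates", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6), 0.5)
  expect_equal(cc[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L), ignore_attr = TRUE)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 4L)

  all_pos <- confusionCounts(rep(1, 5), rep(0.9, 5), 0.5)
  expect_equal(c(all_pos$FN, all_pos$FP, all_pos$TN), c(0L, 0L, 0L))

  # FPR = FP / (TN + FP)
  cc2 <- confusionCounts(c(0, 0, 0, 0, 1), c(0.8, 0.1, 0.2, 0.3, 0.9), 0.5)
  expect_equal(falsePositiveRate(cc2), 1 / 4)
  expect_equal(truePositiveRate(cc2), 1)
  expect_error(confusionCounts(c(1, 0), 0.5), "labels but")
})

test_that("rank-based AUC equals known values and handles edge cases", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0.0)
  # 3 of 4 positive-negative pairs concordant
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.85)), 0.75)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "AUC undefined")
})

test_that("rank-based AUC equals the O(n^2) pairwise-concordance oracle", {
  withr::with_seed(123, {
    for (i in 1:500) {
      n <- sample(4:40, 1)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      # discretized scores force ties regularly
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      expect_equal(rocAuc(labels, scores), pairwiseAuc(labels, scores),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC is antisymmetric under score negation for tie-free scores", {
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(6:50, 1)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- runif(n)
      expect_equal(rocAuc(labels, scores) + rocAuc(labels, -scores), 1)
    }
  })
})

test_that("uniform random scores on balanced labels average AUC 0.50", {
  aucs <- vapply(0:199, function(s) {
    withr::with_seed(s, rocAuc(c(rep(1, 100), rep(0, 100)), runif(200)))
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("stratified folds preserve class proportions and partition the data", {
  labels <- c(rep(1, 215), rep(0, 215))
  folds <- stratifiedFolds(labels, 10, seed = 4)
  expect_equal(sort(unique(folds)), 1:10)
  for (f in 1:10) {
    expect_equal(sum(folds == f), 43)
    expect_true(abs(sum(labels[folds == f]) - 21.5) <= 0.5)
  }
  # unbalanced label counts stay within one sample of proportional
  labels2 <- c(rep(1, 33), rep(0, 47))
  folds2 <- stratifiedFolds(labels2, 5, seed = 4)
  per_fold_pos <- vapply(1:5, function(f) sum(labels2[folds2 == f]), 0)
  expect_true(all(abs(per_fold_pos - 33 / 5) <= 1))

  expect_error(stratifiedFolds(c(rep(1, 3), rep(0, 50)), 5, seed = 1),
               "fewer than k")
})

test_that("stratified split holds out the ceiling of the test fraction per class", {
  labels <- c(rep(1, 39), rep(0, 39))
  sp <- stratifiedSplit(labels, train_frac = 0.7, seed = 2)
  expect_equal(length(sp$test), 24)  # ceiling(0.3 * 39) per class
  expect_equal(sum(labels[sp$test]), 12)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
})

test_that("cross-validation folds cover the data exactly once and CV is reproducible", {
  sim <- separableFeatures(n_per_class = 30, dim = 16, seed = 41)
  cfg <- classifierConfig("dnn", epochs = 5, seed = 41)
  cv1 <- stratifiedKfoldCV(sim$features, sim$labels, k = 5, cfg, seed = 41)
  cv2 <- stratifiedKfoldCV(sim$features, sim$labels, k = 5, cfg, seed = 41)
  expect_identical(perUnitAuc(cv1), perUnitAuc(cv2))
  expect_equal(meanAuc(cv1), mean(perUnitAuc(cv1)), tolerance = 1e-15)
  expect_equal(sum(vapply(cv1@details, function(d) d$n_test, 0)), 60)
})

test_that("the disjoint-negative protocol enforces its preconditions and runs all repetitions", {
  sim <- simulateLabeledFeatures(simConfig(10, 30, embedding_separation = 6,
                                           embedding_dim = 16, seed = 43))
  X <- featureMatrix(sim$features)
  g <- geneSymbols(sim$features)
  pos <- FeatureBlock("pos", g[1:10], X[1:10, ])
  negs <- lapply(0:2, function(i) {
    idx <- 11 + i * 10 + 0:9
    FeatureBlock(paste0("neg", i), g[idx], X[idx, ])
  })
  res <- disjointNegativeProtocol(pos, negs,
                                  classifierConfig("dnn", epochs = 5,
                                                   seed = 43), seed = 43)
  expect_length(perUnitAuc(res), 3)
  expect_equal(res@protocol, "disjoint_negative")

  overlapping <- c(negs[1:2], list(FeatureBlock("dup", g[c(11, 31:39)],
                                                X[c(11, 31:39), ])))
  expect_error(disjointNegativeProtocol(pos, overlapping,
                                        classifierConfig("dnn", epochs = 2)),
               "overlap")
  short <- list(FeatureBlock("s", g[21:25], X[21:25, ]))
  expect_error(disjointNegativeProtocol(pos, short,
                                        classifierConfig("dnn", epochs = 2)),
               "10 genes")
})

test_that("Y-randomization separates informative data from noise", {
  sim <- separableFeatures(n_per_class = 60, dim = 59, seed = 11)
  yr <- yRandomization(sim$features, sim$labels,
                       classifierConfig("dnn", epochs = 10, seed = 11),
                       n_perm = 30, seed = 11)
  expect_gt(yr@originalR2, max(yr@permutedR2))
  expect_lt(pValue(yr), 0.05)
  expect_gt(sum(yr@permutedR2 < 0), 0)
  # empirical p-value formula holds exactly
  expect_equal(pValue(yr),
               (1 + sum(yr@permutedR2 >= yr@originalR2)) / (1 + 30))

  noise <- noiseFeatures(n_per_class = 30, dim = 16, seed = 12)
  yr0 <- yRandomization(noise$features, noise$labels,
                        classifierConfig("dnn", epochs = 5, seed = 12),
                        n_perm = 30, seed = 12)
  expect_gte(pValue(yr0), 0.05)
  expect_error(yRandomization(sim$features, sim$labels, n_perm = 0), "n_perm")
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(rocAuc(labels, scores), ref, tolerance = 1e-12)
    }
  })
})
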