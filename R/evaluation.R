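#' Confusion counts at a score threshold
#'
#' A score at or above the threshold predicts the positive class. The four
#' counts partition the evaluated samples; the derived rates are
#' `FPR = FP / (TN + FP)` and `TPR = TP / (TP + FN)`.
#'
#' @param labels Binary vector of true labels (0/1).
#' @param scores Numeric scores, same length.
#' @param threshold Decision threshold in \[0, 1\]; default 0.5.
#' @return A list of class `ConfusionCounts` with elements TP, FP, TN, FN.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6))
#' @export
confusionCounts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop(sprintf("%d labels but %d scores", length(labels), length(scores)))
  }
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1L),
                 FP = sum(pred == 1L & labels == 0L),
                 TN = sum(pred == 0L & labels == 0L),
                 FN = sum(pred == 0L & labels == 1L)),
            class = "ConfusionCounts")
}

#' @rdname confusionCounts
#' @param counts A `ConfusionCounts` object.
#' @export
falsePositiveRate <- function(counts) counts$FP / (counts$TN + counts$FP)

#' @rdname confusionCounts
#' @export
truePositiveRate <- function(counts) counts$TP / (counts$TP + counts$FN)

#' Area under the ROC curve
#'
#' AUC of the ROC curve swept over all score thresholds, computed through the
#' rank (Mann-Whitney) statistic with midranks for ties — identical to the
#' trapezoidal area under the (FPR, TPR) curve and to the probability that a
#' random positive outranks a random negative, ties counted one half.
#'
#' @param labels Binary vector (0/1); both classes must be present.
#' @param scores Numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.85))
#' @export
rocAuc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop(sprintf("%d labels but %d scores", length(labels), length(scores)))
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: both classes must be present")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that every fold's class
#' proportions match the global proportions within one sample per class.
#'
#' @param labels Binary vector (0/1).
#' @param k Number of folds; every class must have at least `k` members.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  folds <- integer(length(labels))
  offset <- 0L
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop(sprintf("class %d has %d members, fewer than k = %d folds",
                   cls, length(idx), k))
    }
    shuffled <- withr::with_seed(deriveSeed(seed, paste0("fold-class-", cls)),
                                 sample(idx))
    # rotate the cycle per class so the leftover samples of successive
    # classes land in different folds and total fold sizes stay within one
    folds[shuffled] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds
}

#' Stratified train/test split
#'
#' Per class, `ceiling((1 - train_frac) * n_class)` samples go to the test
#' set, keeping the class-label distribution of both portions within one
#' sample of the global one.
#'
#' @param labels Binary vector (0/1).
#' @param train_frac Fraction of each class used for training (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, train_frac = 0.7, seed = 1L) {
  labels <- as.integer(labels)
  test_idx <- integer()
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    n_test <- ceiling((1 - train_frac) * length(idx))
    if (n_test < 1L || n_test >= length(idx)) {
      stop(sprintf("class %d cannot be split at train_frac = %g", cls, train_frac))
    }
    test_idx <- c(test_idx,
                  withr::with_seed(deriveSeed(seed, paste0("split-class-", cls)),
                                   sample(idx, n_test)))
  }
  list(train = setdiff(seq_along(labels), test_idx), test = sort(test_idx))
}

.evalResult <- function(protocol, aucs, seeds, details) {
  methods::new("EvalResult", protocol = protocol, perUnitAuc = aucs,
               meanAuc = mean(aucs), seeds = as.numeric(seeds),
               details = details)
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `k` stratified folds, and for each fold trains the
#' configured classifier on the other `k - 1` folds and scores the held-out
#' fold. When `normalize` is `TRUE` (the default), min-max scaling is fitted
#' on the training rows of each fold and merely applied to the test rows, so
#' no information leaks from test to train. Per-fold model seeds derive from
#' the fold index, making the whole procedure reproducible.
#'
#' @param features [FeatureBlock-class] or numeric matrix.
#' @param labels Binary labels (0/1), one per row.
#' @param k Number of folds (default 10).
#' @param config [classifierConfig()] used for every fold.
#' @param seed Seed controlling the fold assignment.
#' @param normalize Fit a min-max scaler on each fold's training rows.
#' @return An [EvalResult-class] with `protocol = "kfold"`: per-fold AUCs and
#'   their mean.
#' @export
stratifiedKfoldCV <- function(features, labels, k = 10L,
                              config = classifierConfig(), seed = 1L,
                              normalize = TRUE) {
  X <- .featuresToMatrix(features)
  labels <- as.integer(labels)
  folds <- stratifiedFolds(labels, k, seed)
  aucs <- numeric(k)
  details <- vector("list", k)
  fold_seeds <- numeric(k)
  for (i in seq_len(k)) {
    test <- which(folds == i)
    train <- which(folds != i)
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (normalize) {
      norm <- minmaxNormalize(X, fit_rows = train)
      scaled <- featureMatrix(norm$block)
      Xtr <- scaled[train, , drop = FALSE]
      Xte <- scaled[test, , drop = FALSE]
    }
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, paste0("cv-fold-", i))
    fold_seeds[i] <- cfg$seed
    fit <- trainClassifier(Xtr, labels[train], cfg)
    scores <- predictScores(fit, Xte)
    aucs[i] <- rocAuc(labels[test], scores)
    details[[i]] <- list(n_test = length(test),
                         confusion = confusionCounts(labels[test], scores,
                                                     config$threshold))
  }
  .evalResult("kfold", aucs, fold_seeds, details)
}

#' Disjoint-negative-set evaluation protocol
#'
#' Baseline-comparison protocol: ten (in general, `length(negative_sets)`)
#' pairwise-disjoint negative gene sets, each the size of the single positive
#' set. Each repetition combines the positives with one negative set,
#' stratified-splits it 70/30 into train and test, trains the classifier and
#' records the test AUC; the per-repetition AUCs are averaged.
#'
#' @param positives [FeatureBlock-class] of the positive genes.
#' @param negative_sets List of [FeatureBlock-class] objects, pairwise
#'   disjoint by gene symbol, each with as many genes as `positives`.
#' @param config [classifierConfig()].
#' @param split Training fraction (default 0.7).
#' @param seed Seed; per-repetition split and model seeds derive from it.
#' @param normalize Fit min-max scaling on training rows per repetition.
#' @return An [EvalResult-class] with `protocol = "disjoint_negative"`.
#' @export
disjointNegativeProtocol <- function(positives, negative_sets,
                                     config = classifierConfig(), split = 0.7,
                                     seed = 1L, normalize = TRUE) {
  n_pos <- length(geneSymbols(positives))
  all_neg <- unlist(lapply(negative_sets, geneSymbols), use.names = FALSE)
  if (anyDuplicated(all_neg)) {
    stop("negative sets overlap: ",
         paste(utils::head(unique(all_neg[duplicated(all_neg)]), 5L),
               collapse = ", "))
  }
  sizes <- vapply(negative_sets, function(b) length(geneSymbols(b)), 1L)
  if (any(sizes != n_pos)) {
    stop(sprintf("every negative set must have %d genes (found: %s)", n_pos,
                 paste(sizes, collapse = ", ")))
  }
  n_rep <- length(negative_sets)
  aucs <- numeric(n_rep)
  rep_seeds <- numeric(n_rep)
  details <- vector("list", n_rep)
  Xpos <- .featuresToMatrix(positives)
  for (i in seq_len(n_rep)) {
    X <- rbind(Xpos, .featuresToMatrix(negative_sets[[i]]))
    y <- c(rep(1L, n_pos), rep(0L, n_pos))
    sp <- stratifiedSplit(y, train_frac = split,
                          seed = deriveSeed(seed, paste0("rep-", i)))
    Xtr <- X[sp$train, , drop = FALSE]
    Xte <- X[sp$test, , drop = FALSE]
    if (normalize) {
      norm <- minmaxNormalize(X, fit_rows = sp$train)
      scaled <- featureMatrix(norm$block)
      Xtr <- scaled[sp$train, , drop = FALSE]
      Xte <- scaled[sp$test, , drop = FALSE]
    }
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, paste0("rep-", i))
    rep_seeds[i] <- cfg$seed
    fit <- trainClassifier(Xtr, y[sp$train], cfg)
    scores <- predictScores(fit, Xte)
    aucs[i] <- rocAuc(y[sp$test], scores)
    details[[i]] <- list(n_test = length(sp$test),
                         negatives_used = geneSymbols(negative_sets[[i]]))
  }
  .evalResult("disjoint_negative", aucs, rep_seeds, details)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; negative whenever the predictions fit worse than the
#' constant mean predictor.
#'
#' @param observed Numeric vector (here: binary test labels).
#' @param predicted Numeric vector of predicted scores.
#' @return R-squared value (at most 1, unbounded below).
#' @export
rSquared <- function(observed, predicted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R-squared undefined: observed values are constant")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Y-randomization (label permutation) model validation
#'
#' Tests whether model performance could arise by chance: the feature vectors
#' are held fixed while the labels are shuffled, the model is retrained on
#' each shuffled dataset, and its held-out R-squared is compared with that of
#' the model trained on the true labels. A dataset/split is made once
#' (stratified 70/30 by default); the original model's R-squared is computed
#' on the held-out labels, and each of `n_perm` permutations shuffles the full
#' label vector before training and is evaluated against its own permuted
#' held-out labels. Shuffled models typically score low or negative
#' R-squared. The empirical p-value is `(1 + b) / (1 + n_perm)` with `b` the
#' number of permuted R-squared values at or above the original — exact under
#' exchangeability.
#'
#' @param features [FeatureBlock-class] or numeric matrix.
#' @param labels Binary labels (0/1).
#' @param config [classifierConfig()].
#' @param n_perm Number of label permutations (default 100).
#' @param seed Seed for the split and the permutations.
#' @param split Training fraction for the internal split (default 0.7).
#' @param normalize Fit min-max scaling on the training rows.
#' @return A [YRandResult-class].
#' @export
yRandomization <- function(features, labels, config = classifierConfig(),
                           n_perm = 100L, seed = 1L, split = 0.7,
                           normalize = TRUE) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  X <- .featuresToMatrix(features)
  labels <- as.integer(labels)
  sp <- stratifiedSplit(labels, train_frac = split,
                        seed = deriveSeed(seed, "yrand-split"))
  if (normalize) {
    X <- featureMatrix(minmaxNormalize(X, fit_rows = sp$train)$block)
  }
  Xtr <- X[sp$train, , drop = FALSE]
  Xte <- X[sp$test, , drop = FALSE]

  fitEval <- function(y, model_seed) {
    cfg <- config
    cfg$seed <- model_seed
    fit <- trainClassifier(Xtr, y[sp$train], cfg)
    rSquared(y[sp$test], predictScores(fit, Xte))
  }
  original <- fitEval(labels, deriveSeed(config$seed, "yrand-original"))
  permuted <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    y_perm <- withr::with_seed(deriveSeed(seed, paste0("yrand-perm-", i)),
                               sample(labels))
    # a permutation may put a single class into train or test; redraw if so
    tries <- 0L
    while ((length(unique(y_perm[sp$train])) < 2L ||
            length(unique(y_perm[sp$test])) < 2L) && tries < 100L) {
      tries <- tries + 1L
      y_perm <- withr::with_seed(
        deriveSeed(seed, paste0("yrand-perm-", i, "-retry-", tries)),
        sample(labels))
    }
    permuted[i] <- fitEval(y_perm, deriveSeed(config$seed,
                                              paste0("yrand-model-", i)))
  }
  methods::new("YRandResult", originalR2 = original, permutedR2 = permuted,
               pValue = (1 + sum(permuted >= original)) / (1 + n_perm),
               seed = as.numeric(seed))
}
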