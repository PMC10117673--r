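#' CancerDataset: a balanced labeled gene collection for one cancer type
#'
#' Container for the per-cancer classification dataset: an equal number of
#' target (label 1) and non-target (label 0) genes with no symbol shared
#' between the classes. Balance matters because the downstream classifiers
#' are trained without class weighting; it gives both classes equal priority.
#'
#' @slot cancerType Single non-empty string; the ten canonical types are
#'   listed by [cancerTypes()] but synthetic datasets may use any name.
#' @slot geneData data.frame of gene records (columns symbol, protein_id,
#'   sequence, label, reviewed).
#' @seealso [assembleDataset()], [positives()], [negatives()]
#' @export
setClass("CancerDataset",
         representation(cancerType = "character", geneData = "data.frame"))

setValidity("CancerDataset", function(object) {
  msg <- character()
  if (length(object@cancerType) != 1L || is.na(object@cancerType) ||
      !nzchar(object@cancerType)) {
    msg <- c(msg, "cancerType must be a single non-empty string")
  }
  gd <- object@geneData
  missing_cols <- setdiff(.geneRecordColumns, names(gd))
  if (length(missing_cols)) {
    return(paste("geneData lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(gd$symbol)) || any(!nzchar(gd$symbol))) {
    msg <- c(msg, "gene symbols must be non-empty")
  }
  if (anyDuplicated(gd$symbol)) {
    msg <- c(msg, "gene symbols must be unique within a dataset (positives and negatives disjoint)")
  }
  if (!all(gd$label %in% c(0L, 1L))) {
    msg <- c(msg, "labels must be 0 or 1")
  }
  n_pos <- sum(gd$label == 1L)
  n_neg <- sum(gd$label == 0L)
  if (n_pos != n_neg) {
    msg <- c(msg, sprintf("dataset is imbalanced: %d positives vs %d negatives",
                          n_pos, n_neg))
  }
  has_seq <- !is.na(gd$sequence)
  if (any(has_seq & nchar(gd$sequence) < 1L)) {
    msg <- c(msg, "present sequences must have length >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureBlock: a named gene-by-feature numeric matrix
#'
#' One feature source for a set of genes. The canonical blocks are
#' `"embedding"` (1,024 columns, per-protein sequence embeddings), `"omics"`
#' (5 columns: max/mean/median/min expression plus mutation count) and
#' `"integrated"` (1,029 = 1,024 + 5 columns, embeddings first). Other names
#' carry no dimensionality constraint and are used for reduced-dimension
#' synthetic blocks.
#'
#' @slot name Block name.
#' @slot genes Ordered gene symbols; row i of `matrix` is gene i.
#' @slot matrix Numeric matrix, all entries finite.
#' @seealso [FeatureBlock()], [integrateFeatures()], [minmaxNormalize()]
#' @export
setClass("FeatureBlock",
         representation(name = "character", genes = "character",
                        matrix = "matrix"))

.canonicalBlockDims <- c(embedding = 1024L, omics = 5L, integrated = 1029L)

setValidity("FeatureBlock", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name)) {
    msg <- c(msg, "name must be a single non-empty string")
  }
  m <- object@matrix
  if (!is.numeric(m)) {
    msg <- c(msg, "matrix must be numeric")
  } else {
    if (nrow(m) != length(object@genes)) {
      msg <- c(msg, sprintf("matrix has %d rows but %d genes", nrow(m),
                            length(object@genes)))
    }
    bad <- which(!apply(m, 2L, function(col) all(is.finite(col))))
    if (length(bad)) {
      msg <- c(msg, paste("non-finite entries in column(s):",
                          paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  if (anyDuplicated(object@genes)) {
    msg <- c(msg, "gene symbols must be unique")
  }
  want <- .canonicalBlockDims[object@name]
  if (!is.na(want) && ncol(m) != want) {
    msg <- c(msg, sprintf("block '%s' must have %d columns, found %d",
                          object@name, want, ncol(m)))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureBlock
#'
#' @param name Block name; `"embedding"`, `"omics"` and `"integrated"` enforce
#'   1024, 5 and 1029 columns respectively.
#' @param genes Character vector of gene symbols, one per matrix row.
#' @param matrix Numeric matrix of features.
#' @return A [FeatureBlock-class] object.
#' @export
FeatureBlock <- function(name, genes, matrix) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  rownames(matrix) <- genes
  methods::new("FeatureBlock", name = name, genes = as.character(genes),
               matrix = matrix)
}

#' EmbeddingBackend: pluggable per-protein sequence embedders
#'
#' Virtual parent of sequence-embedding backends. A backend maps one
#' amino-acid sequence to a fixed-length numeric vector and must be
#' deterministic at inference (identical sequence, identical vector). The
#' reference protein-language-model backend produces 1,024-dimensional
#' vectors (mean over token positions of the final hidden states); since such
#' a model runs outside this package, embeddings computed elsewhere are
#' consumed via [CachedEmbedder-class] and offline work uses
#' [MockEmbedder-class].
#'
#' @slot name Backend name.
#' @slot dimension Embedding dimension (1,024 for the reference backend).
#' @slot maxTokens Maximum residues embedded; longer sequences are truncated
#'   with a warning.
#' @export
setClass("EmbeddingBackend",
         representation("VIRTUAL", name = "character", dimension = "integer",
                        maxTokens = "integer"))

setValidity("EmbeddingBackend", function(object) {
  if (length(object@dimension) != 1L || object@dimension < 1L) {
    return("dimension must be a positive integer")
  }
  if (length(object@maxTokens) != 1L || object@maxTokens < 1L) {
    return("maxTokens must be a positive integer")
  }
  TRUE
})

#' MockEmbedder: deterministic hash-seeded embedding backend
#'
#' Offline stand-in backend for testing the embedding pipeline end-to-end.
#' Each sequence is embedded as `dimension` standard-normal draws from an RNG
#' seeded by a stable hash of the (truncated) sequence string, so identical
#' sequences always embed identically and distinct sequences get effectively
#' independent vectors.
#'
#' @seealso [MockEmbedder()], [embedSequences()]
#' @export
setClass("MockEmbedder", contains = "EmbeddingBackend")

#' @rdname MockEmbedder-class
#' @param dimension Embedding dimension; defaults to the reference backend's
#'   1,024.
#' @param maxTokens Truncation length in residues; default 2,000, the longest
#'   training length of the reference protein language model.
#' @return A MockEmbedder object.
#' @export
MockEmbedder <- function(dimension = 1024L, maxTokens = 2000L) {
  methods::new("MockEmbedder", name = "mock",
               dimension = as.integer(dimension),
               maxTokens = as.integer(maxTokens))
}

#' CachedEmbedder: embeddings precomputed by an external model
#'
#' Serves per-gene embedding vectors from a numeric matrix computed once by an
#' external protein language model and cached to disk (rows keyed by gene
#' symbol). Lookup is by symbol; a symbol absent from the cache is an error.
#'
#' @slot table Numeric matrix, rownames = gene symbols.
#' @seealso [CachedEmbedder()], [readEmbeddingCache()]
#' @export
setClass("CachedEmbedder", contains = "EmbeddingBackend",
         representation(table = "matrix"))

#' @rdname CachedEmbedder-class
#' @param table Numeric matrix with gene symbols as rownames.
#' @param maxTokens Truncation length recorded for provenance (the cache
#'   producer's limit); default 2,000.
#' @return A CachedEmbedder object.
#' @export
CachedEmbedder <- function(table, maxTokens = 2000L) {
  table <- as.matrix(table)
  storage.mode(table) <- "double"
  if (is.null(rownames(table))) stop("embedding cache must have gene-symbol rownames")
  methods::new("CachedEmbedder", name = "cached",
               dimension = ncol(table), maxTokens = as.integer(maxTokens),
               table = table)
}

#' TrainedModel: a fitted classifier with its training provenance
#'
#' @slot kind One of "dnn", "random_forest", "gradient_boosting", "svm".
#' @slot config The [classifierConfig()] list used for training.
#' @slot fit Opaque fitted parameters (for the DNN: layer weight list).
#' @slot featureDimension Number of feature columns the model accepts.
#' @slot trainingManifest List: n_samples, class counts, seed.
#' @slot lossHistory Per-epoch training loss (DNN only; empty otherwise).
#' @seealso [trainClassifier()], [predictScores()], [saveModel()]
#' @export
setClass("TrainedModel",
         representation(kind = "character", config = "list", fit = "ANY",
                        featureDimension = "integer",
                        trainingManifest = "list", lossHistory = "numeric"))

#' EvalResult: per-fold or per-repetition AUCs and their mean
#'
#' @slot protocol "kfold" or "disjoint_negative".
#' @slot perUnitAuc AUC per fold / repetition, each in \[0, 1\].
#' @slot meanAuc Arithmetic mean of `perUnitAuc`.
#' @slot seeds Seeds used per unit.
#' @slot details List of per-unit confusion counts and sizes.
#' @export
setClass("EvalResult",
         representation(protocol = "character", perUnitAuc = "numeric",
                        meanAuc = "numeric", seeds = "numeric",
                        details = "list"))

setValidity("EvalResult", function(object) {
  msg <- character()
  if (!object@protocol %in% c("kfold", "disjoint_negative")) {
    msg <- c(msg, "protocol must be 'kfold' or 'disjoint_negative'")
  }
  if (any(object@perUnitAuc < 0 | object@perUnitAuc > 1)) {
    msg <- c(msg, "AUCs must lie in [0, 1]")
  }
  if (abs(object@meanAuc - mean(object@perUnitAuc)) > 1e-12) {
    msg <- c(msg, "meanAuc must equal mean(perUnitAuc) within 1e-12")
  }
  if (length(msg)) msg else TRUE
})

#' YRandResult: Y-randomization (label permutation) test result
#'
#' @slot originalR2 Test-set R-squared of the model trained on true labels.
#' @slot permutedR2 R-squared for each label-permuted refit (features fixed).
#' @slot pValue Empirical permutation p-value, `(1 + b) / (1 + N)` where `b`
#'   counts permuted R-squared values at or above the original.
#' @slot seed Seed used for the split and permutations.
#' @export
setClass("YRandResult",
         representation(originalR2 = "numeric", permutedR2 = "numeric",
                        pValue = "numeric", seed = "numeric"))

setValidity("YRandResult", function(object) {
  if (object@pValue <= 0 || object@pValue > 1) {
    return("p-value must lie in (0, 1]")
  }
  TRUE
})
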