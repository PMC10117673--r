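#' @name oncoTargetML-accessors
#' @title Accessors for the package's S4 containers
#' @description Accessor generics for [CancerDataset-class],
#'   [FeatureBlock-class], [TrainedModel-class], [EvalResult-class] and
#'   [YRandResult-class] objects.
#' @param x An object.
#' @param object An object (for `show`).
NULL

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("cancerType", function(x) standardGeneric("cancerType"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("positives", function(x) standardGeneric("positives"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("negatives", function(x) standardGeneric("negatives"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("geneData", function(x) standardGeneric("geneData"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("blockName", function(x) standardGeneric("blockName"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("embedDimension", function(x) standardGeneric("embedDimension"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("maxTokens", function(x) standardGeneric("maxTokens"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("perUnitAuc", function(x) standardGeneric("perUnitAuc"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("meanAuc", function(x) standardGeneric("meanAuc"))

#' @rdname oncoTargetML-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Embed one amino-acid sequence (backend primitive)
#'
#' Internal generic dispatched on the backend class; users call
#' [embedSequences()].
#'
#' @param backend An [EmbeddingBackend-class] object.
#' @param sequence Single amino-acid string (already truncated/validated).
#' @param symbol Gene symbol of the sequence (used by cache lookups).
#' @return Numeric vector of length `embedDimension(backend)`.
#' @keywords internal
#' @export
setGeneric("embedOne", function(backend, sequence, symbol)
  standardGeneric("embedOne"))

#' Predict target probabilities
#'
#' @param model A [TrainedModel-class].
#' @param features A [FeatureBlock-class] or numeric matrix whose column count
#'   matches the model's feature dimension.
#' @return Numeric vector of scores in \[0, 1\], one per row.
#' @export
setGeneric("predictScores", function(model, features)
  standardGeneric("predictScores"))

# ---- accessor methods ----

#' @rdname oncoTargetML-accessors
#' @export
setMethod("cancerType", "CancerDataset", function(x) x@cancerType)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("positives", "CancerDataset", function(x)
  x@geneData[x@geneData$label == 1L, , drop = FALSE])

#' @rdname oncoTargetML-accessors
#' @export
setMethod("negatives", "CancerDataset", function(x)
  x@geneData[x@geneData$label == 0L, , drop = FALSE])

#' @rdname oncoTargetML-accessors
#' @export
setMethod("geneSymbols", "CancerDataset", function(x) x@geneData$symbol)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("geneData", "CancerDataset", function(x) x@geneData)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("geneSymbols", "FeatureBlock", function(x) x@genes)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("blockName", "FeatureBlock", function(x) x@name)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("featureMatrix", "FeatureBlock", function(x) x@matrix)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("embedDimension", "EmbeddingBackend", function(x) x@dimension)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("maxTokens", "EmbeddingBackend", function(x) x@maxTokens)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("perUnitAuc", "EvalResult", function(x) x@perUnitAuc)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("meanAuc", "EvalResult", function(x) x@meanAuc)

#' @rdname oncoTargetML-accessors
#' @export
setMethod("pValue", "YRandResult", function(x) x@pValue)

# ---- show methods ----

#' @rdname oncoTargetML-accessors
#' @export
setMethod("show", "CancerDataset", function(object) {
  cat(sprintf("CancerDataset '%s': %d genes (%d targets, %d non-targets)\n",
              object@cancerType, nrow(object@geneData),
              sum(object@geneData$label == 1L),
              sum(object@geneData$label == 0L)))
  n_seq <- sum(!is.na(object@geneData$sequence))
  cat(sprintf("  sequences attached: %d/%d\n", n_seq, nrow(object@geneData)))
})

#' @rdname oncoTargetML-accessors
#' @export
setMethod("show", "FeatureBlock", function(object) {
  cat(sprintf("FeatureBlock '%s': %d genes x %d features\n",
              object@name, nrow(object@matrix), ncol(object@matrix)))
})

#' @rdname oncoTargetML-accessors
#' @export
setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel (%s), %d input features\n", object@kind,
              object@featureDimension))
  mf <- object@trainingManifest
  cat(sprintf("  trained on %d samples (%d pos / %d neg), seed %s\n",
              mf$n_samples, mf$n_pos, mf$n_neg, format(mf$seed)))
  if (length(object@lossHistory)) {
    cat(sprintf("  final training loss: %.4f over %d epochs\n",
                utils::tail(object@lossHistory, 1L),
                length(object@lossHistory)))
  }
})

#' @rdname oncoTargetML-accessors
#' @export
setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult [%s]: mean AUC %.4f over %d units\n",
              object@protocol, object@meanAuc, length(object@perUnitAuc)))
  cat("  per-unit AUC:", paste(sprintf("%.3f", object@perUnitAuc),
                               collapse = " "), "\n")
})

#' @rdname oncoTargetML-accessors
#' @export
setMethod("show", "YRandResult", function(object) {
  cat(sprintf("YRandResult: original R2 %.4f, %d permutations, p = %.4g\n",
              object@originalR2, length(object@permutedR2), object@pValue))
  cat(sprintf("  permuted R2 range: [%.3f, %.3f], %d negative\n",
              min(object@permutedR2), max(object@permutedR2),
              sum(object@permutedR2 < 0)))
})
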