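#' Rank unlabeled genes as novel therapeutic target candidates
#'
#' Applies a trained classifier (conventionally the best configuration
#' retrained on the full labeled dataset with 100 epochs) to unlabeled genes
#' and ranks those predicted positive — score at or above the positivity
#' threshold, default 0.5 — by descending prediction probability. Ties are
#' broken by ascending gene symbol so repeated runs return an identical
#' ordering. At most `top_k` candidates are returned.
#'
#' @param model A [TrainedModel-class].
#' @param unlabeled_features [FeatureBlock-class] of the unlabeled genes. If
#'   the model was trained on min-max-scaled features, apply the
#'   training-fitted scaler (see [scalerTransform()]) before calling.
#' @param top_k Maximum number of candidates (default 10).
#' @param threshold Positivity cut on the score (default 0.5).
#' @return data.frame with columns `symbol`, `score`, `rank` (rank 1 = highest
#'   score), at most `top_k` rows, every score >= `threshold`.
#' @export
rankCandidates <- function(model, unlabeled_features, top_k = 10L,
                           threshold = 0.5) {
  top_k <- as.integer(top_k)
  if (top_k < 1L) stop("top_k must be a positive integer")
  symbols <- geneSymbols(unlabeled_features)
  scores <- predictScores(model, unlabeled_features)
  keep <- which(scores >= threshold)
  ord <- keep[order(-scores[keep], symbols[keep])]
  ord <- utils::head(ord, top_k)
  data.frame(symbol = symbols[ord], score = scores[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Write a ranked candidate table
#'
#' Tab-separated `gene`, `score` (4 decimals), `rank`.
#'
#' @param candidates data.frame from [rankCandidates()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCandidateTable <- function(candidates, path) {
  out <- data.frame(gene = candidates$symbol,
                    score = sprintf("%.4f", candidates$score),
                    rank = candidates$rank)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
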