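# Amino-acid alphabet: the 20 standard residues plus the ambiguity /
# non-standard codes X, U (selenocysteine), B, Z accepted by UniProt exports.
.aaAlphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "U", "B", "Z")

.checkSequence <- function(seq, symbol) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .aaAlphabet)
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d in sequence '%s'",
                 chars[bad[1]], bad[1], symbol))
  }
  invisible(TRUE)
}

#' @describeIn MockEmbedder-class deterministic hash-seeded standard-normal
#'   vector for one sequence.
#' @inheritParams embedOne
#' @export
setMethod("embedOne", "MockEmbedder", function(backend, sequence, symbol) {
  withr::with_seed(stableHash(sequence), stats::rnorm(backend@dimension))
})

#' @describeIn CachedEmbedder-class look the gene symbol up in the cache.
#' @inheritParams embedOne
#' @export
setMethod("embedOne", "CachedEmbedder", function(backend, sequence, symbol) {
  if (!symbol %in% rownames(backend@table)) {
    stop(sprintf("gene '%s' absent from the embedding cache", symbol))
  }
  backend@table[symbol, ]
})

#' Embed amino-acid sequences into fixed-length feature vectors
#'
#' Maps each protein sequence to one numeric vector using the given backend.
#' For the reference protein-language-model backend the per-protein vector is
#' the mean over token positions of the final hidden states (1,024
#' dimensions); here that backend is consumed through a [CachedEmbedder-class]
#' of externally computed vectors, while [MockEmbedder-class] provides a
#' deterministic offline stand-in. Sequences longer than
#' `maxTokens(backend)` are truncated with a warning; an invalid residue is an
#' error naming its position.
#'
#' @param sequences Named character vector (or `Biostrings::AAStringSet`) of
#'   amino-acid sequences, names = gene symbols; or a two-column data.frame
#'   (symbol, sequence).
#' @param backend An [EmbeddingBackend-class].
#' @return A [FeatureBlock-class] named `"embedding"` when the backend is
#'   1,024-dimensional (otherwise `"embedding<d>"`), rows in input order.
#' @examples
#' emb <- embedSequences(c(G1 = "ACDEFG", G2 = "MKLVW"), MockEmbedder(8))
#' dim(featureMatrix(emb))
#' @export
embedSequences <- function(sequences, backend) {
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$symbol)
  }
  if (length(sequences) == 0L) stop("no sequences to embed")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by gene symbol")
  }
  symbols <- normalizeSymbols(names(sequences))
  seqs <- toupper(as.character(sequences))
  n_long <- sum(nchar(seqs) > maxTokens(backend))
  if (n_long > 0L) {
    warning(sprintf("truncating %d sequence(s) longer than %d residues",
                    n_long, maxTokens(backend)))
    seqs <- substr(seqs, 1L, maxTokens(backend))
  }
  mat <- matrix(0, nrow = length(seqs), ncol = embedDimension(backend),
                dimnames = list(NULL, sprintf("E%04d",
                                              seq_len(embedDimension(backend)))))
  for (i in seq_along(seqs)) {
    .checkSequence(seqs[i], symbols[i])
    mat[i, ] <- embedOne(backend, seqs[i], symbols[i])
  }
  nm <- if (embedDimension(backend) == 1024L) "embedding"
        else paste0("embedding", embedDimension(backend))
  FeatureBlock(nm, symbols, mat)
}

#' Aggregate one gene's expression over patient samples
#'
#' Each gene is summarized by four order/location statistics of its expression
#' values across all patient samples of the matching cancer type: maximum,
#' mean, median and minimum (in that order). Together they capture whether a
#' gene is consistently highly expressed. The median of an even-length vector
#' is the midpoint of the two central order statistics.
#'
#' @param values Non-negative numeric vector of expression values for one
#'   gene (one entry per patient sample).
#' @return Named numeric vector `c(max, mean, median, min)`.
#' @examples
#' aggregateExpression(c(1, 3, 5))
#' @export
aggregateExpression <- function(values) {
  if (length(values) == 0L) stop("no expression samples for gene")
  if (any(!is.finite(values))) stop("non-finite expression values")
  c(max = max(values), mean = mean(values),
    median = stats::median(values), min = min(values))
}

#' Count how often a gene is mutated across patient samples
#'
#' @param maf_records MAF-like data.frame with columns `gene_symbol`,
#'   `sample_id`, `mutated_flag` (logical).
#' @param gene Gene symbol; a gene absent from the table counts 0.
#' @return Non-negative integer count of `mutated_flag == TRUE` records.
#' @examples
#' maf <- data.frame(gene_symbol = c("TP53", "TP53", "KRAS"),
#'                   sample_id = c("s1", "s2", "s1"),
#'                   mutated_flag = c(TRUE, TRUE, FALSE))
#' countMutations(maf, "TP53")
#' @export
countMutations <- function(maf_records, gene) {
  symbols <- normalizeSymbols(maf_records$gene_symbol)
  sum(symbols == normalizeSymbols(gene) & maf_records$mutated_flag,
      na.rm = TRUE)
}

#' Build the 5-column omics feature block
#'
#' For each gene: the four expression aggregates ([aggregateExpression()])
#' plus the mutation count ([countMutations()]). A gene with no expression
#' rows gets zeros for the four expression features (recorded in the
#' `missing_expression` attribute); a gene absent from the mutation table
#' counts 0 mutations.
#'
#' @param genes Ordered character vector of gene symbols.
#' @param expression Numeric matrix, genes x samples, gene-symbol rownames
#'   (see [readExpressionMatrix()]).
#' @param maf MAF-like data.frame (see [readMafTable()]).
#' @return A [FeatureBlock-class] named `"omics"` with columns
#'   `expr_max`, `expr_mean`, `expr_median`, `expr_min`, `mutation_count` and
#'   a `missing_expression` attribute on its matrix.
#' @export
omicsFeatureBlock <- function(genes, expression, maf) {
  genes <- normalizeSymbols(genes)
  rn <- normalizeSymbols(rownames(expression))
  # precompute per-gene mutation counts in one pass
  mut_tab <- table(normalizeSymbols(
    maf$gene_symbol[as.logical(maf$mutated_flag) %in% TRUE]))
  mat <- matrix(0, nrow = length(genes), ncol = 5L,
                dimnames = list(genes, c("expr_max", "expr_mean",
                                         "expr_median", "expr_min",
                                         "mutation_count")))
  missing_expr <- character()
  for (i in seq_along(genes)) {
    g <- genes[i]
    row <- which(rn == g)
    if (length(row) >= 1L) {
      mat[i, 1:4] <- aggregateExpression(expression[row[1L], ])
    } else {
      missing_expr <- c(missing_expr, g)
    }
    mat[i, 5L] <- if (g %in% names(mut_tab)) as.numeric(mut_tab[[g]]) else 0
  }
  if (length(missing_expr)) {
    message(sprintf("%d gene(s) without expression data imputed as 0: %s",
                    length(missing_expr),
                    paste(utils::head(missing_expr, 5L), collapse = ", ")))
  }
  attr(mat, "missing_expression") <- missing_expr
  block <- FeatureBlock("omics", genes, mat)
  block
}

#' Min-max feature normalization fitted on chosen rows
#'
#' Rescales every column to \[0, 1\] via `(x - min) / (max - min)`, with the
#' per-column min and max computed over `fit_rows` only. Fitting on the
#' training rows and merely transforming held-out rows avoids information
#' leakage from test to train; transformed out-of-fit values are clipped to
#' \[0, 1\]. A constant column maps to 0.
#'
#' @param block A [FeatureBlock-class] or numeric matrix.
#' @param fit_rows Row indices used to fit the scaler (default: all rows).
#' @return List with elements `block` (the transformed block) and `scaler`
#'   (reusable with [scalerTransform()] / [scalerInverse()]).
#' @examples
#' b <- FeatureBlock("toy", c("a", "b", "c"), matrix(c(2, 4, 6), 3, 1))
#' minmaxNormalize(b)$block
#' @export
minmaxNormalize <- function(block, fit_rows = NULL) {
  is_block <- methods::is(block, "FeatureBlock")
  m <- if (is_block) featureMatrix(block) else as.matrix(block)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(m))
  if (length(fit_rows) == 0L) stop("fit_rows must be non-empty")
  bad <- which(!apply(m, 2L, function(col) all(is.finite(col))))
  if (length(bad)) {
    stop("non-finite values in column(s): ", paste(bad, collapse = ", "))
  }
  fit <- m[fit_rows, , drop = FALSE]
  mins <- apply(fit, 2L, min)
  maxs <- apply(fit, 2L, max)
  scaler <- structure(list(min = mins, max = maxs,
                           constant = maxs - mins == 0),
                      class = "minmaxScaler")
  out <- scalerTransform(scaler, m)
  rn <- if (!is.null(rownames(m))) rownames(m)
        else sprintf("row%d", seq_len(nrow(m)))
  new_block <- if (is_block) FeatureBlock(blockName(block), geneSymbols(block), out)
               else FeatureBlock("scaled", rn, out)
  list(block = new_block, scaler = scaler)
}

#' Apply or invert a fitted min-max scaler
#'
#' `scalerTransform` rescales new rows with the stored per-column min/max
#' (clipping to \[0, 1\]); `scalerInverse` maps scaled values back to the
#' original units (exact for rows inside the fitted range).
#'
#' @param scaler A scaler from [minmaxNormalize()].
#' @param m A [FeatureBlock-class] or numeric matrix with matching columns.
#' @return A numeric matrix.
#' @export
scalerTransform <- function(scaler, m) {
  if (methods::is(m, "FeatureBlock")) m <- featureMatrix(m)
  m <- as.matrix(m)
  if (ncol(m) != length(scaler$min)) {
    stop(sprintf("scaler fitted on %d columns, data has %d",
                 length(scaler$min), ncol(m)))
  }
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1  # constant columns map to 0
  out <- sweep(sweep(m, 2L, scaler$min, "-"), 2L, rng, "/")
  out[, scaler$constant] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' @rdname scalerTransform
#' @export
scalerInverse <- function(scaler, m) {
  if (methods::is(m, "FeatureBlock")) m <- featureMatrix(m)
  m <- as.matrix(m)
  rng <- scaler$max - scaler$min
  sweep(sweep(m, 2L, rng, "*"), 2L, scaler$min, "+")
}

#' Concatenate embedding and omics blocks into the integrated features
#'
#' Row-wise concatenation with embedding columns first; with the canonical
#' 1,024-column embedding block and 5-column omics block the result is the
#' 1,029-column integrated block. Gene order must match exactly — mismatched
#' order is an error, never silently reordered.
#'
#' @param embedding_block [FeatureBlock-class] of sequence embeddings.
#' @param omics_block [FeatureBlock-class] of omics features.
#' @return A [FeatureBlock-class] named `"integrated"` (1,029 columns) or
#'   `"integrated<d>"` for non-canonical dimensions.
#' @export
integrateFeatures <- function(embedding_block, omics_block) {
  if (!identical(geneSymbols(embedding_block), geneSymbols(omics_block))) {
    stop("gene order differs between the embedding and omics blocks")
  }
  m <- cbind(featureMatrix(embedding_block), featureMatrix(omics_block))
  nm <- if (ncol(m) == 1029L) "integrated" else paste0("integrated", ncol(m))
  FeatureBlock(nm, geneSymbols(embedding_block), m)
}
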