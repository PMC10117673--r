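#' Readers for the curated tabular inputs
#'
#' The pipeline consumes file-based exports of the curated sources: a
#' drug-target interaction table (CSV: drug_id, gene_symbol), a biomarker
#' gene list (CSV: gene_symbol), a human protein-coding gene pool (CSV:
#' gene_symbol, protein_name, reviewed), protein sequences (FASTA, record id
#' = gene symbol), a gene-by-sample expression matrix (TSV, first column
#' gene_symbol, remaining columns samples) and a MAF-like mutation table
#' (TSV: gene_symbol, sample_id, mutated_flag as TRUE/FALSE).
#'
#' @param path File path.
#' @return The parsed object (data.frame, matrix, or named character vector
#'   of sequences).
#' @name input-readers
NULL

#' @rdname input-readers
#' @export
readDtiTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"gene_symbol" %in% names(df)) {
    stop("DTI table must have a 'gene_symbol' column: ", path)
  }
  df
}

#' @rdname input-readers
#' @export
readBiomarkerList <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"gene_symbol" %in% names(df)) {
    stop("biomarker list must have a 'gene_symbol' column: ", path)
  }
  df$gene_symbol
}

#' @rdname input-readers
#' @export
readGenePool <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"gene_symbol" %in% names(df)) {
    stop("gene pool must have a 'gene_symbol' column: ", path)
  }
  if ("reviewed" %in% names(df)) df$reviewed <- as.logical(df$reviewed)
  df
}

#' @rdname input-readers
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  # FASTA descriptions are free-form; the record id (first word) is the symbol
  names(aa) <- normalizeSymbols(sub("\\s.*$", "", names(aa)))
  stats::setNames(as.character(aa), names(aa))
}

#' @rdname input-readers
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_symbol") {
    stop("expression matrix must have 'gene_symbol' as its first column: ", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- normalizeSymbols(df$gene_symbol)
  m
}

#' @rdname input-readers
#' @export
readMafTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("gene_symbol", "sample_id", "mutated_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("MAF table lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$mutated_flag <- as.logical(df$mutated_flag)
  df
}

#' Read / write a per-cancer embedding cache
#'
#' Expensive embedding backends run once; their output is cached as a
#' tab-separated numeric matrix with the gene symbol as the first column
#' (`gene_symbol`), one row per gene.
#'
#' @param path File path.
#' @param block A [FeatureBlock-class] to write.
#' @return `readEmbeddingCache` returns a numeric matrix with gene-symbol
#'   rownames, suitable for [CachedEmbedder()].
#' @export
readEmbeddingCache <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- normalizeSymbols(df$gene_symbol)
  m
}

#' @rdname readEmbeddingCache
#' @export
writeEmbeddingCache <- function(block, path) {
  df <- data.frame(gene_symbol = geneSymbols(block),
                   featureMatrix(block), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
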