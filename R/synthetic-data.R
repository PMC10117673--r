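#' Synthetic-data generator configuration
#'
#' Controls the seeded generators that emulate every pipeline input with known
#' ground truth: random protein sequences, class-separated embedding clouds,
#' expression matrices with a class-dependent location shift, and per-gene
#' mutation counts with class-dependent rates.
#'
#' The embedding clouds are class-conditional spherical unit-variance
#' Gaussians whose means lie `embedding_separation` apart — since the
#' covariance is the identity, that separation is the Mahalanobis distance
#' between the classes, and the optimal linear score has the closed-form AUC
#' `pnorm(embedding_separation / sqrt(2))`. Expression is log-normal (so
#' non-negativity holds, matching real expression supports) with a
#' multiplicative positive-class shift of `exp(omics_effect)`; mutation counts
#' are Poisson with per-sample rates `mutation_rates` accumulated over
#' `n_patient_samples`.
#'
#' @param n_pos,n_neg Positive / negative gene counts.
#' @param seq_length_range Integer (min, max) sequence lengths.
#' @param embedding_separation Distance between class means in embedding
#'   space (Mahalanobis, identity covariance).
#' @param omics_effect Positive-class location shift of log-expression.
#' @param mutation_rates Per-sample mutation rates `c(pos, neg)`.
#' @param n_patient_samples Patient samples per cancer type (default 10, the
#'   cohort size the omics queries use).
#' @param embedding_dim Embedding dimension; default the canonical 1,024
#'   (reduce only for cheap tests).
#' @param expression_meanlog,expression_sdlog Log-normal baseline parameters
#'   (defaults log(100) and 1).
#' @param seed Master seed; each generator derives its own stream from it.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(n_pos, n_neg, seq_length_range = c(50L, 500L),
                      embedding_separation = 0, omics_effect = 0,
                      mutation_rates = c(pos = 0.15, neg = 0.05),
                      n_patient_samples = 10L, embedding_dim = 1024L,
                      expression_meanlog = log(100), expression_sdlog = 1,
                      seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop("n_pos and n_neg must be >= 1")
  if (length(seq_length_range) != 2L ||
      seq_length_range[2] < seq_length_range[1]) {
    stop("seq_length_range must be (min, max) with max >= min")
  }
  if (embedding_separation < 0) stop("embedding_separation must be >= 0")
  if (any(mutation_rates < 0)) stop("mutation_rates must be >= 0")
  if (n_patient_samples < 1L) stop("n_patient_samples must be >= 1")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seq_length_range = as.integer(seq_length_range),
                 embedding_separation = embedding_separation,
                 omics_effect = omics_effect,
                 mutation_rates = stats::setNames(as.numeric(mutation_rates),
                                                  c("pos", "neg")),
                 n_patient_samples = as.integer(n_patient_samples),
                 embedding_dim = as.integer(embedding_dim),
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 seed = seed),
            class = "SimConfig")
}

.simSymbols <- function(n, prefix = "SYN") sprintf("%s%04d", prefix, seq_len(n))

# twenty standard residues only — simulated sequences carry no ambiguity codes
.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate protein sequences
#'
#' `n_pos + n_neg` random sequences over the 20-letter amino-acid alphabet
#' with lengths uniform in `seq_length_range`, named `SYN0001`, `SYN0002`, ...
#' Reproducible: the same config yields byte-identical FASTA output.
#'
#' @param config A [simConfig()].
#' @return A `Biostrings::AAStringSet` named by gene symbol.
#' @export
simulateSequences <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$n_pos + config$n_neg
  seqs <- withr::with_seed(deriveSeed(config$seed, "sequences"), {
    lens <- sample(seq(config$seq_length_range[1], config$seq_length_range[2]),
                   n, replace = TRUE)
    vapply(lens, function(L) paste(sample(.aa20, L, replace = TRUE),
                                   collapse = ""), "")
  })
  Biostrings::AAStringSet(stats::setNames(seqs, .simSymbols(n)))
}

.simEmbedding <- function(n_pos, n_neg, d, delta, seed) {
  mat <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm((n_pos + n_neg) * d), n_pos + n_neg, d)
    shift <- rep(delta / (2 * sqrt(d)), d)  # |mu_pos - mu_neg| = delta
    m[seq_len(n_pos), ] <- sweep(m[seq_len(n_pos), , drop = FALSE], 2L,
                                 shift, "+")
    m[n_pos + seq_len(n_neg), ] <- sweep(m[n_pos + seq_len(n_neg), ,
                                           drop = FALSE], 2L, shift, "-")
    m
  })
  colnames(mat) <- sprintf("E%04d", seq_len(d))
  mat
}

.simExpression <- function(n_pos, n_neg, config, seed) {
  n <- n_pos + n_neg
  withr::with_seed(seed, {
    shift <- c(rep(config$omics_effect, n_pos), rep(0, n_neg))
    t(vapply(seq_len(n), function(i) {
      stats::rlnorm(config$n_patient_samples,
                    meanlog = config$expression_meanlog + shift[i],
                    sdlog = config$expression_sdlog)
    }, numeric(config$n_patient_samples)))
  })
}

.simMutations <- function(n_pos, n_neg, config, seed) {
  withr::with_seed(seed, {
    lambda <- c(rep(config$mutation_rates["pos"], n_pos),
                rep(config$mutation_rates["neg"], n_neg)) *
      config$n_patient_samples
    stats::rpois(n_pos + n_neg, lambda)
  })
}

.simOmicsBlock <- function(expr, mut) {
  agg <- t(apply(expr, 1L, aggregateExpression))
  m <- cbind(agg, mutation_count = as.numeric(mut))
  colnames(m) <- c("expr_max", "expr_mean", "expr_median", "expr_min",
                   "mutation_count")
  m
}

#' Simulate an integrated labeled feature set with known class structure
#'
#' Draws `n_pos` positive and `n_neg` negative genes: a class-separated
#' Gaussian embedding block (separation `embedding_separation`), four
#' expression aggregates from class-shifted log-normal draws over
#' `n_patient_samples`, and a Poisson mutation count at the class rate; the
#' blocks are concatenated embeddings-first (1,029 columns at the default
#' dimension).
#'
#' @param config A [simConfig()].
#' @return List with `features` (a [FeatureBlock-class], name `"integrated"`
#'   at the canonical dimension), `labels` (1 for the first `n_pos` genes,
#'   then 0) and the raw `expression` matrix and `mutations` vector.
#' @examples
#' sim <- simulateLabeledFeatures(simConfig(20, 20, embedding_separation = 4,
#'                                          embedding_dim = 8, seed = 3))
#' table(sim$labels)
#' @export
simulateLabeledFeatures <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n_pos <- config$n_pos
  n_neg <- config$n_neg
  emb <- .simEmbedding(n_pos, n_neg, config$embedding_dim,
                       config$embedding_separation,
                       deriveSeed(config$seed, "embedding"))
  expr <- .simExpression(n_pos, n_neg, config,
                         deriveSeed(config$seed, "expression"))
  mut <- .simMutations(n_pos, n_neg, config,
                       deriveSeed(config$seed, "mutations"))
  genes <- .simSymbols(n_pos + n_neg)
  rownames(expr) <- genes
  m <- cbind(emb, .simOmicsBlock(expr, mut))
  nm <- if (ncol(m) == 1029L) "integrated" else paste0("integrated", ncol(m))
  list(features = FeatureBlock(nm, genes, m),
       labels = c(rep(1L, n_pos), rep(0L, n_neg)),
       expression = expr, mutations = mut)
}

#' Simulate a positive-unlabeled candidate pool
#'
#' An unlabeled gene pool drawn from the negative-class generator with
#' `n_planted` rows swapped for positive-class draws at seeded random
#' positions — the planted positives are returned for evaluation only (the
#' ranking stage never sees them), emulating hidden true targets among
#' unlabeled human genes.
#'
#' @param config A [simConfig()] (class structure parameters are reused).
#' @param n_unlabeled Pool size.
#' @param n_planted Number of hidden positives, `<= n_unlabeled`.
#' @return List with `features` (a [FeatureBlock-class] of genes
#'   `UNL0001`, ...) and `planted` (sorted indices of the hidden positives).
#' @export
simulatePuPool <- function(config, n_unlabeled, n_planted) {
  stopifnot(inherits(config, "SimConfig"))
  n_unlabeled <- as.integer(n_unlabeled)
  n_planted <- as.integer(n_planted)
  if (n_planted > n_unlabeled || n_planted < 0L) {
    stop(sprintf("n_planted (%d) must lie in [0, n_unlabeled = %d]",
                 n_planted, n_unlabeled))
  }
  # draw a full pool of each class, then swap planted rows in
  neg_cfg <- config
  emb_neg <- .simEmbedding(0L, n_unlabeled, config$embedding_dim,
                           config$embedding_separation,
                           deriveSeed(config$seed, "pu-neg-embedding"))
  expr_neg <- .simExpression(0L, n_unlabeled, neg_cfg,
                             deriveSeed(config$seed, "pu-neg-expression"))
  mut_neg <- .simMutations(0L, n_unlabeled, neg_cfg,
                           deriveSeed(config$seed, "pu-neg-mutations"))
  planted <- sort(withr::with_seed(deriveSeed(config$seed, "pu-planted"),
                                   sample(n_unlabeled, n_planted)))
  if (n_planted > 0L) {
    emb_pos <- .simEmbedding(n_planted, 0L, config$embedding_dim,
                             config$embedding_separation,
                             deriveSeed(config$seed, "pu-pos-embedding"))
    expr_pos <- .simExpression(n_planted, 0L, config,
                               deriveSeed(config$seed, "pu-pos-expression"))
    mut_pos <- .simMutations(n_planted, 0L, config,
                             deriveSeed(config$seed, "pu-pos-mutations"))
    emb_neg[planted, ] <- emb_pos
    expr_neg[planted, ] <- expr_pos
    mut_neg[planted] <- mut_pos
  }
  genes <- .simSymbols(n_unlabeled, prefix = "UNL")
  rownames(expr_neg) <- genes
  m <- cbind(emb_neg, .simOmicsBlock(expr_neg, mut_neg))
  nm <- if (ncol(m) == 1029L) "integrated" else paste0("integrated", ncol(m))
  list(features = FeatureBlock(nm, genes, m), planted = planted)
}

#' Write a complete set of synthetic input files
#'
#' Emits every file format the assembly and feature stages consume, so the
#' full chain (and its command-line driver) runs end-to-end offline: protein
#' FASTA, gene-by-sample expression TSV, MAF-like mutation TSV, a drug-target
#' interaction CSV covering the positive genes, a biomarker CSV, and a human
#' gene pool CSV (positives, negatives and extra decoy genes, all flagged
#' reviewed).
#'
#' @param config A [simConfig()].
#' @param out_dir Output directory (created if needed).
#' @param n_decoys Extra pool-only genes (default `2 * (n_pos + n_neg)`).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulateInputTables <- function(config, out_dir,
                                n_decoys = 2L * (config$n_pos + config$n_neg)) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- config$n_pos + config$n_neg
  genes <- .simSymbols(n)
  pos_genes <- genes[seq_len(config$n_pos)]

  seqs <- simulateSequences(config)
  decoys <- if (n_decoys > 0L) sprintf("DCY%04d", seq_len(n_decoys)) else character()
  decoy_cfg <- config
  decoy_seqs <- if (n_decoys > 0L) withr::with_seed(
    deriveSeed(config$seed, "decoy-sequences"), {
      lens <- sample(seq(config$seq_length_range[1], config$seq_length_range[2]),
                     n_decoys, replace = TRUE)
      stats::setNames(vapply(lens, function(L)
        paste(sample(.aa20, L, replace = TRUE), collapse = ""), ""), decoys)
    }) else character()

  paths <- list(
    fasta = file.path(out_dir, "sequences.fasta"),
    expression = file.path(out_dir, "expression.tsv"),
    maf = file.path(out_dir, "mutations.tsv"),
    dti = file.path(out_dir, "dti.csv"),
    biomarkers = file.path(out_dir, "biomarkers.csv"),
    pool = file.path(out_dir, "gene_pool.csv"))

  all_seqs <- c(stats::setNames(as.character(seqs), names(seqs)), decoy_seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(all_seqs), paths$fasta)

  sim <- simulateLabeledFeatures(config)
  expr <- sim$expression
  samples <- sprintf("SAMPLE%02d", seq_len(config$n_patient_samples))
  expr_df <- data.frame(gene_symbol = rownames(expr), expr,
                        check.names = FALSE)
  names(expr_df) <- c("gene_symbol", samples)
  utils::write.table(expr_df, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # expand per-gene counts into MAF-like records (one row per mutated sample)
  maf_rows <- do.call(rbind, lapply(seq_along(genes), function(i) {
    k <- min(sim$mutations[i], config$n_patient_samples)
    if (k == 0L) return(NULL)
    data.frame(gene_symbol = genes[i], sample_id = samples[seq_len(k)],
               mutated_flag = TRUE, stringsAsFactors = FALSE)
  }))
  if (is.null(maf_rows)) {
    maf_rows <- data.frame(gene_symbol = character(), sample_id = character(),
                           mutated_flag = logical())
  }
  utils::write.table(maf_rows, paths$maf, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  half <- ceiling(config$n_pos / 2)
  dti <- data.frame(drug_id = sprintf("DRG%03d", rep(seq_len(half),
                                                     length.out = half)),
                    gene_symbol = pos_genes[seq_len(half)])
  utils::write.table(dti, paths$dti, sep = ",", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_symbol = pos_genes[seq(half + 1,
                                                            length.out = config$n_pos - half)]),
                     paths$biomarkers, sep = ",", quote = FALSE,
                     row.names = FALSE)
  pool <- data.frame(gene_symbol = c(genes, decoys),
                     protein_name = paste("synthetic protein",
                                          c(genes, decoys)),
                     reviewed = TRUE)
  utils::write.table(pool, paths$pool, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
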