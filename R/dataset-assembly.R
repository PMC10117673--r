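#' Build the positive (target) gene set for one cancer type
#'
#' Positives are the union of the unique approved drug-target gene symbols and
#' the overexpressed biomarker gene symbols, restricted to SwissProt-reviewed
#' entries. Duplicate symbols within one source are de-duplicated silently
#' (with a message); duplicates across the two sources collapse by set union.
#'
#' @param dti_table data.frame with at least a `gene_symbol` column (one row
#'   per approved drug-target interaction; `drug_id` optional).
#' @param biomarker_genes Character vector of overexpressed biomarker gene
#'   symbols (may be empty).
#' @param reviewed_flags Named logical vector mapping gene symbol to its
#'   SwissProt-reviewed status. Symbols absent from the map are treated as
#'   unreviewed and dropped.
#' @return data.frame of gene records (see [geneRecords()]), all `label = 1`.
#' @examples
#' dti <- data.frame(drug_id = c("D1", "D1"), gene_symbol = c("EGFR", "ERBB2"))
#' flags <- c(EGFR = TRUE, ERBB2 = TRUE, MYC = TRUE)
#' buildPositiveSet(dti, "MYC", flags)
#' @export
buildPositiveSet <- function(dti_table, biomarker_genes, reviewed_flags) {
  if (is.null(dti_table) || is.null(reviewed_flags)) {
    stop("dti_table and reviewed_flags must be non-null")
  }
  if (!"gene_symbol" %in% names(dti_table)) {
    stop("dti_table must have a 'gene_symbol' column")
  }
  dti_symbols <- normalizeSymbols(dti_table$gene_symbol)
  if (anyDuplicated(dti_symbols)) {
    message(sprintf("de-duplicated %d repeated DTI target symbol(s)",
                    sum(duplicated(dti_symbols))))
    dti_symbols <- unique(dti_symbols)
  }
  bio_symbols <- normalizeSymbols(biomarker_genes)
  if (anyDuplicated(bio_symbols)) {
    message(sprintf("de-duplicated %d repeated biomarker symbol(s)",
                    sum(duplicated(bio_symbols))))
    bio_symbols <- unique(bio_symbols)
  }
  pool <- union(dti_symbols, bio_symbols)
  names(reviewed_flags) <- normalizeSymbols(names(reviewed_flags))
  is_rev <- reviewed_flags[pool]
  is_rev[is.na(is_rev)] <- FALSE
  kept <- pool[is_rev]
  if (length(kept) == 0L) stop("no positive genes")
  geneRecords(kept, label = 1L, reviewed = TRUE)
}

#' Build the negative sampling pool of human protein-coding genes
#'
#' Removes the positive gene symbols of *all* cancer types from the
#' human protein-coding gene pool; negatives for every cancer type are then
#' drawn from this one shared pool (see [sampleNegatives()]).
#'
#' @param human_gene_table data.frame with a `gene_symbol` column (the human
#'   protein-coding gene pool; `protein_name`/`reviewed` columns optional).
#' @param all_positives Character vector of positive symbols across all
#'   cancer types.
#' @param min_size Smallest acceptable pool size — pass the largest per-cancer
#'   positive count so every cancer type can be balanced.
#' @return Character vector of candidate non-target symbols (sorted).
#' @export
buildNegativePool <- function(human_gene_table, all_positives, min_size = 1L) {
  if (is.null(human_gene_table) || nrow(human_gene_table) == 0L) {
    stop("human gene table must be non-empty")
  }
  if (!"gene_symbol" %in% names(human_gene_table)) {
    stop("human_gene_table must have a 'gene_symbol' column")
  }
  pool <- setdiff(unique(normalizeSymbols(human_gene_table$gene_symbol)),
                  normalizeSymbols(all_positives))
  if (length(pool) < min_size) {
    stop(sprintf("insufficient negative pool: %d genes remain, %d required",
                 length(pool), min_size))
  }
  sort(pool)
}

#' Sample non-target genes without cross-cancer reuse
#'
#' Draws exactly `k` symbols uniformly without replacement from
#' `pool \ already_used`. Threading the accumulated `already_used` set through
#' successive calls (one per cancer type, in a fixed order) guarantees that no
#' non-target gene is shared between cancer types. Identical
#' `(pool, k, seed, already_used)` give an identical sample.
#'
#' @param pool Character vector of candidate symbols
#'   (from [buildNegativePool()]).
#' @param k Number of negatives to draw (the positive count, for balance).
#' @param seed Integer seed for this draw.
#' @param already_used Symbols consumed by earlier cancer types.
#' @return data.frame of gene records, all `label = 0`.
#' @export
sampleNegatives <- function(pool, k, seed, already_used = character()) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  avail <- sort(setdiff(normalizeSymbols(pool), normalizeSymbols(already_used)))
  if (length(avail) < k) {
    stop(sprintf(
      "cannot sample %d negatives: only %d unused genes in the pool (short by %d)",
      k, length(avail), k - length(avail)))
  }
  drawn <- withr::with_seed(seed, sample(avail, k))
  geneRecords(drawn, label = 0L)
}

#' Assemble a balanced per-cancer dataset
#'
#' Combines positive and negative gene records into a [CancerDataset-class];
#' the class validity enforces balance (equal class sizes) and symbol
#' disjointness, so any violation raises an error here.
#'
#' @param cancer_type Name of the cancer type.
#' @param positives data.frame of gene records with `label = 1`.
#' @param negatives data.frame of gene records with `label = 0`.
#' @return A [CancerDataset-class] of size `nrow(positives) + nrow(negatives)`.
#' @export
assembleDataset <- function(cancer_type, positives, negatives) {
  if (any(positives$label != 1L)) stop("positives must all carry label 1")
  if (any(negatives$label != 0L)) stop("negatives must all carry label 0")
  gd <- rbind(positives, negatives)
  rownames(gd) <- NULL
  methods::new("CancerDataset", cancerType = as.character(cancer_type),
               geneData = gd)
}

#' Attach protein sequences to gene records
#'
#' Left-joins amino-acid sequences (FASTA keyed by gene symbol) onto gene
#' records. Genes without a sequence after the join are dropped with a
#' warning, whatever their class — sequence features cannot be computed for
#' them.
#'
#' @param records data.frame of gene records.
#' @param sequences Named character vector or `Biostrings::AAStringSet`
#'   keyed by gene symbol.
#' @return The records with the `sequence` column filled, missing-sequence
#'   rows removed.
#' @export
attachSequences <- function(records, sequences) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  names(sequences) <- normalizeSymbols(names(sequences))
  records$sequence <- unname(sequences[records$symbol])
  missing <- is.na(records$sequence)
  if (any(missing)) {
    warning(sprintf("dropping %d gene(s) with no sequence: %s",
                    sum(missing),
                    paste(utils::head(records$symbol[missing], 5L),
                          collapse = ", ")))
    records <- records[!missing, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Assemble balanced datasets for several cancer types
#'
#' Runs the full per-cancer construction: positives from approved drug-target
#' interactions plus overexpressed biomarkers (reviewed entries only),
#' negatives drawn from the shared human gene pool with no overlap between
#' cancer types, optional sequence attachment, and balancing. Cancer types are
#' processed in alphabetical order with per-cancer seeds derived from
#' `master_seed` (see [deriveSeed()]), so a rerun reproduces the datasets
#' exactly.
#'
#' When sequences are attached, positives that lack a sequence are dropped
#' *before* negatives are drawn, and sampled negatives without sequences are
#' replaced by redrawing, so the final dataset stays balanced.
#'
#' @param dti_tables Named list (cancer type -> DTI data.frame).
#' @param biomarker_lists Named list (cancer type -> character vector).
#' @param human_gene_table Human protein-coding gene pool data.frame with
#'   columns `gene_symbol` and optionally `reviewed`.
#' @param reviewed_flags Named logical vector of SwissProt-reviewed status; if
#'   `NULL`, taken from the `reviewed` column of `human_gene_table`.
#' @param sequences Optional named sequences (see [attachSequences()]).
#' @param master_seed Master seed; per-cancer seeds derive from it.
#' @return Named list with elements `datasets` (list of
#'   [CancerDataset-class]) and `manifest` (per-cancer counts and seeds, plus
#'   the global unique-gene count).
#' @export
assembleCancerDatasets <- function(dti_tables, biomarker_lists,
                                   human_gene_table, reviewed_flags = NULL,
                                   sequences = NULL, master_seed = 1L) {
  cancers <- sort(names(dti_tables))
  if (is.null(cancers) || !length(cancers)) stop("dti_tables must be a named list")
  if (is.null(reviewed_flags)) {
    if (!"reviewed" %in% names(human_gene_table)) {
      stop("supply reviewed_flags or a 'reviewed' column in human_gene_table")
    }
    reviewed_flags <- stats::setNames(as.logical(human_gene_table$reviewed),
                                      normalizeSymbols(human_gene_table$gene_symbol))
  }
  pos_sets <- lapply(cancers, function(cc) {
    buildPositiveSet(dti_tables[[cc]],
                     if (is.null(biomarker_lists[[cc]])) character()
                     else biomarker_lists[[cc]],
                     reviewed_flags)
  })
  names(pos_sets) <- cancers
  if (!is.null(sequences)) {
    pos_sets <- lapply(pos_sets, attachSequences, sequences = sequences)
  }
  all_pos <- unique(unlist(lapply(pos_sets, `[[`, "symbol"), use.names = FALSE))
  pool <- buildNegativePool(human_gene_table, all_pos,
                            min_size = max(vapply(pos_sets, nrow, 1L)))
  if (!is.null(sequences)) {
    # negatives must be embeddable too; restrict the pool up front
    seq_names <- normalizeSymbols(
      names(if (methods::is(sequences, "XStringSet")) as.character(sequences)
            else sequences))
    pool <- intersect(pool, seq_names)
  }

  used <- character()
  datasets <- list()
  manifest <- list(master_seed = master_seed, cancers = list())
  for (cc in cancers) {
    pos <- pos_sets[[cc]]
    seed_cc <- deriveSeed(master_seed, cc)
    neg <- sampleNegatives(pool, k = nrow(pos), seed = seed_cc,
                           already_used = used)
    if (!is.null(sequences)) neg <- attachSequences(neg, sequences)
    used <- c(used, neg$symbol)
    datasets[[cc]] <- assembleDataset(cc, pos, neg)
    manifest$cancers[[cc]] <- list(seed = seed_cc, n_pos = nrow(pos),
                                   n_neg = nrow(neg),
                                   n_total = nrow(pos) + nrow(neg))
  }
  all_symbols <- unlist(lapply(datasets, geneSymbols), use.names = FALSE)
  manifest$total_records <- length(all_symbols)
  manifest$total_unique_genes <- length(unique(all_symbols))
  list(datasets = datasets, manifest = manifest)
}

#' Write assembled datasets to disk
#'
#' One tab-separated file per cancer type (columns symbol, protein_id, label,
#' sequence) plus a JSON manifest with counts and seeds. Output is
#' byte-reproducible: rerunning the same assembly writes identical files.
#'
#' @param assembly Result of [assembleCancerDatasets()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeDatasets <- function(assembly, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (cc in names(assembly$datasets)) {
    gd <- geneData(assembly$datasets[[cc]])
    path <- file.path(out_dir, paste0(gsub("[^a-z0-9]+", "_", tolower(cc)),
                                      "_dataset.tsv"))
    utils::write.table(gd[, c("symbol", "protein_id", "label", "sequence")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(assembly$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, manifest_path))
}

#' Read one assembled dataset file
#'
#' @param path Path to a TSV written by [writeDatasets()].
#' @param cancer_type Cancer type name for the resulting object; defaults to
#'   the file name stem.
#' @return A [CancerDataset-class].
#' @export
readDatasetFile <- function(path, cancer_type = NULL) {
  gd <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = c(symbol = "character",
                                         protein_id = "character",
                                         label = "integer",
                                         sequence = "character"))
  gd$reviewed <- TRUE
  if (is.null(cancer_type)) {
    cancer_type <- sub("_dataset$", "", tools::file_path_sans_ext(basename(path)))
  }
  methods::new("CancerDataset", cancerType = cancer_type, geneData = gd)
}
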