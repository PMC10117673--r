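#' Normalize gene symbols
#'
#' Gene symbols arrive in mixed case and with stray whitespace across curated
#' sources; every set operation in the package works on the uppercased,
#' trimmed form.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector, uppercased and whitespace-trimmed.
#' @examples
#' normalizeSymbols(c(" tp53", "Egfr "))
#' @export
normalizeSymbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Stable string hash
#'
#' 32-bit FNV-1a hash of a string, reduced to `[0, .Machine$integer.max]` so it
#' can seed R's RNG. Used to derive independent, reproducible random streams
#' from strings (sequence-seeded mock embeddings, per-cancer seeds).
#'
#' @param s A single character string.
#' @return A non-negative integer-valued double below 2^31.
#' @examples
#' stableHash("ACDEFG")
#' @export
stableHash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  prime <- 16777619
  two32 <- 4294967296
  for (b in bytes) {
    # XOR affects only the low byte because b < 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply via 16-bit limbs (doubles stay < 2^53)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% two32
  }
  h %% 2147483647
}

#' Derive a seed from a master seed and a label
#'
#' Per-cancer (and per-operation) seeds are derived as
#' `(master + stableHash(label)) mod (2^31 - 1)` so that independent stages get
#' independent, reproducible random streams from one configured master seed.
#'
#' @param master Integer master seed.
#' @param label Character label naming the stream.
#' @return A single seed value below 2^31.
#' @export
deriveSeed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  (abs(master) + stableHash(as.character(label))) %% 2147483647
}

#' The ten cancer types of the reference dataset
#'
#' @return Character vector of the ten GLOBOCAN-prevalent cancer types the
#'   curated dataset covers.
#' @export
cancerTypes <- function() {
  c("bladder", "breast", "colon", "kidney", "leukemia",
    "liver", "lung", "non-hodgkin lymphoma", "rectal", "thyroid")
}

# shared column templates for gene record tables
.geneRecordColumns <- c("symbol", "protein_id", "sequence", "label", "reviewed")

#' Construct gene record rows
#'
#' A gene record holds one gene: symbol, optional protein accession and
#' amino-acid sequence, its binary target label (1 = target, 0 = non-target)
#' and the SwissProt-reviewed flag. Records are plain data.frame rows so they
#' compose with base tooling; [CancerDataset-class] enforces the invariants.
#'
#' @param symbol Character vector of gene symbols (normalized internally).
#' @param label Integer vector of 0/1 labels (recycled if length 1).
#' @param protein_id Optional accession strings.
#' @param sequence Optional amino-acid sequences.
#' @param reviewed Logical reviewed flags.
#' @return A data.frame with columns symbol, protein_id, sequence, label,
#'   reviewed.
#' @export
geneRecords <- function(symbol, label, protein_id = NA_character_,
                        sequence = NA_character_, reviewed = TRUE) {
  symbol <- normalizeSymbols(symbol)
  n <- length(symbol)
  if (n == 0L) {
    return(data.frame(symbol = character(), protein_id = character(),
                      sequence = character(), label = integer(),
                      reviewed = logical(), stringsAsFactors = FALSE))
  }
  label <- as.integer(rep_len(label, n))
  if (!all(label %in% c(0L, 1L))) {
    stop("labels must be 0 (non-target) or 1 (target)")
  }
  data.frame(symbol = symbol,
             protein_id = rep_len(as.character(protein_id), n),
             sequence = rep_len(as.character(sequence), n),
             label = label,
             reviewed = rep_len(as.logical(reviewed), n),
             stringsAsFactors = FALSE)
}
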