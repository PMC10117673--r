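# Shared fixture builders: everything is generated in code at test time.

# small reduced-dimension labeled feature set with strong class structure
separableFeatures <- function(n_per_class = 60, dim = 59, delta = 6,
                              seed = 11) {
  simulateLabeledFeatures(simConfig(n_per_class, n_per_class,
                                    embedding_separation = delta,
                                    embedding_dim = dim, seed = seed))
}

# exchangeable classes: no embedding separation, identical omics generators
noiseFeatures <- function(n_per_class = 30, dim = 16, seed = 1) {
  simulateLabeledFeatures(simConfig(n_per_class, n_per_class,
                                    embedding_separation = 0,
                                    omics_effect = 0,
                                    mutation_rates = c(pos = 0.05, neg = 0.05),
                                    embedding_dim = dim, seed = seed))
}

# brute-force all-pairs concordance AUC (independent O(n^2) oracle)
pairwiseAuc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# independent reimplementation of the mock embedder's generator:
# FNV-1a 32-bit over the sequence bytes, reduced mod 2^31 - 1, seeding rnorm
referenceMockVector <- function(sequence, dimension) {
  h <- 2166136261
  for (b in utf8ToInt(sequence)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(h %% 2147483647)
  rnorm(dimension)
}

randomGeneSymbols <- function(n, prefix = "G") sprintf("%s%05d", prefix, seq_len(n))
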