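---
title: "Prioritising cancer therapeutic targets from sequence embeddings and omics features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising cancer therapeutic targets from sequence embeddings and omics features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoTargetML)
```

## The problem

Most late-stage failures in anticancer drug development trace back to poorly
chosen targets. Framing target identification as supervised learning, a gene
is a *positive* (label 1) if it is the approved target of an anticancer drug
or a significantly overexpressed cancer biomarker, and a *negative* (label 0)
if it is an ordinary human protein-coding gene. For each of ten prevalent
cancer types, a balanced dataset of positives and randomly drawn negatives is
assembled; a classifier trained on per-gene feature vectors then scores
unlabeled genes, and the highest-scoring ones are nominated as candidate
novel targets.

Because only some true targets are known and the "negatives" are merely
unlabeled human genes, the final ranking stage is positive–unlabeled (PU)
learning: the pool being scored may well contain hidden positives, which is
precisely what the method is after.

## Dataset assembly

`buildPositiveSet()` forms the union of the unique approved drug–target gene
symbols and the biomarker gene symbols, keeping only SwissProt-reviewed
entries. `buildNegativePool()` removes the positives of **all** cancer types
from the human protein-coding gene pool, and `sampleNegatives()` draws, per
cancer type, exactly as many negatives as there are positives — balance gives
both classes equal weight during training — while threading an
`already_used` accumulator so that no negative gene is shared between cancer
types. Cancer types are processed in alphabetical order (the allocation order
is otherwise arbitrary, so we fix one) with per-cancer seeds derived from a
single master seed via a stable string hash, making every assembly run
byte-reproducible.

Two policies the sources leave open are fixed here: gene symbols are
uppercased and trimmed before any set operation (symbols arrive in mixed case
across curated sources), and genes that lack an amino-acid sequence after the
FASTA join are dropped from either class with a warning, since no sequence
features can be computed for them. The manifest reports both the per-cancer
record count and the number of globally unique genes; the two differ whenever
a gene is positive for several cancers, and neither is asserted against any
external total.

## Feature construction

Each gene is represented by the concatenation of two blocks
(`integrateFeatures()`, embeddings first):

* **Sequence embeddings (1,024 columns).** A protein language model maps the
  amino-acid sequence to the mean over token positions of its final hidden
  states — mean pooling is the conventional per-protein reduction for such
  models. Running a transformer is outside this package's scope, so
  embeddings computed elsewhere are consumed through a `CachedEmbedder`
  (a gene-keyed numeric matrix cached on disk, computed once), and all
  offline work and testing uses the deterministic `MockEmbedder`: each
  sequence seeds a random-number stream with a stable FNV-1a hash of the
  sequence string (32-bit, since R's RNG seeds are 32-bit integers) and draws
  standard-normal coordinates. Identical sequences therefore always embed
  identically, and distinct sequences collide with negligible probability.
  Sequences longer than 2,000 residues — the longer of the two training
  lengths the reference model saw — are truncated with a warning.
* **Omics summaries (5 columns).** Four order/location statistics of the
  gene's expression across the patient samples of the matching cancer type
  (maximum, mean, median, minimum; the median of an even-length sample is the
  midpoint of the central order statistics) plus the count of samples in
  which the gene is mutated. A gene with no expression rows gets zeros (and
  is recorded in the block's `missing_expression` attribute); a gene absent
  from the mutation table counts zero mutations.

All 1,029 columns are then min-max normalized **per column, jointly** —
embeddings, expression aggregates and mutation counts alike — matching the
convention of normalizing the combined feature matrix. Two choices the
convention leaves open are resolved as follows and exposed as arguments
rather than hard-wired: the scaler is *fitted on training rows only* and
merely applied (with clipping to [0, 1]) to held-out rows, because fitting on
all rows leaks test information into training (`minmaxNormalize(fit_rows =)`;
the evaluation protocols default to the leakage-free variant via
`normalize = TRUE`), and whether embeddings are normalized at all is
controlled by simply passing either the embedding block or the integrated
block. Constant columns map to 0.

## The classifier

The deep model is a dense feed-forward network:

    input (5 / 1,024 / 1,029) -> 64 tanh -> 32 tanh -> 1 sigmoid

with L2 penalties on every kernel *and* bias, binary cross-entropy loss, a
Nesterov-accelerated adaptive optimizer (Nadam) at learning rate 0.01, batch
size 16 and zero-mean Gaussian kernel initialization (sd 0.05, biases zero).
The grid that selected these values bolded both 20 and 30 epochs; 30 is the
package default, 20 remains one keyword away, and 100 epochs are used when
retraining on a full dataset before ranking novel candidates
(`classifierConfig(epochs = 100)`). The L2 strength is not pinned by the
selection grid; the default is `1e-3`, configurable. Where a hard label is
needed (confusion counts, the positivity cut when ranking candidates) the
threshold is 0.5; AUC itself never uses it.

Random-forest, gradient-boosting and SVM baselines (via `randomForest`,
`xgboost` and `e1071`, at library defaults unless overridden) expose the
identical `trainClassifier()` / `predictScores()` contract, so every
evaluation protocol is classifier-agnostic. All four kinds are deterministic
given `(data, config, seed)`, and `saveModel()` / `loadModel()` reproduce
scores exactly.

### A numerical note on training

Min-max-scaled inputs are all non-negative, so within any hidden unit every
kernel-weight gradient shares the sign of that unit's back-propagated error.
An adaptive optimizer normalizes per-coordinate steps, which turns those
perfectly sign-correlated gradients into a coherent common-mode random walk
of each unit's entire weight vector; at a thousand inputs per unit this walk
is large enough to saturate the tanh layer and stall training at the origin
saddle (where coupled L2 decay then parks it). The trainer therefore centers
the inputs by their column means before optimization — an equivalent
reparameterization, absorbable into the first-layer biases, with the centering
vector stored in the fitted model and re-applied at prediction. With
centering, the configuration above trains to perfect accuracy on strongly
separated synthetic data at the full 1,029-dimensional input.

## Evaluation protocols

**ROC/AUC.** `rocAuc()` computes the area under the ROC curve through the
rank (Mann–Whitney) statistic with midranks for ties. This is provably equal
to the trapezoidal area under the (FPR, TPR) curve swept over all thresholds
— with `FPR = FP / (TN + FP)` and `TPR = TP / (TP + FN)` — and to the
probability that a random positive outranks a random negative with ties
counted one half; the test suite checks the equality against a brute-force
all-pairs oracle at `1e-12`. An AUC on single-class labels is undefined and
raises an error rather than returning a default.

**Stratified 10-fold CV.** `stratifiedKfoldCV()` assigns folds per class
(rotating the assignment cycle across classes so total fold sizes differ by
at most one), trains on nine folds, scores the held-out fold, and averages
the per-fold AUCs. Fold-specific model seeds derive from the fold index, so
the procedure is reproducible while folds remain independently initialized.

**Disjoint-negative protocol.** For comparison settings where ten
pairwise-disjoint negative sets each match the single positive set in size,
`disjointNegativeProtocol()` runs one repetition per negative set: combine,
stratified 70/30 split (per class, the test portion is the ceiling of 30%),
train, record the test AUC, average over the ten repetitions.

**Y-randomization.** `yRandomization()` keeps the feature vectors fixed,
shuffles the label vector, retrains, and evaluates each refit on the held-out
portion of a stratified 70/30 split (the split ratio follows the comparison
protocol; the evaluation is on held-out data because in-sample fit is exactly
what label shuffling inflates). Performance is measured as the coefficient of
determination R² between held-out labels and predicted scores — computed on
scores, not hard labels, so near-misses and confident errors are
distinguished; shuffled refits typically land at low or negative R². The
p-value is the exact permutation form `(1 + b) / (1 + N)`, with `b` the
number of permuted R² values at or above the original — chosen over a
parametric z-test because it is exact under exchangeability and makes no
distributional assumption. A permutation that leaves a single class in the
training or test portion is redrawn.

**Candidate ranking.** `rankCandidates()` keeps unlabeled genes scoring at or
above 0.5 (the natural sigmoid midpoint; the positivity cut is not otherwise
pinned), sorts by descending probability with ties broken by ascending gene
symbol (a pure function of its inputs), and returns at most `top_k`
candidates, 10 by default. The training-fitted min-max scaler is re-applied
to the unseen pool rather than refitted there, keeping the pool's score scale
commensurate with training.

## The synthetic-data generator

`simConfig()` + `simulateLabeledFeatures()` generate integrated feature sets
with known ground truth:

* the embedding block is a pair of spherical unit-variance Gaussians whose
  means are `embedding_separation` (δ) apart — with identity covariance that
  gap **is** the Mahalanobis distance, so the optimal linear score has the
  closed-form AUC Φ(δ/√2): a positive-minus-negative score difference is
  N(δ², 2δ²). The test suite verifies the empirical AUC against this closed
  form within 0.01 at 2,000 genes, a limit check on the whole
  feature-to-AUC path;
* expression is log-normal (meanlog `log(100)`, sdlog 1 — a right-skewed,
  strictly positive support, as real expression matrices have) with a
  multiplicative positive-class shift of `exp(omics_effect)` over
  `n_patient_samples` (default 10, the per-cancer cohort size used for the
  omics queries);
* mutation counts are Poisson at per-sample rates 0.15 (positives) and 0.05
  (negatives) by default — targets are enriched for mutated genes, so the
  default generator is deliberately *not* class-exchangeable; exchangeability
  checks set `omics_effect = 0` and equal rates explicitly.

`simulateSequences()` emits uniform-random 20-letter protein sequences
(lengths 50–500 by default), `simulatePuPool()` plants a known number of
positive-class rows inside an otherwise negative pool, and
`simulateInputTables()` writes every consumed file format (FASTA, expression
TSV, MAF-like TSV, DTI CSV, biomarker CSV, gene-pool CSV) so the whole
pipeline — including the command-line driver in `inst/cli/targetcli.R` — runs
end-to-end offline.

What the generator does **not** emulate: sequence homology or motif
structure (mock embeddings carry no information about the sequence beyond
identity), expression batch effects and gene–gene correlation, and realistic
mutation spectra. Passing tests therefore certify the pipeline's mechanics,
contracts and statistical calibration — not that any particular AUC is
attainable on real cohorts, which depends on the real embeddings and omics
data.

## Problem sizes and runtime choices

The test suite exercises the classifier at the full 1,029-dimensional input
where the claim concerns that dimension (10-fold CV at 200 genes per class),
and at reduced embedding dimensions (16–64 columns) where the claim is about
protocol mechanics, using 25–60 genes per class and 5–15 epochs; the
Y-randomization null calibration runs 20 trials of 100 permutations each at
30 genes per class. Reduced-dimension blocks carry non-canonical names
(`"embedding16"`, `"integrated64"`, ...) — only the canonical names
`embedding`/`omics`/`integrated` enforce the 1,024/5/1,029 column contract.

## Known limitations

* The reference protein-language-model backend is consumed, never computed:
  rankings on real data require an externally produced embedding cache.
* Balanced training ignores the true class imbalance of the genome; scores
  are therefore not calibrated probabilities of being a target in the wild.
* Negative "labels" are unlabeled genes; evaluation AUCs on such data are
  lower bounds with respect to hidden positives.
* The Y-randomization p-value resolution is bounded below by
  `1 / (1 + n_perm)`.
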