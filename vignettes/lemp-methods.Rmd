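---
title: "Predicting lysine malonylation sites with lemp: models, data handling and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine malonylation sites with lemp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lysine malonylation (Kmal) is a post-translational modification detected at a
small fraction of the lysines in a proteome. Given a protein sequence, the
prediction task is binary: is the lysine at a given position malonylated?
`lemp` scores each candidate lysine from the 31-residue sequence window
centered on it (15 residues each side, `'-'` padding where the protein
terminates) and combines two complementary classifiers:

* **RF_EAAC** — a random forest (1000 trees) on the *enhanced amino-acid
  composition* (EAAC) encoding: the frequencies of the 20 amino acids counted
  in an 8-residue window slid across the peptide, giving
  (31 − 8 + 1) × 20 = 480 position-resolved composition features such as
  `G[-5,2]`.
* **LSTM_WE** — a recurrent network that reads the window one residue at a
  time. Each of the 21 window symbols (20 amino acids + gap) is mapped to a
  learned 5-dimensional embedding, fed through an LSTM with 32 hidden units,
  a 128-unit ReLU dense layer, and a single sigmoid output. Training uses
  binary cross-entropy, Adam, mini-batches of 512, up to 300 epochs, and
  dropout 0.2 after the recurrent and dense layers.

The final score integrates the two by logistic regression:

log S/(1 − S) = w₁·C₁ + w₂·C₂ + b,

with C₁ the LSTM score, C₂ the forest score, and (w₁, w₂, b) fitted by plain
maximum likelihood (`glm`) on *out-of-fold* component scores from a
protein-grouped cross-validation, so the weights are never estimated on
scores the component models produced for their own training windows.

## Dataset construction

`build_dataset()` implements a five-stage pipeline from sequences plus a site
table to labeled windows:

1. **High-confidence filtering.** Positive sites are retained only when their
   identification score is strictly greater than 50 and their localization
   probability strictly greater than 0.75; positives with missing scores are
   rejected with a warning. Negatives (all other lysines on the same
   proteins) pass through.
2. **Redundancy reduction.** Proteins above 30% pairwise identity are
   clustered greedily (longest-first seeds, shared-5-mer prefilter, global
   alignment identity = matched positions / shorter-sequence length). Within
   each cluster the member with the most positive sites is kept as
   representative (ties: longer sequence, then lexicographically smaller id).
   A representative's negative lysine is dropped — not relabeled — when a
   positive site elsewhere in the cluster carries an identical center 7-mer,
   a conservative stand-in for "the aligned counterpart is modified".
   `cluster_proteins(precomputed = ...)` accepts assignments from external
   tools such as CD-HIT when exact replication of their output matters.
3. **Conflict removal.** Any center 7-mer (positions −3..+3) occurring in
   both a positive and a negative window removes every window carrying it.
   The operation is idempotent.
4. **Window extraction** at odd sizes (default 31), with `'-'` padding.
5. **Protein-grouped splits.** Both the 80/20 train/test split and the
   k-fold CV assign whole proteins to one side, so homologous windows never
   leak across the boundary. Fold assignment is protein-level (not
   peptide-level): this matches the leakage-avoidance motivation of the
   protein-level train/test split, and is the convention used everywhere in
   the package.

Rare one-letter codes (B, Z, U, O, J) are sanitised to `X`, which is counted
in window length but contributes to no composition feature; for the token
alphabet the pipeline maps `X` to the gap id.

## The native deep-learning implementation

The LSTM and CNN classifiers are implemented directly in R (forward pass,
backpropagation through time, Adam, inverted dropout), vectorised over
mini-batches so the heavy lifting is BLAS matrix multiplication. Every
gradient is verified against central finite differences in the test suite
(relative error below 1e-5 for dense paths, 1e-3 for the embedding path).
Weight initialisation follows common practice (Glorot-uniform input weights,
orthogonal recurrent weights, forget-gate bias 1, embeddings uniform in
±0.05); the Adam step size defaults to 0.001. These choices, and the seeds,
are recorded in each saved model's metadata. Training is exactly
reproducible from the seed: weight initialisation, shuffling and dropout all
draw from one seeded RNG stream, and inference disables dropout, so repeated
prediction is bit-identical.

The CNN comparator (embedding → four 1-d convolution layers, 64 filters of
width 5, ReLU, same padding → global max pooling → sigmoid) uses filter
counts and kernel sizes that are free parameters of this package; they are
deliberately modest and documented rather than tuned.

Deep models serialise to JSON at full double precision (round-trip
predictions agree to ≤1e-6); forests keep their fitted state in an RDS file
beside the JSON metadata. The forest score is the averaged per-tree class
probability by default; a vote-fraction option exists. Candidate features
per split default to √d — the bagged-unrandomised alternative (mtry = d) is
available but makes trees highly correlated and is not the default.

## The synthetic study conditions

Because real malonylation compendia cannot be bundled, every claim the
package tests is grounded in `generate_proteome()`, whose defaults define
the package's standard study conditions:

* 2000 proteins, Poisson lengths with mean 80 (floor 15), residues i.i.d.
  uniform over the 20 amino acids (an option accepts empirical frequencies;
  uniform keeps the analytic expectations simple);
* 25% of lysines labeled positive;
* a planted motif mirroring the sequence pattern around real Kmal sites:
  glycine enriched (+3.5 log-odds) at offsets −4..+2 and lysine depleted
  (−3.5) at −1..+2 around positives, glutamic acid enriched (+1.75) at
  −4..+4 except −1/+3 around negatives — implemented as per-position
  categorical resampling of the flanks. Neighbouring site centers are
  protected from resampling, with one deliberate exception: at offsets whose
  motif explicitly depletes lysine, resampling may overwrite a neighbouring
  site's central K (that site is then dropped from the table). Without this,
  flank lysines would consist almost entirely of protected centers and the
  planted depletion would be invisible in window statistics — whereas around
  real modified sites the neighbourhood genuinely holds fewer lysines;
* 5% of proteins duplicated with 5% point mutations, to exercise the
  clustering stage;
* identification-score stand-ins drawn from N(110, 40) and Beta(8, 1.5), so
  a realistic minority of positives fails the high-confidence filter. These
  are statistical stand-ins, not a model of mass-spectrometry evidence.

Two emergent properties of this generator are worth knowing. First, because
lysines occur at ~1/20 frequency, sites often fall within 15 residues of one
another; flank resampling of one site then contaminates a neighbour's
window. This interference caps the achievable separability: the effect
sizes above were calibrated once against the generating-model
log-likelihood-ratio oracle so that the planted signal supports AUC ≈ 0.95
at the information limit, leaving trained classifiers headroom above the
0.85 mark the end-to-end checks use. Second, *depletion* motifs carry much
weaker univariate composition signal than enrichment motifs (a residue
falling from ~5% to ~1% shifts counts far less than one rising to ~50%), so
depletion features sit at the margin of a top-30 information-gain ranking;
`planted_eaac_features()` therefore scores recall over enrichment features
by default, while depletion pairs are asserted through the two-sample-logo
statistics (direction `"depleted"`), where they are recovered decisively.

What passing these tests shows — and does not show. The generator produces
i.i.d. backgrounds with a stationary, position-factorised motif; real
proteomes have domain structure, compositional autocorrelation, homology
beyond near-duplicates, and label noise correlated with detectability.
Recovery of the planted signal validates the machinery (encodings, models,
ensembling, statistics), not field performance on real proteomic data.

## Evaluation measures

`metrics()` computes Ac, Sn, Sp and MCC from a confusion table obtained
under a strict-greater call rule (a score exactly at the threshold is a
negative call). MCC with a zero denominator factor is reported as 0, with a
message. `roc_auc()` sweeps thresholds over distinct scores (ties grouped)
and integrates by trapezoids, which equals P(score⁺ > score⁻) + ½P(tie);
this identity is asserted against an exhaustive pairwise oracle. `auc01()`
reports the *unnormalised* trapezoid area over FPR ∈ [0, 0.1] (maximum 0.1)
with linear interpolation at the right edge — the same magnitude convention
as published partial-AUC values such as 0.026 — with a normalised option off
by default. The default operating point is the smallest threshold reaching
specificity 0.90 on the training data, stored in each model bundle and
overridable at prediction time.

## Interpretation analyses

* `two_sample_logo()` compares per-position residue occurrence between
  positive and negative windows with an unpooled two-proportion z-test (the
  large-sample equivalent of the t-test on 0/1 indicators), switching to
  Fisher's exact test when an expected count falls below 5, and applies
  Bonferroni correction over the full 600-cell family (30 positions × 20
  residues; the constant center is excluded).
* `information_gain_ranking()` ranks features by IG in bits, discretising by
  supervised minimum-description-length (Fayyad–Irani) binning with an
  equal-frequency 10-bin fallback; features where no cut passes the MDL
  criterion get IG 0. Ties break lexicographically by feature name.
* `cluster_embeddings()` performs average-linkage hierarchical clustering of
  the 20 learned amino-acid embedding rows on Euclidean distances (the gap
  row is excluded); `dendrogram_newick()` exports the tree.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the full pipeline at the
default 2000-protein conditions (≈6000 windows after redundancy reduction),
train the forest at its full 1000 trees, and train the LSTM for 30 epochs
for the held-out checks and 15 epochs inside the 5-fold ensemble
cross-validation — enough for the loss to flatten on data of this size while
keeping a complete run in minutes on one CPU. The null-generator control
uses 800 proteins, and the ensemble-recovery check 20,000 simulated score
pairs. Larger settings (300 epochs, 10 folds) are the defaults users get.

## Known limitations

* The internal greedy clustering approximates, but does not replicate,
  CD-HIT; identity is computed from a single global alignment.
* Aligned-counterpart exclusion uses exact center-7-mer matches, which is
  conservative; a full multiple alignment would catch more counterparts.
* Whether the published EAAC shrank the denominator near termini is not
  derivable from its definition; this implementation fixes the denominator
  at the slide length (gaps dilute composition), keeping feature scales
  comparable across terminal and internal windows.
* The deep models run on CPU only and are practical to tens of thousands of
  windows, not millions.
* The AAindex screening operates on whatever property table the user
  supplies; the package bundles only a synthetic example of the flat-file
  format, not the AAindex database.
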