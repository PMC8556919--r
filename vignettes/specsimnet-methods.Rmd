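---
title: "Predicting structural similarity from MS/MS spectra: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting structural similarity from MS/MS spectra: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tandem mass spectrometry fragments an ionized compound and records a peak
list of fragment m/z values and intensities. Two compounds with similar
structures tend to produce overlapping fragments, which is why spectral
similarity is widely used as a proxy for chemical relatedness — in spectral
library matching, analogue search and molecular networking. Classical
measures (cosine and its precursor-mass-shifted variants) quantify shared
peaks directly; they work well for nearly identical spectra but correlate
loosely with *structural* similarity as chemists measure it, namely
fingerprint similarity: the Tanimoto (Jaccard) or Dice coefficient between
binary substructure fingerprints of the two molecules.

`specsimnet` trains a regression model that maps a *pair* of spectra
directly to the structural similarity of their (unseen) underlying
molecules. The model is a Siamese network: a single "base" dense network
embeds each binned spectrum into a low-dimensional vector, and the head
scores a pair as the cosine of the two embeddings. Training minimizes the
mean squared error between that cosine and the fingerprint similarity of
the two annotated compounds.

## Data preparation

Spectra are read from MGF, MSP or an internal JSON dialect and pass a
selection step: positive ionization mode, a layout-valid InChIKey plus at
least one structure string, and at least 5 peaks with m/z in [10, 1000] Da
(the bound is treated as closed; the convention is stated because library
sources differ). Each retained spectrum is then

1. peak-filtered: peaks below 0.1% of the base-peak intensity are dropped
   and at most the 1000 most intense peaks kept;
2. normalized to unit base-peak intensity and square-root transformed
   (damping the dominance of the strongest peaks). Both scales are kept:
   the pre-transform scale drives the augmentation rule below;
3. binned onto a fixed grid of 10,000 equal bins over [10, 1000) m/z,
   half-open with floor indexing; several peaks in one bin max-pool.

Bins never occupied in the training corpus are removed from the input
vector ("known bins"). At inference, intensity falling into unknown bins or
outside the grid is dropped, and its share of the spectrum's total
transformed intensity is reported as `missing_fraction` — a diagnostic
only; it never modifies scores. Normalization happens *before* the 0.1%
filter and the transform, so the augmentation threshold of 0.4 (see below)
refers to a well-defined scale.

## Labels

Compounds are identified by the first 14 InChIKey characters (2D structure,
stereochemistry disregarded). Per compound the most common structure string
is chosen (ties broken by the lexicographically smallest string, for
determinism), a 2048-bit fingerprint computed — topological ("daylight")
or circular (Morgan radius 2 or 3) — and the K×K matrix of pairwise
Tanimoto or Dice scores cached as the label matrix. Fingerprint bits are
toolkit-specific; the toolkit version is recorded in the matrix metadata.
An all-zero fingerprint pair is defined to score 0 (avoiding 0/0); the
matrix diagonal is 1 by definition. Fingerprints of real structures are
computed with RDKit through the system Python; precomputed fingerprints can
be supplied instead, which is how the synthetic fixtures bypass chemistry
entirely.

## Balanced pair sampling

Across all spectrum pairs the label distribution is heavily skewed toward
low similarity, so uniform pair sampling would teach the model little about
the high-similarity regime. The generator therefore visits every spectrum
once per cycle as an anchor, draws one of 10 equal score bins uniformly,
and samples a partner whose label with the anchor falls inside the bin.
An empty bin is widened by 0.1 on both edges per iteration until a label
falls inside; widening terminates because the full [0, 1] interval always
contains a label. Bin edges are half-open, the last bin closed at 1.
Partner sampling is two-stage by default (uniform over eligible compounds,
then uniform over that compound's spectra) so that heavily re-measured
compounds are not over-weighted; a spectrum-uniform mode is available as a
configuration switch. An anchor may pair with a different spectrum of its
own compound (realizing labels of 1.0) but never with itself. The
validation stream uses a fixed seed and, by convention, 10 cycles.

## Augmentation

Three operators perturb each binned spectrum independently on both sides of
every training pair, in order: (1) removal — of the non-zero bins whose
*pre-transform* intensity is below 0.4, a uniformly drawn fraction in
[0, 20%] is zeroed; (2) jitter — every remaining non-zero post-transform
value is multiplied by a factor uniform in [0.6, 1.4] (the multiplicative
reading of "±40%"; the additive reading is possible but interacts badly
with the unit-maximum normalization); (3) addition — a uniform count in
[0, 10] of zero bins is set to values below 0.01. The two pair members
draw independently.

## Architecture and training

The base network is input → dense(500) → dense(500) → dense(200,
linear output), with L1 and L2 penalties (10⁻⁶ each) on the first dense
layer's weights, batch normalization after each dense layer except the
output, and dropout (rate 0.2) in the layers after the first. Choices the
reference description leaves open, fixed here and exposed in
`model_config()`: hidden activation is ReLU applied before batch
normalization (the common dense-ReLU-BN-dropout stacking); batch-norm uses
ε = 10⁻³ and running-average momentum 0.9; Adam uses β₁ = 0.9, β₂ = 0.999,
ε = 10⁻⁷. The head is parameter-free: the cosine of the two embeddings,
reported raw (not clipped to [0, 1]; clipping is available as a flag).

Training uses Adam (learning rate 0.001), batch size 32, MSE loss, one
generator cycle per epoch, and early stopping: training halts once the
validation loss has not improved for 5 consecutive epochs, and the
best-validation weights are restored (restoration is the standard reading
of patience-based stopping and can be disabled). Training and validation
pools must not share a compound key; the trainer enforces this. All
randomness — weight init, pair sampling, dropout, augmentation — derives
from one seed, and the forward/backward pass is plain single-threaded
matrix code, so runs are bit-reproducible.

The network and its backpropagation (dense, batch-norm, ReLU, dropout,
cosine head) are implemented directly in base R matrix operations: no
neural-network framework exists in the package's dependency stack, the
architecture is small, and an explicit implementation keeps the training
path fully deterministic and testable (gradients were verified against
central differences during development; the test suite retains an
overfitting capacity check).

## Monte-Carlo-dropout uncertainty

Keeping dropout active at inference samples an ensemble of perturbed
networks. Per spectrum, n = 10 embeddings are drawn (seeded per spectrum
identifier, so a spectrum's draws are identical across pairings); a pair
yields n² = 100 cosine samples summarized by their median (robust to
outliers) and interquartile range (IQR, 25–75%), the uncertainty measure.
Quantiles use the linear-interpolation convention — this matters because
IQR values are compared against thresholds. Filtering retains scores with
IQR strictly below a threshold; the retained fraction is the retrieval
rate. Embeddings are computed per spectrum, never per pair, so ensemble
scoring of an m-spectrum library costs m·n forward passes.

## Evaluation

`all_vs_all()` embeds each spectrum once and scores all m(m+1)/2 unique
pairs including self-pairs (that count is what the pair-counting identity
checks); error statistics and precision/recall exclude self-pairs, which
are uninformative. `binned_errors()` reports RMSE/MAE per true-label bin
(10 equal bins, last closed at 1; empty bins report NA, never 0).
`precision_recall_high_similarity()` defines "related" as true label
above a threshold (default 0.6) and sweeps a predicted-score threshold X:
precision is the related fraction of the selection (NA on an empty
selection), recall the selected fraction of all related pairs.
`aggregate_same_compound()` medians all spectrum-pair scores per compound
pair and can drop compound pairs with high IQR, reporting the retained
fraction.

## The synthetic world

Real training corpora are large, external and chemically redundant; the
package instead ships a generator whose output is a *stated world* with a
planted, tunable correlation between spectral content and fingerprint
similarity:

- compounds come in clusters: each cluster has a seed fingerprint
  (256 bits, 10% density) and members are per-bit mutations of it
  (flip probability 0.05), mimicking compound families that share a
  scaffold;
- every active bit maps deterministically (seeded hash) to 2 fragment m/z
  values in [10, 1000] Da, so fingerprint overlap literally becomes peak
  overlap — the planted signal;
- per compound, 3 replicate spectra with log-normal intensity noise
  (sdlog 0.1) and 3 low-intensity uniform noise peaks emulate repeated
  measurements.

Defaults (40 clusters × 5 members) give a library of 200 compounds with
labels spanning all score bins: cross-cluster pairs ≈ 0.05, within-cluster
pairs ≈ 0.4–0.7, replicate pairs 1.0. What the generator deliberately does
*not* emulate: chemically realistic fragmentation cascades, precursor-mass
structure, instrument-type batch effects, or class imbalance across
compound superclasses. A green learnability test therefore establishes that
the pipeline can recover a planted spectrum–structure relationship at desk
scale — not that the architecture reaches any particular accuracy on real
libraries.

For the desk-scale learnability check (a miniature model — 1000 bins,
hidden layers of 64, embedding 32 — must beat 0.6× the RMSE of the best
constant predictor on held-out compounds) the library is reshaped to
20 clusters × 10 members (200 compounds; 150/25/25 train/validation/test)
with mutation rate 0.01. Two capacity arguments fix these numbers a
priori rather than by trial:

1. *Cluster count versus embedding dimension.* A 32-dimensional embedding
   holds at most 32 mutually orthogonal directions; with many more
   clusters than dimensions, cross-cluster cosines cannot approach their
   near-zero labels (random codes give |cos| ≈ 1/√32 ≈ 0.18), so the
   cluster count must stay clearly below 32.
2. *Rank-32 representability floor.* Any cosine-of-embedding model is
   bounded below by the best rank-32 unit-diagonal approximation of the
   training label Gram matrix, computable by eigendecomposition. The
   within-cluster detail created by mutation raises that floor (floor
   ≈ 0.094 / 0.054 / 0.033 at mutation 0.05 / 0.02 / 0.01 in this
   geometry, against targets around 0.10–0.13). A small network trained
   with a desk-scale step budget lands at a multiple of its floor, so the
   world must leave a clear margin between floor and target; mutation
   0.01 provides ≈ 3.8×.

Two further points of procedure matter at this scale. First, the known-bin
reduction is fitted on the *training* split only — bins that only held-out
compounds occupy would otherwise feed never-trained random first-layer
weights and inject noise into held-out embeddings. Second, the miniature
recipe (dropout 0.05, learning rate 0.005, a fixed budget of 900 one-cycle
epochs, final weights kept) compensates for the tiny step budget
(15 batches per epoch versus thousands at full scale) with more epochs,
and does not rely on patience-based model selection: its few-hundred-pair
validation stream is far noisier than a full-scale one, making the
patience rule (which remains the package default, with the usual patience
of 5) stop too early and select mediocre checkpoints. The recipe is
exercised end-to-end by the test suite.

Desk-scale training remains seed-sensitive: across three library seeds the
held-out-to-constant RMSE ratio of this recipe varied roughly between 0.45
and 0.7. The test suite runs the one fixed, fully deterministic world it
states; the variability is a property of miniature training, not of the
pipeline, and disappears with larger libraries and step budgets.

## Numerical conventions and degenerate inputs

- Quantiles: linear interpolation (type 7) everywhere.
- Zero-norm embeddings make cosine undefined: `score_pair()` errors;
  ensemble scoring skips such draws with a warning and errors only if all
  draws are degenerate.
- An all-zero binned vector embeds without error (bias- and batch-norm
  driven).
- Empty label bins in error reports are NA, never 0; precision of an empty
  selection is NA, never 1.
- Model archives store weights as JSON with 17 significant digits, which
  round-trips IEEE doubles exactly; loading verifies an archive version
  tag, the presence of the binning scheme, and the input-dimension
  invariant.

## Known limitations

- The dense-network engine is plain R: perfectly adequate at the scales the
  package targets (thousands of spectra, hundreds of input bins), but not a
  GPU replacement for training on full public libraries.
- Scores are model-dependent: retraining with other data or seeds changes
  them; archives carry config, binning scheme and label metadata so results
  are attributable to a specific model.
- Fingerprint bits depend on the chemistry toolkit release; label matrices
  record the toolkit version and should not be mixed across versions.
- The sampler guarantees termination but not exact bin balance when entire
  score ranges are unpopulated; the flattening is relative to the raw pair
  distribution.
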