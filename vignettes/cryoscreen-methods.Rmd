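---
title: "Few-shot micrograph quality screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot micrograph quality screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A cryo-EM session produces thousands of micrographs, a sizeable fraction of
which are unusable: crystalline (non-vitreous) ice, surface contamination,
stage drift, or support-film edges in the field of view. Screening them by
hand is tedious; training a conventional classifier needs hundreds of labels
and has to be redone whenever the detector, grid type or sample preparation
changes. `cryoscreen` implements a few-shot alternative: learn a metric
embedding from a handful of labeled micrographs per class, then classify new
micrographs by k-nearest-neighbour voting in that embedding space.

Quality information lives in both domains: contamination and film edges are
real-space features, while crystalline ice and drift are most visible in the
power spectrum (sharp Bragg-like peaks; anisotropic damping of Thon-ring
texture). Each micrograph is therefore represented by crops together with
their centered log-scaled power spectra, and the network has two input
streams, one per domain.

## Pipeline

1. **Preprocessing** (`normalize_intensities`, `extract_crops`,
   `power_spectrum`). Intensities are clipped at `clip_sigma` (default 5)
   standard deviations — a hot-pixel guard — and standardized to mean 0,
   sd 1. By default four crops per micrograph are taken from a centered
   2 x 2 grid of non-overlapping windows (0-based, half-open pixel ranges);
   each crop's spectrum is `log(1 + |FFT|^2)` with the DC bin shifted to the
   center pixel. Crops and spectra are bilinearly resized to the model input
   size and standardized per channel. Four crops per micrograph matches the
   crop-to-micrograph count ratio used throughout evaluation. Crop size
   defaults to 512 px (resized to 224) for real data and 128 px (resized to
   64) in the bundled synthetic world; the crop geometry is configurable
   because no canonical value exists.
2. **Embedding model** (`build_model`, `embed_crops`). Two backbone streams
   with unshared weights — real-space textures and Fourier textures are
   statistically unlike, so shared early filters would be a poor prior —
   feed concatenated features into a head of linear(256) / ReLU /
   dropout(0.5) / linear(128) / batch norm. Embeddings are plain 128-d
   vectors compared by Euclidean distance; no L2 normalization is applied.
   The `tiny_cnn` backbone (4 conv blocks, ~100k parameters) trains on a CPU
   in minutes and is used by every test; `resnet18` (stem + 8 basic blocks,
   built from the same layer primitives) is the documented full-scale
   choice. ImageNet initialization is exposed as a config flag but errors in
   this offline build, where weight downloads are unavailable.
3. **Triplet training** (`train_triplet`). Batches of P = 2 classes x K = 8
   crops (sampled with replacement when an episode holds fewer crops) are
   embedded in train mode; batch-hard mining picks, per anchor, the farthest
   same-class and nearest other-class sample; the mean hinge loss
   `max(0, d(a,p) - d(a,n) + margin)` on squared Euclidean distances is
   minimized with Adam at learning rate 1e-4. The margin defaults to 0.2
   (the common metric-learning convention; no canonical value exists for
   this task). An epoch is a fixed 20 batches — episode pools are tiny, so a
   "data pass" is not meaningful — and the best checkpoint is kept by
   validation micrograph-level AUPRC with early-stopping patience 10 over at
   most 100 epochs (tests and the acceptance run scale this down to ~8
   epochs; see below).
4. **Inference** (`knn_classify_crops`, `aggregate_micrographs`,
   `select_k`). Crop embeddings are classified against the support set (all
   crops of the episode's training micrographs, embedded in eval mode) by
   k-NN; k is chosen from {1, 3, 5, 7, 9} by validation micrograph-level
   AUPRC, ties to the smallest k. Micrograph decisions are majority votes
   over crop labels with ties resolved to "bad" — the conservative choice
   for a screening tool, where discarding a good micrograph is cheaper than
   keeping a bad one. The same rule is applied one level down: a tied
   neighbour vote labels the crop "bad". The continuous micrograph score
   used for precision-recall analysis is the mean crop good-fraction, the
   minimal choice consistent with the voting rule. `average_micrograph_embeddings`
   provides micrograph-level embeddings (crop means) for embedding-space
   analysis.
5. **Evaluation** (`make_splits`, `sample_episode`, `average_precision`,
   `auprc_gain`, `run_experiment`). Splits are stratified at the micrograph
   level so every crop inherits its parent's split — the leakage guard.
   AUPRC is step-wise average precision with tied scores processed as one
   block: block precision is computed after including the whole block and no
   interpolation is applied. This convention is load-bearing: it makes a
   constant-score (collapsed) classifier score exactly the positive-class
   prevalence, so AUPRC divided by the majority-class proportion — the
   *Gain* — equals exactly 1.0 for a collapsed classifier and exceeds 1.0
   only with genuine discrimination. The positive class is "good"
   throughout, and the majority proportion is measured on the fixed test
   split. Experiments run over a shot grid with three seeds; aggregate rows
   are arithmetic seed means.

## The synthetic world

Real evaluation data (EMPIAR-scale exposures) cannot ship with a package,
so `cryoscreen` includes a seeded generator whose output exercises every
stage. A "good" micrograph is low-pass-filtered Gaussian noise (unit DC
gain, sd = `noise_sd`) with Poisson-placed soft dark discs standing in for
particles. A "bad" micrograph starts from the same background and applies
one analytic defect operator:

* *ice_crystallinity* — a two-frequency sinusoidal lattice (non-collinear
  wave vectors), giving sharp Bragg-like spectral peaks;
* *contamination* — one or more soft-edged dark ellipses covering at least
  10% of the field;
* *drift* — convolution with a line kernel of length `image_size / 8` at a
  random angle, giving a strongly anisotropic spectrum;
* *support_film* — a high-contrast straight intensity step.

Defect amplitudes default to 3 x `noise_sd`: clearly separable yet embedded
in noise, which keeps the few-shot tests well-posed (a Fisher-score
separability check is part of the test suite). Streams are keyed by
(seed, label, kind, index), so datasets are reproducible and extensible
without reshuffling existing items, and pixels are snapped to float32 so
MRC round-trips are bit-exact.

These are analytic stand-ins, not physics: there is no contrast transfer
function, no dose model, no detector response, and defect severities are
free parameters. A green test therefore establishes that the pipeline
learns and evaluates correctly on controllable contrast — not that any
particular performance level transfers to real exposures.

## Numerical choices and degenerate inputs

* Zero-variance grids standardize to all zeros rather than NaN.
* `log(epsilon + |F|^2)` uses epsilon = 1.0 on raw counts; spectra are then
  standardized like real crops, so the epsilon scale is not load-bearing.
* Distance ties in k-NN break toward the lower support index; performance
  ties in `select_k` toward the smaller k; argmax ties in batch-hard mining
  toward the lower index (`which.max` semantics).
* Batch norm uses population statistics within a batch, running statistics
  (momentum 0.1) in eval mode; eval-mode embeddings are therefore
  deterministic and independent of batch partitioning.
* A single-class batch yields no triplets and the step is skipped; a
  single-class training set is rejected outright.
* `max_epochs = 0` returns the initial weights with an empty history.
* Backpropagation is exact and verified against central finite differences
  in the test suite.

## Scaled-down testing and what it establishes

The bundled end-to-end acceptance world uses 256 px micrographs, a test
split of 88 good / 22 bad (majority proportion 0.8, mirroring the
imbalance of public screening datasets), the tiny_cnn backbone at 64 px
input, and seeds {0, 1, 2}. Training cells run 8 epochs x 20 batches —
scaled down from the 100-epoch default purely for CPU budget. With this
world, 5-shot triplet training must beat the collapsed baseline
(mean micrograph-level Gain > 1.05). At 1-shot, the unweighted
cross-entropy baseline — same backbone, 2-way softmax head — concentrates
its predictions heavily on the majority class (at least 90% of test
micrographs predicted "good" in every seed, with recall(bad) far below the
triplet model's), while the triplet model keeps recall(bad) > 0. The
stricter form of the failure mode, literally one predicted class for every
test micrograph, does not reproduce in this synthetic world: its analytic
defects are strong enough that even four crops of one bad micrograph
partially generalize, and the corresponding acceptance expectation is left
red rather than weakening the generator to force it. GPU-scale claims
(ResNet18 at 224 px on real archives) are deliberately out of scope.

## Known limitations

* The generator's defect taxonomy is coarse; real "bad" categories overlap
  and co-occur.
* `resnet18` is architecturally faithful but never trained in tests; no
  pretrained weights are available offline.
* Checkpoints are RDS files; they are versioned but not portable across
  incompatible package versions.
* The CLI accepts JSON configuration only.
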