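---
title: "Multi-class fusion attention networks for motor imagery EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-class fusion attention networks for motor imagery EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a limb movement — modulates
band-limited EEG power over sensorimotor cortex: event-related
desynchronization and synchronization (ERD/ERS) in the mu (8–12 Hz) and beta
(12–30 Hz) rhythms, with scalp topographies that differ between imagined
effectors. Classical decoders exploit this with the Common Spatial Pattern
(CSP) algorithm: given trial covariance matrices of two conditions,
\(\Sigma_i\) and \(\Sigma_j\), CSP finds spatial filters \(w\) maximizing the
variance ratio \(w^\top\Sigma_i w / w^\top\Sigma_j w\), solved as the
generalized eigenproblem \(\Sigma_i w = \lambda \Sigma_j w\). Filter-bank CSP
(FBCSP) repeats this per 4-Hz sub-band of 8–32 Hz and classifies the
log-variance of the projected trials.

Two structural losses motivate the method implemented here. First, the
one-vs-rest multi-class extension of CSP solves `K` independent binary
problems whose outputs never meet in one feature space. Second, log-variance
collapses each projected time series to a single energy number, erasing
onset latency, development rate and duration of the ERD/ERS response —
temporal structure that is itself class-informative.

The fusion network addresses both: all `K` one-vs-rest CSP projections from
all `F` sub-bands are applied to every trial and concatenated along the
channel axis into a *virtual channel* representation of
\(D = K \times F \times 2m\) time series (class-major, band-minor,
component-last order), which preserves the full time course. A compact
convolutional network with a channel-attention gate then learns
spatio-temporal features from this spatially pre-optimized representation.

## Pipeline stages and their parameters

**Filter bank.** 8–32 Hz in six contiguous 4-Hz bands. The filter family is
a design choice of this package: a 4th-order Butterworth band-pass per band
(2nd-order prototype), applied forward–backward so the pass is zero-phase
(effective order 8). Each pass starts from the steady state of a step at the
first sample, on top of odd-reflection padding of three filter lengths, so a
constant input produces an exactly transient-free zero output and ERD
latency information is not smeared by group delay. Order and band layout
are configurable (`apply_filterbank()`, `make_bands()`).

**Covariance and CSP.** Trial covariance is the mean-centered outer product
divided by the sample count, plus a relative ridge
\(\varepsilon\,\mathrm{tr}(\Sigma)/C \cdot I\) with
\(\varepsilon = 10^{-8}\), keeping estimates positive definite even with a
flat channel. Per-trial trace normalization is available
(`trace_normalize`) but off by default, following the plain averaged
estimator. The one-vs-rest "rest" covariance pools all non-target trials
with equal trial weight. The generalized eigenproblem is solved by Cholesky
whitening of \(\Sigma_j\) followed by a symmetric eigendecomposition;
columns are ordered `m` largest eigenvalues descending then `m` smallest
ascending, unit-normalized (making filters invariant to global rescaling of
the data) and sign-fixed so the largest-magnitude coefficient is positive —
all so that repeated fits are bit-identical. `2m` may not exceed the channel
count; requesting `m = 12` on a 22-channel montage is a configuration error.

**Backbone.** For an input of one map of `D` virtual channels by `T`
samples: input batch-norm; zero-pad (32, 31) and temporal convolution
(kernel 64) to `F1 = 16` maps; batch-norm; depthwise convolution over the
full channel axis (`D x 1`, groups 16, multiplier 2) to 32 maps; batch-norm,
ELU, average-pool 4, dropout 0.5; zero-pad (7, 8), depthwise temporal
convolution (kernel 16, 32 groups) and pointwise 1x1 to `F2 = 32`;
batch-norm, ELU, average-pool 8, dropout; channel attention; flatten; dense
128 (no bias) + batch-norm + ReLU + dropout; dense `K`. Pooling uses floor
division without padding, so `T = 1000` flattens to `32 x 31 = 992`
features. The attention gate concatenates global average and max pooling of
the 32 maps (64 values) and passes them through one shared bottleneck
64 → 32 → 16 → 32 with a terminal sigmoid, multiplying each map by its gate
— the concat-then-bottleneck form, not the sum-of-two-MLP-passes variant.
Convolutions and the pre-batch-norm dense layer carry no additive bias
(batch-norm absorbs it); no max-norm constraints are applied. The input
batch-norm treats the whole `D x T` map as one feature (a single
scale/shift pair).

Because no deep-learning framework is available to this package's target
environment, the backbone — forward pass, backpropagation through every
layer (including train-mode batch-norm coupling and the max-pool path of
the attention gate), Adam with bias correction, and inverted dropout — is
implemented from first principles in C++ (RcppArmadillo). Activations are
stored time-major so the temporal convolution is a single GEMM over a
contiguous im2col matrix. The implementation is verified against
central finite differences for every layer's parameters and for the input
gradient (`test-network.R`), which also underwrites the gradient-based
importance analysis.

**Initialization and determinism.** Weights draw from fan-in uniform
\(U(-1/\sqrt{n_{in}}, 1/\sqrt{n_{in}})\), biases start at zero, batch-norm
at scale 1 / shift 0. All randomness (initialization, dropout, batch
shuffling) comes from an internal xorshift generator seeded explicitly, so
a seed reproduces losses and predictions bit-identically on one platform.
Training uses Adam (lr 0.001), batch size 32, shuffled batches, cross-entropy
loss, a fixed epoch budget, and no early stopping — early stopping would
require a validation split the protocol does not define.

**Evaluation protocol.** Stratified `k`-fold cross-validation (default 5)
with all data-dependent fitting — covariance estimation, CSP, classifier or
network training — confined to the training split of each fold; the fold
plan and the exact trial indices used for fitting are recorded in the
report so leakage is checkable after the fact. Fold predictions are
concatenated before the confusion matrix is computed, making the aggregate
accuracy exactly `trace/total`. Stratification is a package choice: with
few trials per class, unstratified folds risk class starvation. Paired
comparisons between methods use the paired t-test plus Cohen's
\(d = \bar{\Delta}/s_\Delta\) (paired standardizer; a pooled-SD variant is
available by flag).

**Gradient importance.** In eval mode, the gradient of the true-class logit
with respect to the input virtual channels is averaged (absolute value)
over time and trials, then aggregated by sub-band and by CSP filter class
through the fusion index map, normalized to percentages summing to 100
within a subject — the "which bands and which class's filters does the
network rely on" view. Welch band power (1-s Hann segments, 50% overlap,
trapezoid integration over band bins) provides the raw `C x F` comparison
features, and the 128-dimensional penultimate activations are exported for
any external 2-D projector; the projection itself is out of scope.

## The synthetic study presets

The generator plants exactly the structure the pipeline claims to exploit,
so every stage has a falsifiable target without external recordings. Each
class `k` owns a unit-norm spatial pattern (a random orthonormal set by
default) and a 4-Hz source band; sources are white noise band-passed with
the same filter family as the analysis bank; noise is broadband white noise
mixed through a random `C x C` matrix, i.e. spatially correlated, scaled to
a configured SNR.

* **Mode A (spatial-variance coding)** — the trial's own source carries
  `erd_gain = 4` times the variance of the others. Presets: `easy-A`
  (12 dB SNR) and `hard-A` (0 dB), both 8 channels, 4 classes, 40
  trials/class, 4 s at 250 Hz.
* **Mode B (temporal coding at matched power)** — every source in every
  trial is amplitude-modulated by a time-shifted copy of one raised-cosine
  burst (2 s wide; onsets 0.5/1.0/1.5/2.0 s) and rescaled to exactly unit
  realized variance; the class determines only the rotation that pairs
  sources with onsets. Two designs that look equivalent on paper fail this
  purpose and were rejected after measurement: rescaled ramp envelopes with
  class-specific onsets leak class information through their differing
  magnitude spectra (the modulation sidebands land in neighboring analysis
  bands), and modulating only the trial's own source leaks it through the
  location of the modulation signature. With the rotation design, band
  power is class-blind by symmetry: the FBCSP baseline sits at chance while
  time-resolved decoders separate the classes — the package-level
  embodiment of the claim that discarding temporal dynamics discards class
  information.

What the generator does *not* emulate: volume-conduction forward models,
non-stationary background rhythms, eye/muscle artifacts, inter-session
covariate shift. Passing its tests therefore demonstrates correctness of
the machinery on data satisfying the model's assumptions, not performance
on real EEG.

## Problem sizes and numerical choices

The simulation-backed checks run at the preset study scale (160 trials of
8 x 1000 samples). Fold-averaged network checks use a fixed budget of 12
training epochs — on the presets test accuracy saturates by epoch 10, and
averaging over five folds absorbs an occasional slow start — while the
temporal-B backbone check, which evaluates a single held-out stratified
fold with no such averaging, trains for 20 epochs. The cheap log-variance
baseline is cross-validated fully; its chance-level estimate is averaged
over eight fold assignments, since a single 160-trial cross-validation
carries ~3.4% binomial spread (and overfit linear classifiers on null
features systematically test slightly *below* chance). Unit tests use
miniature copies (6–8 channels, 0.25–2 s) of the same constructions.

Other numerical choices: batch-norm epsilon `1e-5`, running-statistics
momentum 0.1 (unbiased running variance); eigenvalue ties broken by solver
order; degenerate \(\Sigma_i = \Sigma_j\) returns solver-order eigenvectors
with a warning rather than failing; zero-variance virtual channels floor
log-variance at `log(.Machine$double.eps)` with a warning; the shrinkage
LDA behind the FBCSP/CSP baselines (the original FBCSP's feature selection
and classifier are out of scope) estimates its intensity analytically
toward a scaled identity and falls back to full shrinkage, with a warning,
if the within-class scatter is singular.

## Known limitations

* Within-subject decoding only; no cross-subject transfer or session
  adaptation.
* The ablation baseline's "single filter set" is inherently ambiguous in
  the one-vs-rest setting; this package uses the filters of a configurable
  `reference_class` (default 0) and documents that choice rather than
  guessing.
* EDF/GDF ingestion is a thin optional adapter surface (`load_epochs()` is
  the contract); dataset-specific channel selection and artifact rejection
  are left to the caller.
* Training the backbone on a CPU is the dominant cost; the implementation
  favors reproducibility (bit-identical seeding) over parallel speed.
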