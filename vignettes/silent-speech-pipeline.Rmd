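---
title: "Classifying silently articulated letters from chin EMG and piezoelectric signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying silently articulated letters from chin EMG and piezoelectric signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A chin-worn wearable records two channels while a person mouths letters
without vocalizing: a surface-EMG electrode pair captures the electrical
activity of the suprahyoid muscles that drive tongue and jaw motion, and a
piezoelectric (PZT) plate senses the minute low-frequency vibration and
pressure changes of the chin skin. Both channels are sampled at 4096 Hz. The
classification task is to recognize which of the eight most frequent English
letters — E, T, A, O, I, N, R, S — was silently articulated in a single
trial, from 100 recorded trials per letter split 60/20/20 into training,
validation and test partitions.

`silentspeech` implements the full comparison protocol: nine per-channel
signal descriptors, recursive feature elimination, feature-space (SMOTE) and
signal-space augmentation of the training partition, grid-searched SVM /
decision-tree / random-forest baselines, a 1D-convolutional feature
extraction network, a Siamese few-shot classifier driven by a
cosine-similarity loss, and the Parallel Multi-Layer Data Fusion (PMLDF)
architecture that fuses the two sensor streams layer by layer. A seeded
synthetic generator stands in for the recordings, so every stage is testable
end to end.

## The synthetic generator

The generator does not attempt physiological fidelity; it emulates the two
properties of the recordings that the pipeline actually exploits:

* **EMG**: enveloped band-limited Gaussian noise bursts. Each class places
  its main burst in its own frequency band (centres spaced over roughly
  90–384 Hz within the 50–500 Hz surface-EMG range) with class-specific
  onset timing. Because muscle noise is zero-mean, only the band placement
  and the energy envelope are informative — the same property real surface
  EMG has.
* **PZT**: exponentially decaying low-frequency sinusoids (6–34 Hz, well
  under the 100 Hz ceiling of skin vibration), again with class-specific
  frequency and onset.

Per-trial variability is controlled by `jitter` (default 0.1: ±10 %
amplitude scaling and ±50 ms·jitter onset shifts) and an additive white
noise floor at 20 dB SNR. `separability` linearly interpolates every class
template between a shared baseline (0) and the fully distinct motifs (1);
the default 1.0 represents the cleanly articulated, distinct motions of the
study protocol. Trial duration is 1 s (the protocol does not state one; one
second comfortably contains one articulation at 4096 Hz).

The `cross_channel_only` mode builds the eight classes from 4 EMG motifs ×
4 PZT motifs, with every motif reused in exactly two classes. Each single
channel therefore carries at most 4-way information (a ~50 % accuracy
ceiling over 8 balanced classes), while the motif *pair* identifies the
class uniquely — a constructed benchmark in which sensor fusion is provably
necessary, used to demonstrate the PMLDF fusion gain.

What passing tests on this generator shows: that the implementation of every
stage is correct and that the architectures can extract band, timing and
cross-channel structure. What it does not show: robustness to electrode-skin
artifacts, session-to-session drift, or speaker variability in real
recordings.

All randomness flows from one integer seed through per-trial substreams
keyed by (label, trial index), so a dataset is reproducible even if trials
are generated in a different order.

## Features

Nine descriptors per channel, computed over the whole trial as one window
(no sub-windowing): mean absolute value, RMS, variance, waveform length,
zero-crossing count, and — from the raw one-sided DFT magnitude spectrum —
dominant frequency, mean frequency, median frequency and frequency centroid.
Conventions the printed formulas leave open were fixed once:

* variance is the population form (1/N);
* zero crossings use the strict product rule `y_i * y_{i+1} < 0`, so an
  exact zero sample breaks a crossing;
* the printed mean-frequency expression is degenerate, so mean frequency is
  implemented as the *power*-weighted mean of the spectrum and frequency
  centroid as the *magnitude*-weighted mean, keeping the two features
  distinct;
* the DC bin participates in all spectral weights; dominant-frequency ties
  resolve to the lowest frequency; no windowing or detrending is applied
  (a Hann window is available but off by default).

Every feature is pinned to an independent naive-loop / naive-DFT oracle in
the test suite.

## Feature selection and the classic models

Recursive feature elimination refits an importance estimator, drops the
least important feature, and repeats until one remains. The estimator is a
random forest with *permutation* importance and `mtry = d`: permutation
importance measures a feature's marginal contribution, so a feature whose
information is duplicated elsewhere scores near zero and is eliminated
early, which matches the backward-elimination semantics. The selected subset
is the smallest one along the elimination path whose validation accuracy is
within 0.5 percentage points of the best — smallest-within-tolerance because
dimensionality reduction is the stated motive of the procedure. A margin
(linear-SVM squared-weight) importance source is available as an option.

The three feature-based classifiers are standard estimators (e1071 SVM,
rpart decision tree, ranger random forest) behind a grid-search driver:
every grid point is trained on the training partition, scored by validation
accuracy, ties resolve to the first grid point, and the winner is refit.
Default grids span several orders of magnitude for continuous parameters
(SVM cost 0.01–100 × three kernels × four kernel widths). Features are
standardized with training-partition statistics for the SVM only; trees are
scale-invariant.

## Augmentation

Feature-space augmentation is SMOTE: a synthetic sample is
`x + U(0,1) · (x_nn − x)` for one of the five nearest same-class
neighbours, applied equally to all (balanced) classes with a default target
of twice the original count. Signal-space augmentation provides eight
operators — four local (hang, Gaussian smoothing, scaled noise,
down/up-sampling, each confined to a random contiguous window) and four
global (linear slope up to 10·sd total rise, circular x-shift up to 5 %,
y-offset up to 5 % of the range, scaling in [0.95, 1.05]) — composed in
seeded random order with a 0.5 per-operator inclusion probability. Two
printed ambiguities were resolved: the noise multiplier is drawn
`U(0, 1)` per sample as printed (a zero-centred `U(−1, 1)` variant is
available, since the one-sided draw adds a positive bias), and the x-shift
is circular so length is preserved (the printed tail behaviour is undefined;
a zero-padding variant exists). Augmentation is applied to the training
partition only; a pipeline test asserts the inputs are byte-identical after
training.

## The neural stack

The Feature Extraction Network (FEN) stacks blocks of 1D convolution →
tanh → batch normalization → adaptive average pooling; the Classification
Network (CN) is two fully connected layers producing a 256-dimensional
embedding. Because every block ends in adaptive pooling to a spec'd length,
all output shapes depend only on the spec, never on the input length or
sampling rate. The full-depth spec is seven layers (channels doubling from
16, capped at 64; kernel 7; pooled lengths halving to 16); the package also
pools the raw input to a working length of 1024 samples before the first
convolution, which fixes the downstream cost independent of the recording
length.

Training uses Adam (batch 32), a step-decay schedule that multiplies the
learning rate by 0.992 every 10 epochs — so after `k·10` epochs the rate is
exactly `lr0 · 0.992^k` — best-validation checkpointing, and early stopping
with a default patience of 150 epochs. The backward passes are hand-derived
and verified against central finite differences in the test suite (worst
relative error below 1e-5 across both architectures).

The Siamese classifier shares one embedder (weight sharing is exact by
construction). Five reference trials per class are drawn from the training
partition; their mean embedding is the class's reference feature vector,
recomputed every epoch. The loss for a sample with label `y` is

```
(1 − cos(f, r_y)) + (1/(C−1)) · Σ_{c≠y} max(0, cos(f, r_c) − m)
```

with margin `m = 0` by default; prediction takes the reference with the
highest cosine similarity, ties resolving to the lexicographically first
label. The exact contrastive form, reference count and selection rule are
package choices (the protocol fixes only cosine similarity and
reference-based classification).

PMLDF runs one FEN per sensor stream and a central fusion network of the
same block type. Fusion layer `l` consumes the channel-concatenation of its
own previous output and every stream's layer-`l` output, with all inputs
adaptively pooled to a common temporal length; concatenation (rather than
summation) was chosen so streams with heterogeneous channel counts — or a
third sensor — fuse without shape constraints. The fused output feeds the
CN head (softmax or Siamese). Gradients flow back through every tap into
both stream networks.

Raw signals are standardized per trial (zero mean, unit variance) before
the network.

## Scenarios and desk-scale sizes

`run_scenario()` executes the nine-scenario protocol: per-class stratified
60/20/20 split (stratified because all comparisons use balanced per-class
metrics), augmentation of the training partition only, feature extraction or
RFE for the feature scenarios (a `fixed_subset` flag reproduces the
protocol's four-feature subset — waveform length, RMS, frequency centroid,
mean frequency — without re-running RFE), model training, and test-set
evaluation. Results carry accuracy, macro-F1 (macro because classes are
balanced), the 8×8 confusion matrix and the config snapshot.

The desk-scale defaults used by the scenario driver and the acceptance
benchmarks are deliberate package choices, documented here once: a reduced
4-layer FEN (channels 8/16/32/64, pooled lengths 512/128/32/16), learning
rate 3e-3, at most 100 epochs (60 for the fused model and 40 for the
single-channel models in the three-model fusion comparison), early-stopping
patience 25, and no signal-space augmentation inside the raw-signal
benchmarks — on the synthetic datasets the networks saturate without it,
and augmentation correctness is covered by its own property tests. The
full-depth 7-layer spec and the 150-epoch patience remain the package
defaults for real-data use.

## Known limitations

* The generator's class structure is stylized; headline accuracies on it
  are not comparable to accuracies on recorded data.
* Batch normalization follows the printed block order (after the
  activation), which is unusual but kept for fidelity.
* The Siamese reference vectors are detached within an epoch (recomputed
  between epochs), a simplification of joint reference/sample optimization.
* RFE inherits the variance of forest importances; the recovery guarantee
  is statistical (9/10 seeded runs), not absolute.
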