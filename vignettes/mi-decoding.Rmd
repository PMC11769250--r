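---
title: "Decoding motor imagery from EEG with CSP, wavelet packets and a five-branch convolutional fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(misynergy)
```

## The problem

In a motor-imagery brain–computer interface, a user imagines a movement
(left hand, right hand, feet, or tongue) and the system must decode which
one from scalp EEG. Imagery modulates the sensorimotor mu (~8–13 Hz) and
beta (~13–30 Hz) rhythms over motor cortex, with a spatial topography that
depends on the imagined effector. `misynergy` implements a complete
decoding pipeline for the four-class paradigm used by the BCI Competition
IV-2a recordings: 22 EEG and 3 EOG channels at 250 Hz, a cue at t = 2 s,
imagery sustained until t = 6 s, 48 trials per class per run, six runs per
session.

The pipeline is: band-pass filtering to 7–30 Hz and exclusion of the EOG
channels; cue-locked trial extraction over the 2–6 s imagery period;
sliding-window segmentation (2 s windows, 50 % overlap); two feature
extractors — one-vs-rest common spatial patterns (CSP) for spatial
structure and wavelet packet decomposition (WPD) band energies for
spectral structure; and a classifier that fuses five heterogeneous
convolutional branches by concatenation under a single softmax head.

## Synthetic sessions

Real recordings require an external download, so the package ships a
generator (`synthetic_spec()`, `simulate_recording()`) that emulates the
recording protocol and plants the statistical structure the method is
designed to detect:

* each class has its own spatial mixing matrix (by default smooth,
  class-distinct Gaussian profiles across the channel axis) applied to
  band-limited oscillatory sources (defaults: one 9–13 Hz and one
  18–24 Hz source, built by Fourier-masking white noise so their spectra
  are exactly confined to the configured bands);
* sources are active only during the imagery period of each trial;
* broadband background noise is half white, half 1/f in power, scaled so
  the EEG-channel signal-to-noise ratio over imagery segments equals
  `snr_db` (default 5 dB);
* the three EOG channels carry a 0.1–4 Hz band-limited drift that leaks
  into the frontal EEG rows with small fixed coefficients, giving the
  EOG-exclusion step something to matter for;
* the cue order is a balanced seeded permutation within every run, and
  the trial length is 7.5 s with the inter-trial pause folded in (the
  protocol fixes only the 2 s cue and 6 s imagery end).

What the generator does **not** emulate: volume conduction from realistic
dipole geometry, inter-session and inter-subject nonstationarity,
line-noise and muscle artifacts, or electrode drift. Passing tests on
synthetic sessions therefore demonstrates that the implementation is
correct and that the method recovers planted class structure — not that
any particular accuracy will be reached on real recordings. Notably, the
planted task stays easy down to strongly negative SNR: the 7–30 Hz filter
removes most broadband noise power while leaving the planted rhythms
untouched, so held-out accuracy saturates near 1.0 between +5 and −10 dB
and degradation appears only as non-strict monotonicity over that range.

## Preprocessing choices

* **Filter realization.** The band edges are the only published fact; the
  filter is a Butterworth of order 5 applied forward–backward, which has
  zero phase and so cannot shift event timing. The input is padded by
  odd-symmetric reflection (9 time constants of the 7 Hz edge) before
  `signal::filtfilt`, because unpadded forward–backward filtering leaves
  edge transients far above the stopband floor.
* **Filter-then-epoch order.** Filtering is applied to the continuous
  recording before trial extraction (the standard order; it avoids edge
  transients inside every epoch).
* **Windows.** Windows that would extend past the imagery segment are
  discarded rather than padded: `floor((T − W)/S) + 1` windows at step
  `S = W·(1 − overlap)`.
* **Per-window standardization.** `standardize_windows()` z-scores every
  channel within every window. It is available and config-controlled but
  **off by default** in `run_all()`: per-window channel z-scoring equalizes
  all channel variances, which is precisely the between-class contrast CSP
  exploits. With planted variance structure it is actively harmful; on
  real data it can help against slow gain drift, which is why it remains a
  switch rather than a fixed step.

## CSP

Two-class CSP solves the generalized eigenproblem
Σ_c w = λ (Σ_c + Σ_rest) w; eigenvalues lie in [0, 1] and the extreme
eigenvectors maximize the variance ratio between the classes. The
published description is two-class only; the package uses the most common
multiclass extension, **one-vs-rest**, with `n_pairs = 2` filter pairs per
class by default (16 filters for four classes).

Covariance estimation follows standard CSP practice: per-epoch
mean-centred covariance, optionally trace-normalized (`cov_norm =
"trace"`, the pipeline default — it equalizes epoch power so strong trials
do not dominate), averaged per class. Trace normalization changes the
generalized eigenvalues whenever the two classes differ in total power;
`cov_norm = "none"` keeps raw sample covariances and is what the planted
closed-form checks use (λ = a/(a+b) for diagonal source variances). An
ill-conditioned composite covariance receives a ridge of
`1e-6 · trace/n` with a warning. The whitening invariant
W (Σ_c + Σ_rest) Wᵀ = I is asserted to 1e-6 in the test suite on every
fit it examines.

## Wavelet packets

No wavelet package is available as a dependency, and the transform is one
of the package's two bespoke feature extractors, so it is implemented in
full: a periodized orthogonal filter-bank tree (`haar`, `db2`, `db4`)
decomposing both approximation and detail branches to depth L. Defaults
are `db4` at L = 4 — at 250 Hz the 16 leaves are 7.8125 Hz wide and tile
the mu and beta bands cleanly — with the 8–30 Hz selection retaining
leaves 1–3.

Numerical conventions that matter:

* **Frequency (sequency) ordering.** High-pass filtering followed by
  decimation mirrors the spectrum, so the natural tree order does not map
  monotonically to frequency. Children are swapped under every odd-band
  parent, and the leaf index k then spans [k, k+1)·fs/2^(L+1) Hz; this is
  asserted against an FFT band-energy oracle for all 16 leaves.
* **Periodic boundary handling.** Coefficient counts halve exactly per
  level and the transform is orthogonal: energy is conserved and
  reconstruction is exact (both asserted to 1e-8 relative) whenever the
  length is divisible by 2^L; odd intermediate lengths are extended by
  repeating the last sample.
* **Phase convention.** The analysis step correlates with the scaling
  filter at even offsets. Other implementations sample the same
  convolution at a different phase; both are orthogonal wavelet-packet
  bases, and per-leaf energies can differ between conventions while every
  invariant above holds.

## The feature map

The published method states that WPD and CSP features jointly feed the
network but not how they are arranged; the layout is therefore an explicit
design decision. Per window, a 2-D map stacks K CSP-filtered time courses
(optionally block-averaged along time by `time_decim`) over B wavelet-band
log short-time-energy envelopes (0.25 s sub-frames, channel-averaged,
linearly resampled to the same width). Rows are standardized with
statistics estimated **on the training set only** and frozen in a scaler
object. Per-epoch row standardization would erase the between-epoch
variance differences that carry the class information; the frozen scaler
preserves them while still giving the network well-scaled inputs.

## The fusion network

Five branches with (conv, dense) block counts (6,3), (4,3), (3,2), (2,2),
(2,1); every conv block is a 3×3, stride-1, same-padded convolution with
tanh activation followed by pooling; dense blocks are 32-unit tanh layers.
The branch outputs are concatenated (width 5·32 = 160), passed through
dropout, and mapped by one dense softmax layer to the four classes.
Decisions where the description is silent:

* **Filters per conv block: 16** by default (configurable; the scaled-down
  study configurations below use 4). Uniform and CPU-friendly.
* **Pooling policy:** max pooling (local average pooling available per
  config) of 2×2 while both dimensions exceed one, then 1×2 along time —
  otherwise the row dimension of a ~19-row map collapses before six blocks.
* **Same padding** keeps the six-block branch viable on short maps.
* **Fusion joins the final dense activations**, not logits, mirroring
  "concatenate, then one softmax dense layer".

Training minimizes categorical cross-entropy with L2 weight decay using
the Adam optimizer (the optimizer is unnamed in the source description;
Adam is the field default and keeps the 0.001–0.01 learning-rate grid
sensible). Dropout acts on the concatenated feature vector. Noise
augmentation (`augment_noise()`) appends a copy of the training windows
with additive Gaussian noise at `sigma ×` per-channel std. Everything —
initialization, shuffling, dropout masks, augmentation — draws from a
single seeded RNG stream, so a fixed seed reproduces training histories
bit-for-bit on CPU. The implementation of the convolution/pooling
primitives is compiled C++ (exact forward/backward, verified against
numerical differentiation in the test suite at 1e-8).

## Splitting, tuning, evaluation

* **Train/test split is by trial, stratified by class** (default 80/20),
  before windowing can leak: windows of one trial never straddle the
  split. `grid_search()` assigns cross-validation folds the same way and
  refits CSP and the feature scaler inside every fold.
* The tuning grids default to learning rates {0.001, 0.005, 0.01}, batch
  sizes {16, 32, 64} and dropout {0.3, 0.4, 0.5} (27 combinations); ties
  in mean validation accuracy break toward the smaller learning rate,
  smaller batch, larger dropout (the more conservative configuration).
* `evaluate()` reports the 4×4 confusion matrix (rows = true), per-class
  precision/recall/F1 with zero-denominator cases defined as 0 and
  flagged, macro averages, and accuracy. `window_vote()` optionally
  aggregates window predictions to trial level by majority, breaking ties
  by mean probability.

## Problem sizes used by the tests and the acceptance script

The full default configuration (16 filters, undecimated 500-column maps,
288 trials per class) is the paper-scale setting and is expensive on one
CPU. The shipped checks therefore run the same code at desk scale, chosen
once: end-to-end recovery uses 200 trials per class at +5 dB SNR with
4-filter branches, `time_decim = 7` (71-column maps) and 100 training
epochs; the SNR sweep uses 32 trials per class, 15 epochs and three seeds
per SNR point; the acceptance script's end-to-end run uses 60 trials per
class and 40 epochs with augmentation on. These sizes are stated here as
the package's reference configurations so results are comparable across
machines.

## Known limitations

* The GDF reader covers the GDF 2.x subset the IV-2a distribution uses
  (uniform sampling rate, int16/float32/float64 records, mode-1/3 event
  tables); it is not a general biosignal-format library.
* Internal containers persist as RDS with an explicit schema version —
  single-file and lossless, but R-specific; export to open formats is out
  of scope.
* The synthetic generator's stationarity makes the classification task
  easier than real EEG at the same nominal SNR (see above); absolute
  accuracies on synthetic sessions should not be read as forecasts for
  real subjects.
* No artifact rejection by EOG regression, no re-referencing, no
  resampling, no cross-subject transfer.
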