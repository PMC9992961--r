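---
title: "Decoding single-limb motor imagery with dual-branch fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding single-limb motor imagery with dual-branch fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mifusion)
```

## The decoding problem

Motor imagery of different movements of the *same* upper limb
(arm extension, object grasping, wrist rotation) modulates largely the
same sensorimotor cortex. The usable signal is event-related
desynchronization (ERD): a task-specific *drop* in 8–30 Hz band power
whose spatial/spectral fingerprint differs slightly between tasks.
`mifusion` decodes it by training two convolutional branches on
complementary representations of every trial — the raw band-passed
multichannel signal, and a time-frequency image of CSP virtual
channels — and fusing their penultimate-layer activations into one
feature vector for a linear SVM.

This vignette documents the model and every place where the design was
genuinely open, what was chosen, and why.

## Preprocessing

Trials are reduced to 20 sensorimotor channels (FC1–6, C1–6, CP1–6, CZ,
CPZ), band-pass filtered to 8–30 Hz, decimated to 250 Hz and cut to the
4 s task window, i.e. a 20 × 1000 matrix per trial.

Open choices and their resolutions:

* **Filter family/order/phase** (unstated upstream): 4th-order
  Butterworth applied forward–backward (zero phase), the de-facto EEG
  default. Zero phase matters because the scalogram branch depends on
  event timing. The design (analog prototype, pre-warped band-pass
  transformation, bilinear transform) reproduces the conventional
  `butter(4, c(8,30)/(fs/2))` coefficients; tests pin the frequency
  response analytically (passband gain within 5%, 45 Hz stopband
  gain² < 0.2, DC rejection) and the zero-lag property.
* **Order of filtering vs. decimation**: filtering first, so the
  8–30 Hz band-limit doubles as the anti-alias filter for the 10:1
  decimation from 2500 Hz; decimation is then plain subsampling.
* **Edge handling**: odd-reflection padding of three filter lengths on
  each side before `filtfilt`, so 4 s epochs have no start-up
  transients inside the analysis window.
* **Window convention**: half-open `[t_start, t_start + duration)` in
  samples, cue onset at t = 0 — this is what makes "4 s at 250 Hz"
  exactly 1000 samples with no off-by-one.

## Common spatial patterns

For a binary contrast, per-trial covariances `E Eᵀ` are trace-normalized,
averaged per side, shrunk with diagonal loading
`C ← (1−ε)C + ε·tr(C)/M·I` (ε = 1e-6, exposed), and the generalized
eigenproblem of `(C⁺, C⁺+C⁻)` is solved by whitening. Rows of `W` are
sorted by descending eigenvalue of the positive class and sign-fixed so
the largest coefficient is positive; consequently `W C⁺ Wᵀ` and
`W C⁻ Wᵀ` are simultaneously diagonal with per-filter pairs
`(λ, 1−λ)`. Multiclass uses one-vs-rest: one model per class, the
pooled remainder as the negative side. With `m = 1`, the first and last
row of `Z = W E` become the two virtual channels per model (two for a
binary problem, six for three classes).

CSP is always fit on the training fold only; the no-leakage acceptance
test verifies byte-identical fits when held-out trials are corrupted.

## Morlet scalogram images

Each virtual channel is convolved with complex Morlet wavelets
(ω₀ = 6 cycles, support ±4σ, mirror padding) at 64 center frequencies
linearly spaced over 8–30 Hz — the analysis band fills the 64-pixel
image height exactly. Magnitudes are averaged into 64 contiguous time
bins (lengths differ by ≤1 sample, every sample used once), the
per-trial maps are averaged across virtual channels, min–max
normalized, bilinearly resized to 64 × 64, and passed through a fixed
256-level "jet" lookup table into a 64 × 64 × 3 image in [0, 1].

Numerical choices worth recording:

* **Wavelet normalization.** The wavelet is normalized to *unit peak
  frequency response* (its envelope sums to one), not unit L2 norm. An
  L2-normalized Morlet responds to a unit sinusoid with amplitude
  ∝ 1/√f, which tilts the scalogram and biases a 25 Hz tone's peak row
  about two bins low at this resolution; the flat-response
  normalization makes tone peaks land on their nearest frequency bin
  exactly (a property the acceptance suite checks at 10/15/20/25 Hz)
  and makes rows comparable across frequency. A unit-amplitude tone
  yields |coefficient| ≈ 0.5 at its own row.
* **Combining maps into one RGB image** (unstated upstream): default
  `mean_colormap` averages all virtual-channel maps and colormaps the
  result, giving one image per trial for any number of one-vs-rest
  models. The alternative reading — one one-vs-rest model per color
  plane — is available as `image_mode = "ovr_planes"` (3-class only).
* **Magnitude vs. power**: magnitude by default, `value = "power"`
  available.
* **Per-image min–max normalization**, not dataset-global: each trial's
  map is saved as an independent image, and an all-constant map renders
  as `colormap(0)` by convention.

## The two branches and their training

**EEG-CNN**: input 20 × 1000; two blocks of (conv 3 × 1 valid, stride
1; ReLU; max-pool 2 × 1 stride 2) with 16 then 32 filters; flatten;
dense 128 (the penultimate feature layer); dense softmax head. The time
axis contracts 1000 → 998 → 499 → 497 → 248, checked against an
independent convolution-arithmetic oracle. Filter counts, padding and
the FC width are unstated upstream; the smallest faithful reading was
chosen and everything is configurable.

**TF-CNN**: VGG16 layout — 13 same-padded 3 × 3 convolutions with five
2 × 2 stride-2 pooling stages (64 → 2 spatially), then three fully
connected layers, the second of which is the penultimate feature layer
(width 4096 at full scale). A `width_multiplier` scales every width;
the desk profile uses 1/8.

Both branches train with Adam (β₁ = 0.9, β₂ = 0.999) on softmax
cross-entropy, mini-batches, seeded initialization (He-normal) and
seeded shuffling — identical seeds reproduce identical weights, which
the leakage and determinism tests rely on. The reference learning rate
is 0.01; the desk profile uses 1e-3, which is the stable choice for
VGG-style nets from random initialization. Epochs and batch size are
unstated upstream; the full profile defaults to 50 × 32 and the desk
profile to 10 × 16 — ten epochs is past the point where the desk-scale
synthetic task converges, and keeps the three-seed end-to-end
acceptance run inside a one-CPU time budget.

One upstream formula prints the activation as `ln(1 + e^a)` — that is
softplus, while the surrounding text says ReLU. `max(0, a)` is the
default here, with `activation = "softplus"` available; the discrepancy
is documented, not resolved.

The engine itself (im2col/col2im, max-pool bookkeeping, Adam) is part
of the package, with the heavy matrix products routed through
single-precision BLAS (`options(mifusion.precision = "double")`
switches to the double path, which the numeric gradient-check oracle
uses). No pretrained weights are used anywhere.

## Fusion and classification

Penultimate activations `A` (length m) and `B` (length n) are
concatenated in that order, each feature dimension is z-scored with
means/SDs estimated on the training fold only, and a linear
L2-regularized squared-hinge SVM (C = 1, one-vs-rest for three classes)
produces the final label. A linear margin is the right default for
high-dimensional learned features; the SVM is solved deterministically
in the primal by L-BFGS-B. Branches are trained independently with
their own softmax heads, the heads discarded, and the SVM refit per
cross-validation fold.

## Evaluation

Stratified five-fold cross-validation (folds drawn from the run seed;
stratification is an explicit choice — "five equal subsets" upstream
does not mention it). Accuracy is `trace/total` of the confusion matrix
(rows = predicted, columns = true); kappa is `(p0 − pe)/(1 − pe)` with
`pe = 1/K`. That fixed-marginal reading of "random classification
accuracy" is confirmed by back-computing four published table entries
exactly from their printed accuracies; the classical marginal-based
form is available (`cohen_kappa(cm, "marginal")`). Paired t-tests
compare per-unit accuracies two-sided, with an explicit error on
zero-variance differences. The classical baseline is CSP log-variance
features (2m per one-vs-rest model) into the same standardized linear
SVM.

## The synthetic world

The generator stands in for a multi-session MI recording and emulates:
20 sensorimotor channels, 250 Hz (or 2500 Hz to exercise decimation),
4 s trials, 2–3 classes, ~50 trials per class, and class-specific ERD
in 8–30 Hz. Concretely, each class owns one band-limited Gaussian
source confined to its own contiguous sub-band of 10–22 Hz (half-open
sub-bands, so sources are spectrally disjoint and the attenuation
contract is testable per source), mixed into the channels through a
fixed random orthonormal column; during class-k trials source k's
amplitude is multiplied by `1 − erd_depth`. Channels receive
independent 1/f noise plus a 10% common-mode 1/f term; `snr` (default
2) is the source-to-noise RMS amplitude ratio per unit-norm mixing
column — band-limited sources at twice the broadband noise amplitude
give a clearly detectable but not trivial contrast, comparable to a
strong ERD recording. `snr = Inf` disables noise for exact power-ratio
oracles, and `keep_sources = TRUE` attaches ground truth for the CSP
recovery tests.

What a green test does **not** establish: the generator has no
forward-modeled head geometry, no ocular/muscular artifacts, no
inter-session nonstationarity, and its class effect size (`erd_depth`)
is a free parameter rather than calibrated to any real recording. The
end-to-end acceptance level (`erd_depth = 0.8`, 60 trials/class,
binary) is a *strong-signal* regime: it verifies that the full chain —
CSP fit per fold, image generation, both branches, fusion — recovers a
recoverable signal and that fusion does not trail its branches, not
that real-data accuracies are reproduced (those require the external
dataset and full-scale training, and are out of scope by design).

## Known limitations

* The full-scale TF-CNN (width multiplier 1, 4096-wide FC layers) is
  impractical to train in R on one CPU; it builds and runs, but all
  tested configurations use reduced widths.
* Only the linear SVM kernel is implemented (no RBF) — no SVM library
  is available in the target environment, and the linear primal is the
  method's default.
* I/O is the plain-text directory dialect (per-trial matrices +
  `labels.csv` + `meta.json`); HDF5 and EDF containers would need
  bindings unavailable in the target environment.
* `pe = 1/K` kappa assumes balanced test sets, which stratified folds
  guarantee here; for unbalanced data use the marginal form.
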