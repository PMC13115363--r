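---
title: "Methods: differential-entropy EEG features, multi-scale dilated attention, and self-learning decision fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-entropy EEG features, multi-scale dilated attention, and self-learning decision fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdafuse)
```

# The problem

Emotion recognition from a single signal source is brittle: facial
expressions are easy to acquire but can be masked or socially regulated,
while EEG is hard to disguise but noisy and highly subject-specific. This
package implements a decision-level multimodal pipeline for binary
valence/arousal classification: each modality gets its own classifier, and
only their class-probability outputs are fused. Decision-level fusion
keeps the two branches fully independent — each can use the preprocessing
and architecture best suited to its signal, and the system degrades
gracefully when one modality is missing or corrupted.

# EEG branch

## Differential-entropy features

For a continuous random variable with density $f$, the differential
entropy is $h(x) = -\int f(x)\,\ln f(x)\,dx$. Band-pass-filtered EEG over
short windows is well approximated as Gaussian, for which the integral has
the closed form

$$h(x) = \tfrac12 \ln\!\left(2\pi e \hat\sigma^2\right),$$

a monotone transform of band power that compresses its heavy-tailed
distribution. The package uses the natural logarithm (required for the
closed form above; the test suite verifies it against numerical quadrature
of the definition to below $10^{-6}$ relative error) and the unbiased
$(n-1)$ variance estimator; with 64-sample windows the distinction from
the maximum-likelihood estimator is negligible, but the unbiased form is
the conventional default in R. A constant window has undefined DE; it is
mapped to a configurable floor (default $-20$ nats, far below any value
arising from real signals) with a warning rather than $-\infty$, so a
single dead channel cannot poison a whole tensor.

## Pipeline

Each 63-s trial (3 s preparation + 60 s task at 128 Hz) is processed as:

1. **Band-pass decomposition** into theta [4–7], alpha [8–13],
   beta [14–30] and gamma [31–45 Hz]. The gamma upper edge is 45 Hz
   because the targeted recordings are band-limited to 4–45 Hz. The
   filter is a zero-phase (forward–backward) Butterworth. Its order is a
   deliberate numerical choice: the two-pass magnitude response of a
   4th-order design loses about 10% of ideal in-band white-noise power
   (the double application squares the transfer function, narrowing the
   effective band), an 8th-order design is numerically unstable on the
   narrow theta band at 128 Hz, while order 6 keeps the in-band power
   within ~7% of the ideal rectangular band and is stable on all four
   bands. Order 6 is therefore the default, exposed as an argument.
2. **Windowed DE**: 120 non-overlapping 0.5-s task windows per trial,
   DE per channel and band in each.
3. **Baseline correction**: the six 0.5-s preparation windows give a
   per-channel, per-band baseline DE (their mean), subtracted from every
   task window to remove subject-level resting-state offsets.
4. **Topographic mapping**: each corrected per-channel vector is placed
   on an 8×9 grid following the electrode layout; cells without an
   electrode stay exactly zero (40 empty cells for the 32-channel
   montage). Grid indices are 0-based, row-major, top-left origin — a
   convention choice, documented in the layout file format, and
   user-overridable since topographic conventions vary between
   laboratories.
5. **Stacking and grouping**: the four band grids are stacked and six
   consecutive windows grouped (non-overlapping, stride 6) into one
   `(6, 4, 8, 9)` sample of 1728 values; a 60-s task span yields exactly
   20 samples. Non-overlapping grouping was chosen because 120 windows
   divide evenly into 20 six-step samples, keeping samples statistically
   independent.

## Classifier

The EEG model is deliberately small, since the DE tensor is already a
strong representation:

* a band-preserving 3×3 convolutional stem applied per time step
  (spatial smoothing over the grid);
* **spectral attention**: per step, the 4 band tokens — each a flattened
  72-dim spatial map — pass through a single-layer, 4-head self-attention
  encoder (embedding width 72 = 8·9 falls out of the grid naturally) with
  a residual connection;
* **spatial attention**: per step, the 72 grid-cell tokens, i.e. 4-dim
  band profiles linearly embedded to width 72, through the same kind of
  encoder, projected back to 4 dims with a residual. Spectral and spatial
  modules run sequentially (spectral first); nothing in the architecture
  forces an order, and the sequential form needs no merge operator;
* **temporal attention**: one scalar weight per step from a linear
  projection + ReLU, normalised to sum to one when any weight is
  positive, applied multiplicatively. The weighted steps are **retained
  and flattened** to 1728 dims rather than summed: collapsing the
  temporal axis would make the advertised 1728-dim classifier input
  impossible, so weighting-then-flattening is the only self-consistent
  reading;
* dropout 0.5 on the flattened representation, then a linear layer and
  softmax.

The encoder blocks are multi-head scaled-dot-product self-attention with
a residual connection and no layer normalisation or feed-forward
sub-layer — the minimal structure that matches the description
"single-layer multi-head self-attention encoder". No positional encoding
is added; spatial identity is carried by the fixed grid ordering, and the
test suite exploits the resulting permutation equivariance as an
invariant.

# Facial branch (MSDAC)

Facial expressions are combinations of action units (AUs) whose spatial
footprint differs by emotion: some are compact (smile corners), others
span distant regions (brow + mouth combinations). A fixed receptive field
cannot serve both, which motivates the multi-scale design:

* **Stem**: two blocks of convolution + batch-norm + ReLU + 2×2 max-pool.
  The block composition is a design choice (the standard modern conv
  block); widths default to 32 → 64 but all tests run a slimmer
  configuration since the architecture, not the capacity, is what is
  under test.
* **MSDC**: three parallel 3×3 branches with dilation 1, 2, 3 ("same"
  padding = dilation), concatenated along channels. A dilated 3×3 kernel
  spans $2d+1$ pixels at constant parameter cost, so the three branches
  see spans 3, 5 and 7 with identical weight counts — the heart of the
  parameter-economics argument, verified in the tests as the exact 9 : 49
  weight ratio against a span-matched standard 7×7 kernel.
* **D-BA**: channel attention (global average pooling → two FC layers →
  sigmoid gate per channel) and spatial attention (channel-mean pooling →
  1×1 convolution → sigmoid gate per position) applied **in parallel** to
  the concatenated map and fused by element-wise **sum** (configurable to
  average). Parallel-plus-sum is the minimal reading of a "dual-branch"
  module whose outputs "are fused"; a sequential (CBAM-style) composition
  is the main alternative and would be a one-line change. The channel
  gate ends in a sigmoid even though only the spatial branch's sigmoid is
  forced by the description: a multiplicative gate must be bounded.
* **Head**: a final convolutional block, max-pool, batch-norm, then a
  two-layer classifier with dropout 0.2 after the first FC layer.

Ablation variants share the interface: `MSAC` replaces the dilated
branches with receptive-field-matched standard 3/5/7 kernels (more
parameters, same spans), `WO_DBA` removes the attention block,
`WO_DBA_MSDC` additionally collapses the branches to one.

# Decision fusion

With per-sample class-probability rows $X_E, X_F \in \Delta^{D-1}$:

* **Fixed-weight baseline**: $k X_E + (1-k) X_F$, $k \in [0,1]$ chosen by
  grid search over $\{0, 0.1, \dots, 1\}$ on the training split.
* **Feature-level baseline**: the branches' penultimate representations
  concatenated, a fresh two-layer head trained on top (features are
  z-scored first, as the two branches' feature scales differ by orders of
  magnitude).
* **Self-learning module**: concatenate $(X_E, X_F)$ → four FC + GELU
  layers with non-decreasing widths $4 \to 16 \to 32 \to 64 \to 64$ →
  reshape to $L = 8$ tokens of width $E = 8$ → 4-head self-attention
  ($d_k = 2$) → flatten → affine → softmax. The widths, $L$ and $E$ are
  architecture constants exposed in `fusion_config()`; published
  descriptions of such modules sometimes write shapes that would tie the
  weights to the mini-batch size, which cannot be meant literally — the
  defaults here were fixed once and are deliberately small, since the
  input is only $2D = 4$ numbers per sample.

**Modality dropout** regularises the fusion model: per training sample,
one modality's row is replaced by the uniform distribution (the only
simplex-valid "missing" code; zeros would break row normalisation) with
marginal probability $p = 0.1$, never both rows at once. The
implementation uses a single coupled draw per sample (drop EEG with
probability $p$, face with probability $p$, neither otherwise), which
achieves the exact marginal rate *and* the never-both guarantee
simultaneously — an independent-draw-then-redraw scheme would bias the
marginal rate to $p/(1+p)$. This requires $p \le 0.5$, which the
constructor enforces.

# Training

All networks are trained with Adam (β₁ = 0.9, β₂ = 0.999) and
cross-entropy loss: branches at learning rate 5×10⁻⁴ (batch 128 for
faces, 32 for EEG), the fusion model at 1×10⁻⁴ (batch 32, 20 epochs,
modality dropout 0.1). Branch epoch counts default to 30 but are
arguments everywhere. Forward and backward passes are written directly
against BLAS-backed matrix operations; the test suite validates every
architecture's backpropagation against central finite differences
(tolerance 10⁻², which absorbs cancellation noise at ReLU/max-pool kinks;
a genuinely wrong gradient shows order-1 errors). Batch-norm keeps
running statistics via an exponential moving average (momentum 0.1) for
evaluation mode; all stochasticity (shuffling, dropout, initialisation)
uses the session RNG, so `set.seed()` makes a fit bit-reproducible.

Cross-validation is stratified by class within subject: on small sample
counts, unstratified folds can produce single-class training splits, which
the harness treats as an error rather than silently fitting a degenerate
model. The paired t-test helper returns $p = 1$ with a warning on
zero-variance differences (identical per-fold accuracies), where the
statistic is undefined.

# Synthetic data: what it does and does not show

The generators emulate the acquisition *protocol* (22 subjects × 40
trials, 63-s trials at 128 Hz, a face frame every 0.5 s of task → 4800
frames per subject, 105,600 over 22) and embed controllable class
structure:

* **EEG**: a pink-noise (1/f) background — so band-pass filtering is
  consequential, unlike white noise — plus band-limited oscillations on
  designated channels whose amplitude depends on the class (defaults:
  beta band, channels 1–4, amplitudes 1 vs 2.5 against a background of
  SD 2). The preparation span carries baseline-only statistics. Two
  choices make the advertised band-confinement contract hold physically:
  oscillation components are drawn from the band interior (25% margin per
  edge), and the background SD defaults to 2 so that every band's
  background power dominates the band-pass filters' stop-band leakage
  floor (~3×10⁻⁵ in power for the order-6 two-pass design — without the
  floor margin, a rank test over 100 trials intermittently detects the
  leaked class effect in the gamma band).
* **Faces**: 48×48 grayscale frames where class 0 is one compact bright
  blob and class 1 two dim blobs separated by ~20 px — detectable only by
  a receptive field larger than any single small kernel, so the
  multi-scale branches are behaviourally distinguishable.
* **Decisions**: each sample has exactly one reliable modality (a
  fraction `complementarity` assigned to EEG); the reliable row puts mass
  `acc` (default 0.85) on the true class, the other row is uniform. A
  rule-aware oracle is therefore near-perfect while either modality alone
  is ignorant on its unreliable span — the cleanest possible test bed for
  whether fusion learns per-sample modality weighting.

Passing tests on these generators demonstrates that the architectures can
extract the feature types they were designed for (band-power contrasts,
multi-scale spatial patterns, per-sample confidence) and that the full
pipeline is wired correctly. It does **not** demonstrate benchmark-level
accuracy on real recordings: real EEG has artifacts, non-stationarity and
inter-subject variability, and real faces have pose, identity and
illumination variation, none of which are modelled. Accuracies on the
synthetic benchmarks (typically 1.0) are property checks, not performance
claims.

# Problem sizes

The shipped tests and the acceptance script run deliberately small
configurations, chosen as the smallest sizes at which each property is
stable: slim network widths (stem 8 → 12, branch 12 for the face model),
240/120 train/test faces over 5 epochs, 20 trials → 400 DE samples for
the EEG branch over 14 epochs (8 channels), 600/300 decision pairs for
the fusion benchmark, and 10,000 draws for the dropout-rate check. The
architectures themselves are identical to the full-size defaults.

# Known limitations

* Subject-dependent evaluation only; no leave-one-subject-out protocol.
* Two modalities, two classes at the defaults (the face branch accepts
  `n_classes = 7`, exercised synthetically only).
* No face detection/alignment: images are assumed pre-cropped; only a
  centre-crop-style preprocessing is implied by the generators.
* No EEG artifact removal or re-referencing — the pipeline assumes
  provider-side preprocessing.
* Full-scale stem widths (32 → 64) are supported but slow to train on a
  single CPU; published parameter totals for such networks depend on
  stem details that are not fully specified anywhere, so only the
  *direction* of the dilated-vs-standard comparison (and the exact 9 : 49
  per-branch ratio) is asserted, not absolute counts.
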