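---
title: "Multi-level contrastive representation learning for AF detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level contrastive representation learning for AF detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(afcontrast)
```

## The problem

Atrial fibrillation (AF) shows itself on the ECG through three cues:
irregular RR intervals, the disappearance of the P wave, and a low-amplitude
4–9 Hz fibrillatory (f) oscillation that replaces it. Labeled long-term ECG
is scarce relative to unlabeled recordings, so the package pre-trains an
encoder on 30-second single-lead segments using labeled *and* unlabeled data
jointly, then evaluates the learned representation on the downstream AF
detection task via linear probing (classifier only) or full fine-tuning
(encoder and classifier).

## Model

The encoder has two stages. A convolutional feature extractor `f` — one
input convolution (kernel 7, stride 1) followed by six residual blocks, each
with two kernel-3 convolutions and a projection shortcut, stride 2 on the
first convolution — downsamples time by $2^6 = 64$, so a segment of
$T_0 = 3840$ samples (30 s at 128 Hz) becomes a hidden representation
$h \in \mathbb{R}^{T \times D_h}$ with $T = 60$. A bidirectional LSTM fusion
network `g` reads $h$; its last-time-step output, L2-normalized onto the
unit hypersphere, is the encoder representation $z \in \mathbb{R}^{D_z}$
(defaults $D_h = 128$, $D_z = 256$).

Three InfoNCE-style objectives act on different levels, all using cosine
similarity $u \odot v = u^\top v / (\lVert u\rVert\,\lVert v\rVert)$:

* **Temporal consistency** (on $h$, temperature $\tau = 1$): for two views
  of one sample, the same timestamp across views is the positive; other
  timestamps of either view are negatives, averaged over timestamps and the
  batch.
* **Channel consistency** (on $z$, $\tau = 0.1$): the time-aligned segment
  of the simultaneously recorded second lead is the positive; the other
  samples' representations of both leads are negatives.
* **Label consistency** (on $z$, $\tau = 0.1$): the supervised contrastive
  objective — every other representation with the same rhythm label is a
  positive, with the denominator running over all other representations.

The combined loss is $\lambda_1 L_t + \lambda_2 L_c + \lambda_3 L_l$ with
$\lambda = (1/3, 1/3, 1/3)$ on labeled batches and $(1/2, 1/2, 0)$ on
unlabeled batches, so unlabeled data contributes through the two
self-supervised terms only.

The strong view used for temporal contrast comes from domain-knowledge
augmentation: T-wave masking (the 50–300 ms ST window after each R peak set
to 0 — the post-z-score baseline — for 50% of beats) always, followed by
vertical flipping with probability 0.5. The weak view is the preprocessed
segment itself, matching the unaugmented downstream task.

## Design choices in the open corners

Several components are underdetermined by the method description alone; the
package makes one consistent choice each and tests it:

* **Residual-block internals.** Kernel 3, stride 2 on the first convolution,
  projection (kernel-1) shortcut, ReLU after the addition, no normalization
  layers in the encoder. Every tensor shape in the tests is exact under this
  plan.
* **"Last time step" of a bidirectional recurrence.** $z$ concatenates the
  forward state after reading all $T$ steps with the backward state emitted
  at position $T$ (which has read only $h_T$), the literal reading of the
  fused output sequence's final element.
* **Which views feed the channel loss.** The weak (unaugmented) views of
  both leads — channel positives are defined on the raw pair, without
  augmentation marks.
* **Label-loss views.** The supervised contrastive convention operates on
  the multiview set of size $2B$ (weak + strong, each carrying its sample's
  label); a `label_loss_views = "single"` switch exposes the literal
  single-view reading. Anchors with no positive contribute 0 and leave the
  outer average.
* **Eq-denominator limit.** The channel-loss denominator runs over the batch
  ($N$ read as $B$).
* **bSQI.** The quality index is cited but never defined upstream; the
  package uses the standard two-detector agreement index
  $\mathrm{matched} / (n_A + n_B - \mathrm{matched})$ with a Pan–Tompkins
  style detector, an independent moving-average energy-envelope detector,
  and a 150 ms matching window realized as
  $\lceil 0.150 \cdot f_s \rceil$ samples. It is computed on the
  band-passed, pre-z-score segment; both detectors are amplitude-scale
  invariant, so the ordering of the pipeline does not affect it.
* **Mixed-rhythm windows.** A window is AF iff AF/AFL rhythm covers at least
  50% of its duration (majority-duration rule; the boundary counts as AF).
* **Labeled/unlabeled batch mixing.** Each optimization step draws from one
  source; sources are interleaved deterministically at evenly spaced
  fractional positions proportional to their batch counts.
* **Fine-tuning schedule.** The inverse-decay learning rate
  $\eta = \eta_{base} / (1 + 10\,T_{cur}/T_{max})^2$ is applied per epoch
  ($T_{cur}$ = completed epochs), Adam throughout, no early stopping.

## Numerical core

No automatic-differentiation framework is used: the package implements the
convolution, LSTM, batch-norm and linear layers with hand-derived backward
passes (the convolution gather/scatter runs in compiled code on top of
BLAS), and the loss gradients analytically through the cosine-similarity
softmax and the L2 normalization ($\varepsilon = 10^{-12}$). Correctness is
enforced by finite-difference tests over every parameter group and by
nested-loop reference implementations of all three losses. Two numerical
conventions matter: log-sum-exp stabilization subtracts the per-anchor
maximum everywhere, and gradient checks are run at a generic parameter point
(biases jittered away from zero) because zero-initialized biases put
ReLU pre-activations of dead input regions exactly on the kink, where
one-sided derivatives differ legitimately.

Initialization follows He-normal for convolutions with one correction: the
two branches a residual block sums are each scaled by $1/\sqrt{2}$, so
activation variance stays near 1 through the six blocks instead of doubling
per block. Without this the hidden representations reach standard deviations
around 6 and saturate the LSTM gates, which stalls learning at any
reasonable rate. LSTM weights are uniform $\pm 1/\sqrt{H}$ with forget-gate
bias 1. Fine-tuning clips the global gradient norm at 1 (classifier and
encoder trees separately), the standard safeguard against the gradient
spikes backpropagation through a 60-step recurrence can produce, and damps
the learning rate by 10 during the first epoch (warmup) so an aggressive
base rate cannot collapse a pre-trained representation before the optimizer
state is populated.

Zero-phase filtering is implemented with steady-state initial conditions and
odd-reflection padding, because a naive forward–backward pass leaves edge
transients far above the DC-rejection contract. Resampling is rational
(zero-stuffing, windowed-sinc anti-aliasing low-pass, decimation), verified
against passband-tone amplitude.

## What the synthetic generator emulates — and what it does not

The generator renders each beat as Gaussian bumps (P at −0.16 s for non-AF
only, Q −0.04 s, R 0, S +0.04 s, T +0.20 s; widths 0.02–0.05 s), with two
RR-interval laws: non-AF uses a truncated normal with coefficient of
variation 0.05, AF a truncated uniform over ±40% of the mean RR (CV ≈ 0.23).
AF records drop the P wave and add a 6 Hz sinusoid (0.1× the R amplitude)
with per-beat phase jitter; both classes add Gaussian noise (default
sd 0.02 in R-amplitude units, within the range where the quality filter
passes everything). Lead 2 shares the R-peak timing but differs in
morphology (gain 0.7, T amplitude halved), which is exactly the property the
channel loss needs. Defaults (30 s, 128 Hz, mean RR 0.8 s) mirror the
preprocessing regime of the PhysioNet databases the WFDB path reads.

The generator is deliberately not a physiological simulator: no ectopic
beats, no respiratory or electrode-motion artifacts, no QRS morphology
families, no atrial-flutter waveforms. Passing the end-to-end benchmark
therefore shows that the implementation learns and transfers the intended
invariances on a controlled task — not that it reaches any particular
accuracy on clinical recordings.

## Problem sizes used by the tests and the acceptance run

The shipped benchmark pre-trains a reduced encoder (channel plan
8-16-16-32-32-32, $D_z = 64$) on 512 labeled + 512 unlabeled synthetic pairs
for 5 epochs, then averages three fine-tuning seeds (classifier 32-16) for
the linear probe, full fine-tuning and a random-encoder probe control, with
a stratified 70/30 split. One scaling rule matters: at ~1000 segments, an
epoch at the full-size batch sizes is only a few optimization steps, far too
few for Adam at the full-size learning rates to move a freshly initialized
network. The benchmark therefore trades batch size for step count at equal
compute — pre-training batch 32 (160 steps across the 5 epochs), fine-tuning
batch 32 over 30 epochs with base rate 0.01 under the inverse-decay
schedule — a configuration selected by optimization-sanity checks on
synthetic separable features, not by the downstream metric. Unit tests use
3 s segments and toy channel plans. The full-size defaults
(plan 32-64-64-128-128-128, $D_z = 256$, 40 epochs, batches 256/512, rate
0.001) remain available for real WFDB data via the functions and the
command-line front end.

## Known limitations

* The WFDB reader covers signal formats 16 and 212 and MIT-format
  annotations — the formats of the four AF databases — not the full format
  family, and the package never writes WFDB.
* Training is single-threaded CPU code; it is sized for the desk-scale
  benchmark, and full-scale multi-database pre-training, while functional,
  is slow by deep-learning-framework standards.
* The segment store is R-native serialization with an explicit format
  version; it is not interoperable with HDF5 tooling.
* `detect_qrs` is tuned for 30 s single-lead segments at 128 Hz; it is the
  masking fallback and one arm of bSQI, not a general-purpose clinical QRS
  detector.
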