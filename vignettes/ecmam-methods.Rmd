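---
title: "Methods: a dual-channel multimodal attention network for 12-lead ECG arrhythmia classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-channel multimodal ECG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its model, the design decisions
behind it, what the synthetic data generator does and does not emulate, and
the numerical conventions a user should know before trusting or modifying
the defaults.

## The classification problem and the model

A 12-lead ECG record (6–60 s, 500 Hz) may carry several of nine rhythm
labels: AF, IAVB, LBBB, RBBB, PAC, PVC, SB, STach, SNR. Multi-label output
is essential — atrial fibrillation can coexist with a bundle branch block —
so the classifier ends in nine independent sigmoid units, not a softmax.

The model is a dual-channel fusion network. The 1D channel consumes the
denoised, length-normalized time series `X1` (12 × 15000) and captures
rhythm and morphology in the time domain. The 2D channel consumes a stack
of per-lead STFT magnitude maps `X2` (12 × 224 × 224) and captures the
time–frequency structure that distinguishes, e.g., the disorganized atrial
activity of AF from the clean harmonic structure of sinus rhythm. Both
channels are stacks of bottleneck residual blocks, `H(X) = relu(F(X) + X)`,
where the residual branch `F` compresses channels with a 1×1 convolution,
convolves, and expands back (expansion factor 4). Batch normalization
follows every convolution.

Attention gates sit on each residual branch, applied to `F(X)` before the
skip addition:

* 1D blocks use squeeze-and-excite channel attention: the temporal average
  per channel passes through a two-layer bottleneck (reduction ratio `r`)
  and a sigmoid; the resulting per-channel gate in (0,1) rescales the
  branch output.
* 2D blocks use a hybrid gate: first channel attention with two pooling
  branches (global max and global average) sharing one excitation MLP,
  fused by summation before the sigmoid; then spatial attention — the
  channel-wise max and mean maps are stacked, convolved (`k × k`,
  size-preserving), and squashed into an `H × W` gate shared by all
  channels.

Because every gate is strictly inside (0,1), each attention output is
elementwise dominated by its input, and forcing all gates to 1 (the
`bypass_attention` flag) turns every attention block into the identity.
That bypass is exactly the attention-free ablation variant `EC-MMI`, and
the equality is asserted numerically in the tests — the ablation
comparison is therefore controlled by construction, not by re-implementing
a second network.

## Design decisions where the layout was open

Several architectural details are only depicted, not specified, in the
source material for this family of networks; the package fixes them as
follows and keeps each behind a configuration field:

* **Stage layout** (`model_config("full")`): stem 7×7/stride-2 convolution
  (kernel 15 in 1D) + 3×3/stride-2 max pool, stages of 3/4/6/3 blocks with
  base widths 64/128/256/512 and expansion 4 — the standard 50-layer
  bottleneck arrangement, consistent in order of magnitude with the
  published ~57 M parameter count (this implementation enumerates 51.8 M;
  exact equality is not asserted because the reference layout is known
  only from figures).
* **Attention hyperparameters**: reduction ratio `r = 16` (floored at
  width 1) and spatial kernel `k = 7`, the SE/CBAM conventions; one shared
  excitation MLP for the max- and average-pooled vectors; sum first, then
  sigmoid. Each is isolated in one function so alternatives are one-line
  changes.
* **Fusion head**: concatenated branch features → fully connected (512,
  relu) → dropout 0.4 → fully connected (9) → sigmoid.
* **Serial order of the hybrid gate**: channel attention first, spatial
  second.

## Preprocessing

Denoising has two stages. (1) A wavelet threshold scheme: each lead is
reflect-padded to a power-of-two length, decomposed with a periodized db6
transform (depth `round(log2(fs)) − 1`, i.e. 8 levels at 500 Hz, so the
approximation band sits below ~1 Hz); the approximation is zeroed (baseline
drift), and detail coefficients are shrunk with a soft–hard compromise rule
(`α = 0.5`) at the universal threshold `σ √(2 log n)`, with `σ` the
MAD/0.6745 of the finest detail band (wide-band EMG). This is a standard,
fully documented construction; the threshold function is swappable
(`"soft"`, `"hard"`). (2) A second-order IIR notch (quality factor 30)
applied forward–backward removes mains interference; the frequency
defaults to 60 Hz for Georgia-sourced records and 50 Hz otherwise, since
the mixed dataset spans both mains standards — a per-source default
recorded here as a documented guess.

Length normalization keeps the last 30 s of longer records and pads
shorter ones with zeros *at the tail*, so the informative segment stays
aligned to the record start; the operation is idempotent. No amplitude
normalization is applied to the 1D input by default (an off-by-default
per-lead standardization flag exists).

One practical property worth knowing: with the universal threshold, small
smooth waves (P waves especially) are visibly shrunk on clean signals,
because the finest-band MAD picks up QRS energy. This is inherent to the
scheme, affects all classes equally, and the classifier trains on exactly
what the preprocessing emits.

## Time–frequency maps

Per lead: Hanning-windowed STFT with window length 256 and hop 128 (50%
overlap — the standard choice for a Hanning window; the hop is not
dictated by the model's source), one-sided magnitudes, `log(1+m)`
compression, per-map min–max scaling to [0,1] (a constant map becomes all
zeros rather than dividing by a zero range), bilinear resize to 224 × 224
with corner alignment, rows ordered low→high frequency and columns
early→late. The full 0–250 Hz band is retained. The 12 maps are stacked in
lead order as 12 input channels — grayscale magnitudes, not rendered RGB
images, matching the 12 × 224 × 224 input contract.

## Loss, weights, optimization

The loss is the class-frequency-weighted multi-label cross-entropy with
`w_i = 1/log(n_i)` computed from the training split only. The logarithm is
natural: the base only rescales all weights by a common factor, which the
optimizer absorbs; the base is still configurable. Probabilities are
clipped to `[1e-7, 1 − 1e-7]` so vertex losses stay finite. In training
folds where a class has fewer than two positives (possible only in tiny
toy runs), its weight falls back to the `n = 2` value — `class_weights()`
itself rejects counts below 2, where the formula is undefined.

Optimization is Adam (framework-default β₁ = 0.9, β₂ = 0.999, no weight
decay) at initial rate 0.001, halved after every tenth epoch — "ten
iterations" is read as epochs, consistent with a 50-epoch budget. Batch
size 64 and dropout 0.4 are the full-scale defaults. Multi-hot decisions
threshold the sigmoids at 0.5. Model selection keeps the epoch with the
best validation macro F1. The plain unweighted loss is available behind
`train_config(weighted = FALSE)`.

Data splitting follows the 0.5:0.5 test/(training+validation) design with
five-fold cross-validation of the latter; on odd counts the test side
takes the ceiling, folds are as even as possible with earlier folds
larger, and no stratification is applied (the split is purely random).

## Evaluation conventions

Per class, one-vs-rest: precision, recall, accuracy `(TP+TN)/N`, F1, FNR
`FN/(FN+TP)`, FPR `FP/(FP+TN)`, and ROC AUC by the trapezoidal rule over
unique score thresholds (tied scores collapse to one point). Macro values
are unweighted nine-class means. Zero-denominator metrics are defined as 0
and flagged with a warning; this matters only for degenerate tiny-test
classes. Multi-label confusion reporting is realized as per-class FNR/FPR
rates — a single 9 × 9 confusion matrix is not constructible when records
carry several labels. Resource accounting reports the trainable parameter
count by exhaustive enumeration (cross-checked in the tests against a
closed-form count), forward multiply–accumulates from per-layer formulas,
and the serialized checkpoint size.

## The synthetic generator: what it does and does not emulate

`synth_record()` builds each beat as a sum of Gaussians (P, Q, R, S, T) on
the time axis and projects three source channels (P, QRS, T; plus a fourth
for ectopic QRS morphology) through fixed 12-entry lead-direction vectors.
Those vectors encode the clinically load-bearing polarities: aVR
inversion, negative-V1/positive-V6 LBBB versus positive-V1 RBBB, and
discordant wide PVC complexes. Class rules: SNR 62–98 bpm regular with P
waves; SB below 60; STach above 100; AF log-normally irregular RR
(CV ≈ 0.28) without P waves; IAVB PR 240–320 ms; LBBB/RBBB QRS 140–170 ms
(the R-wave width is `qrs/3` so the *measured* above-25%-of-peak duration
tracks the programmed one, which an independent detector verifies);
PAC/PVC insert early beats (coupling 0.55·RR, compensatory pause) that are
narrow-with-P or wide-without-P respectively. Noise adds a 0.15–0.3 Hz
baseline sinusoid (0.15 mV), mains interference (0.04 mV) and white EMG
noise (0.02 mV) — defaults chosen once as typical clinical magnitudes.

What it does **not** emulate: beat-to-beat morphology variability, T-wave
abnormalities, fibrillatory f-waves, electrode artifacts, pathologies
outside the nine classes, or realistic inter-patient variation. Passing
the desk-scale tests therefore demonstrates that the pipeline — denoising,
spectrograms, both branches, attention, the weighted loss, metrics — is
wired correctly and can learn genuinely class-conditional structure; it
does not certify clinical performance, which requires the real databases
and the full profile.

Two calibrations make the learning acceptance meaningful rather than
vacuous: an independent slope/amplitude-based R-peak oracle in the test
suite recovers the generator's programmed beat times to a few
milliseconds, and a hand-crafted 14-feature classifier (rate, RR CV, QRS
width, PR estimate, V1/V6 polarities, …) reaches macro F1 ≈ 0.99 on
default generator settings — the classes are separable, so a correctly
wired network must separate them too, and the label-shuffled control shows
the headroom is not memorization.

## Desk-scale study conditions

CPU-sized runs use the `tiny` profile, chosen once: records at 125 Hz
(100 Hz would put a 50 Hz notch at the Nyquist frequency) and 10 s, giving
`X1` 12 × 1250; STFT window 64 / hop 32 resized to 32 × 32; one block per
stage with widths 8/16/32/64 (expansion 4, so 256-dimensional branch
features); fusion width 64; batch 32. The learning acceptance trains on 60
records per class, validates on 20, for 15 epochs at seed 1 and requires
validation macro F1 ≥ 0.70, with the same run under shuffled training
labels required to stay ≤ 0.25. Everything the schedule and loss inherit
from the full-scale protocol (lr 0.001 halved every 10 epochs, dropout
0.4, Adam, weighted loss) is kept.

## Numerical choices and degenerate inputs

* Batch-norm eps `1e-5`, momentum 0.1 for running statistics; inference
  uses running statistics, so inference is deterministic.
* He-initialised weights; biases zero; all randomness flows through
  explicit seeds (weight init, shuffling, dropout), and repeated runs are
  bit-identical.
* Max-pool backward scatters through the argmax (ties broken by first
  index) and sums overlapping windows.
* The spatial-attention channel max uses first-index tie-breaking for
  determinism.
* All-zero signals: denoising returns zeros; a constant spectrogram maps
  to zeros; a zero-initialized head emits probability 0.5 everywhere.
* Gradients of every layer, every attention gate and the whole model are
  pinned against central finite differences in the test suite.

## Known limitations

* The full profile is faithful in spirit but not figure-exact; its
  parameter count (51.8 M) is reported, not matched, to the published
  57.19 M.
* Pure-R convolutions are BLAS-bound: fine for the tiny profile and unit
  economics of testing, roughly an order of magnitude too slow for
  full-scale training, which the full-scale path documents but does not
  run on a desk machine.
* The WFDB reader supports the packaged format-16 dialect; the MAT-signal
  variant used by some public distributions needs conversion first.
* Wavelet denoising with the universal threshold over-shrinks low-amplitude
  P waves on very clean signals (see above).
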