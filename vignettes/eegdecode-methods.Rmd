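---
title: "Decoding relaxation vs. workload from dense-array EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding relaxation vs. workload from dense-array EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Guided-imagery (GI) relaxation and mental-task (MT) workload leave
different signatures in scalp EEG: relaxation with closed eyes elevates
posterior alpha (8–12 Hz) power, while demanding cognitive work recruits
broader fronto-parietal networks with stronger theta (4–7 Hz) and beta
(13–30 Hz) activity. `eegdecode` asks whether a classifier fed nothing but
one second of minimally filtered multichannel signal — no hand-crafted
band-power features — can recover that difference, and whether 26
centro-parieto-occipital "cognitive" electrodes carry as much usable
information as the full 256-channel montage.

Because raw recordings of this kind are not publicly deposited, the package
ships a synthetic-cohort generator as a first-class, tested module. All
quantitative claims in the test suite are claims about that generator's
output; the sections below state exactly what it does and does not emulate.

## The synthetic cohort generator

Each subject's recording is a sum of three parts, in microvolts at 250 Hz:

1. **Spatially smooth 1/f background.** Ten pink-noise sources
   (power ∝ 1/f^γ, γ = 1, synthesized by FFT shaping of white noise) are
   projected through Gaussian-in-angle scalp topographies with random
   centres (angular width 1.1 rad) plus a far-field floor of 0.15 — volume
   conduction reaches every sensor, so no scalp site is ever decoupled from
   the background field — scaled so the shared background is
   about 9 µV RMS. A further independent pink-noise stream of 3 µV RMS is
   added per channel. The shared-to-independent ratio (3:1) reproduces the
   high neighbour-channel correlations of dense arrays, which is what makes
   consensus-based bad-channel detection meaningful.
2. **Band-limited rhythms.** Each band is a set of stochastic narrow-band
   oscillators — white noise through an AR(2) resonator with ~1.5 Hz
   bandwidth — at frequencies drawn uniformly within the band: four alpha
   sources centred on the posterior cap (over the cognitive electrodes),
   three theta sources centred frontally, four beta sources split between
   frontal and parietal centres. Baseline RMS amplitudes are 6 (alpha),
   5 (theta) and 4 (beta) µV, chosen so that the posterior alpha fraction
   of 1–45 Hz power sits near 0.6 at baseline — the eyes-closed regime. Per-subject lognormal
   amplitude jitter (sd 0.15) models between-subject variability.
3. **Condition gains.** GI multiplies the alpha amplitude by `alpha_gain`
   (default 1.6); MT multiplies theta and beta by `theta_gain` (1.5) and
   `beta_gain` (1.4). With all gains at 1 the conditions are exchangeable
   in distribution — the null cohort used to verify that classifiers score
   at chance on held-out subjects.

Declared bad channels are overwritten after synthesis (`flat` → zeros,
`high_noise` → white noise of 100 µV sd), and optional blink-like
transients (Gaussian bumps of ~0.25 s, 60–140 µV) are weighted toward the
anterior-inferior face channels; artifacts default off. Everything is a
pure function of the subject seed; per-channel noise streams are seeded by
channel label, so simulating a channel subset reproduces exactly those
columns of the full simulation.

**What the generator does not emulate**: volume-conduction forward
physics, non-stationary state drift within a session, heartbeat/muscle
artifacts, electrode impedance drift, and realistic alpha waveform
asymmetries. Passing tests therefore demonstrate that the pipeline
recovers planted spectral class structure under realistic noise and
between-subject variability — not performance on real recordings.

The electrode layout is an idealized Fibonacci spiral on the unit sphere:
exact manufacturer coordinates are not published in usable form, and only
relative geometry (neighbourhoods, the posterior/frontal split) matters
for interpolation and for the generator's topographies. The 26 cognitive
labels are mapped onto the contiguous posterior cap; the highest-numbered
free labels are mapped to the face region, mirroring the physical net.

## Preprocessing

* **Band-pass 1–45 Hz.** A 1251-tap Hamming-windowed linear-phase FIR,
  applied by FFT convolution with the (1251−1)/2-sample group delay
  removed, so the output is zero-phase without the doubled filtering of a
  forward–backward pass. At 250 Hz the transition band is ≈0.66 Hz: 10 Hz
  passes within −1 dB, while 0.1 Hz drift and 60 Hz line noise are ≥20 dB
  down (the suite checks ≥20 dB; the realized attenuation is ≈−53 dB).
* **Bad-channel detection.** For every non-overlapping 5 s window (the
  first and last 2 s of the recording are excluded as filter edges), each
  channel is predicted by inverse-distance-weighted interpolation from its
  4 nearest neighbours within a random subset of 25% of the channels;
  50 such draws are made and the median predicted signal is correlated
  with the actual one. A channel is flagged when the correlation falls
  below 0.75 in more than 40% of windows. These are the PREP-style
  defaults; all four are arguments. Correlations are computed on a
  2×-decimated grid within each window (>600 points per window), which
  changes nothing statistically and halves the cost. Flat channels have
  undefined correlation and are assigned 0, hence flagged.
* **Interpolation.** Flagged channels are replaced by the
  inverse-distance-weighted mean of their 4 nearest good channels.
  Spherical-spline interpolation would be the laboratory standard; IDW was
  chosen because it is dependency-free, exactly testable (neighbours
  carrying one common signal reproduce it identically), and adequate at
  256-channel density. A recording with ≥25% flagged channels is rejected
  as too corrupted rather than repaired.
* **Order and crop.** Filter → detect → interpolate → crop, following the
  left-to-right order of the preparation pipeline; the analysis window is
  the half-open interval [600 s, 720 s), i.e. minutes 10–12, giving 120 s
  per subject.

## Dataset construction

Cropped recordings are cut into non-overlapping 1 s epochs of 250 samples
(epoch *i* covers samples [250·i, 250·(i+1))); 26 subjects × 120 epochs
give 3120 epochs, 1560 per class. Channel subsets are `FULL-256` or
`COGN-26` (the cognitive electrodes in canonical order). Folds partition
*subjects*, never epochs: the grouped stratified k-fold assigns each
class's shuffled subjects round-robin with a per-class offset, so with
13+13 subjects and k = 6 the test folds hold 4 or 5 subjects with class
counts 2/2, 2/3 or 3/2 — hence 480 or 600 test epochs against 2640 or
2520 training epochs. LOSO uses one fold per subject.

Per-channel standardization (mean/sd over all training epochs and samples,
applied unchanged to the test fold) is on by default: recurrent layers in
particular stall on raw ±50 µV inputs. The ε = 10⁻⁸ clamp on zero-variance
channels only matters for degenerate synthetic inputs. Standardization
statistics never touch test data, so no leakage is introduced.

## The four architectures

All four end in a single sigmoid unit; the positive class is MT, so the
output is P(workload). Parameter counts follow the total-params convention
of the mainstream frameworks: weights + biases + normalization scale/shift
*and* running mean/variance (4 entries per normalized feature). The
BiLSTM, which has no normalization layers, anchors this convention: its
counts are convention-free.

* **BiLSTM** — one bidirectional LSTM layer, 64 units per direction, on
  the raw (channels-per-timestep) sequence; last forward and first
  backward states concatenated → dense 32 → dropout 0.5 → dense 1. Counts:
  2·4·(64·(C+64)+64) + (128·32+32) + 33 = 50,753 (C = 26) and 168,513
  (C = 256).
* **1D CNN** — four Conv1D blocks with filters (16, 32, 64, 128), kernel
  3, stride 2 and 'same' padding (250 → 125 → 63 → 32 → 16 timesteps),
  LeakyReLU (slope 0.3) in every block, batch normalization in blocks 1, 2
  and 4; spatial dropout 0.25 sits before block 3 in place of its
  normalization. Flatten (16·128 = 2048) → dense 64 → dropout 0.5 →
  dense 1. The per-layer values are not printed anywhere in usable form;
  they were **reconstructed** by searching the space of block
  hyperparameters under the published totals for both input widths
  (165,649 and 176,689) as a two-equation oracle. The doubling-filter,
  kernel-3, stride-2 solution is the unique "textbook-shaped" member of
  the solution set and is frozen as the default configuration.
* **CNN–BiLSTM hybrid** — the same convolutional front-end; its 16-step,
  128-feature output sequence passes (time-distributed flatten) into a
  bidirectional LSTM and then dense 32 → dropout 0.5 → dense 1. Closed-form
  matching against the published totals (77,777 / 88,817) forces the
  recurrent width: with the front-end fixed, h² + 137h − 5408 = 0 gives
  h = 32 units per direction exactly. The halving relative to the
  standalone BiLSTM is consistent with the stated intent of shrinking the
  recurrent stage once the CNN has reduced the input. Both CNN-based
  totals differ by 11,040 between 26 and 256 channels because only the
  first convolution touches the channel dimension.
* **EEGNet** — the canonical compact convolutional network (temporal
  convolution F1 = 8, kernel 125; depthwise spatial filters D = 2;
  separable convolution F2 = 16, kernel 16; average pooling 4 then 8; ELU;
  batch normalization; dropout 0.5), with a sigmoid output replacing the
  original softmax. The published totals for this family (2,153 / 6,753)
  are inconsistent with canonical EEGNet-8,2 arithmetic under every
  counting convention we tried (the implied channel-dependence of
  20 parameters/channel would need an extra 4/channel beyond the 16/channel
  depthwise stage); the canonical implementation counts 2,201 / 5,881,
  is pinned by a regression test, and is excluded from the published-count
  checks.

## Training

The engine implements forward and reverse passes for strided 1-D
convolution (per-tap matrix products), batch normalization, LeakyReLU /
ReLU / ELU, ordinary and spatial dropout, average pooling, dense layers,
and bidirectional LSTMs (gate order i, f, g, o; forget-gate bias 1), plus
Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁷). All gradients are verified against
central finite differences in development. Numerical choices that matter:

* **Loss** is binary cross-entropy computed on logits in the numerically
  stable form max(z,0) − z·y + log(1+e^−|z|).
* **Batch-norm momentum is 0.9** (not 0.99): with ~20–40 optimizer steps
  per epoch at this data scale, a 0.99 running average lags the weights by
  many epochs and makes early-epoch validation metrics meaningless.
  Normalization uses ε = 10⁻³.
* **Learning rates** default to 10⁻³ for EEGNet and the BiLSTM and 10⁻⁵
  for the CNN and hybrid, the values used in the original trials; the
  test suite overrides to 10⁻³ with 2–4 epochs, since its cohorts are far
  more separable than real data and long schedules would only add runtime.
* **Early stopping** monitors validation loss with configurable patience
  and restores the best-validation weights. Which epoch's loss the
  published per-fold "Loss" refers to is not stated; best-epoch is used.
* **Determinism.** Weight initialization (Glorot uniform), epoch
  shuffling and dropout masks all draw from seeds derived from the fold
  index and the training seed; two runs with one configuration are
  bit-identical. Degenerate precision/recall (empty denominators) are
  reported as 0 with a warning so fold tables stay bounded.

## Grad-CAM

For the convolutional models, the gradient of the predicted-class score
(the logit; negated when the prediction is GI) with respect to the target
convolutional block's post-activation feature maps is averaged over time
to yield one weight per filter; the ReLU-rectified weighted sum of feature
maps is the temporal importance curve, linearly upsampled from the block's
16 steps to the 250 input timesteps and max-scaled.

A 1-D convolution over time mixes all channels in its first layer, so
classical Grad-CAM yields no channel axis. Channel-resolved maps are
constructed as rectified gradient×input at the input layer, modulated by
the normalized temporal curve, then max-scaled to [0, 1]. This
construction is one defensible choice among several (first-layer CAM,
pure input gradients); it is isolated behind the `channel_attribution`
argument. Per-subject maps average the single-epoch maps of the subject's
held-out epochs (120 under full LOSO), damping epoch-level noise.

## Problem sizes in the shipped test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run on one CPU core in the tens of minutes: cohorts are generated at the
26-channel cognitive scale directly (the channel-subset short-cut above),
with 720 s per subject — the shortest duration containing the 600–720 s
analysis window. The separability suite uses `alpha_gain = 3`: under this
generator's between-subject jitter, the gain-2 cohort's ideal band-power
classifier tops out near 0.85 grouped-CV accuracy, and gain 3 restores the
clearly separable regime the recovery checks are meant to probe. The
grouped 6-fold check trains 4 epochs per fold on all 3120 epochs; the
LOSO check uses 60 of each subject's 120 epochs and 2 training epochs
across all 26 folds; chance-level checks use 10-subject null cohorts and
label-shuffled data over three seeds. For the null cohorts the ±0.1 chance
band is asserted on the accuracy averaged across the seeded cohorts:
under subject-grouped CV a chance-level model produces near-binomial
subject-level outcomes with standard deviation ≈ 0.5/√n_subjects, so a
per-seed band at 10-subject scale would reject a true null far too often;
the epoch-level label-shuffled check, which concentrates tightly, keeps
the per-seed band. Bad-channel recovery runs ten
recordings on a 64-channel montage subset plus a full-montage
interpolation check. The pipeline smoke test runs 4 subjects end to end.

## Known limitations

* Synthetic validation only: no claim transfers to real recordings
  without re-estimating noise, artifact and between-subject structure.
* The CNN/hybrid per-layer values are a reconstruction constrained by the
  published totals and architecture description, not a transcription.
* IDW interpolation underestimates curvature relative to spherical
  splines at low electrode densities.
* The EDF writer targets the 16-bit baseline format with per-channel
  physical scaling; EDF+ annotations and discontinuous records are out of
  scope.
* Training is CPU-only and single-threaded beyond BLAS; wall-times in the
  fold tables are informational, not benchmarks.
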