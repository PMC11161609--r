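---
title: "Constructing contact-quality rPPG by fusing classical extractors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing contact-quality rPPG by fusing classical extractors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A remote photoplethysmogram (rPPG) is a blood-volume-pulse waveform
inferred from the subtle colour changes of facial skin in ordinary video.
Classical extractors — the green channel, CHROM, POS, LGI and ICA — each
turn an RGB trace into a candidate pulse signal, and each fails in its own
way under motion, illumination change and sensor noise. `rppgfuse`
implements a sequence-to-sequence fusion approach: the four extractor
outputs of a 10-second window are stacked into a 4-channel input and a
recurrent (LSTM) model is trained to reproduce the reference *contact* PPG
(cPPG) of the same window. The goal is explicitly morphological — the
whole waveform including the diastolic lobe, not just the dominant heart
rate frequency — which is why the loss and the evaluation criteria are
waveform-level (RMSE, Pearson *r*, dynamic time warping) rather than
heart-rate-level.

## Pipeline and processing order

For each video the stages run in this order:

1. **RoI reduction** (when starting from frames): 30 face landmarks
   (10 forehead, 10 per cheek), a 30×30-pixel patch mean per landmark and
   channel, giving a landmarks × time × channel *spatiotemporal map*;
   optional histogram equalization and low-variance landmark rejection;
   then region averages and the unweighted whole-face RGB trace.
2. **Windowing**: the RGB trace is cut into non-overlapping 10-s windows
   (300 samples at 30 fps); trailing partial windows are discarded.
3. **Extraction per window**: ICA, LGI, CHROM, POS (fixed channel
   order) plus the green baseline.
4. **Conditioning**: each extracted signal, and the cPPG (first
   resampled from 60 Hz to the frame rate by cubic splines), is linearly
   detrended, bandpassed with a zero-phase sixth-order Butterworth filter
   at 0.65–4 Hz, and min–max normalized to [0, 1] per window.
5. **Fusion**: the 300×4 normalized stack is mapped to a 300-sample
   fused waveform by the trained model.
6. **Evaluation**: DTW, Pearson *r*, RMSE and |ΔHR| per window,
   aggregated per method, video and activity.
7. **Ranking**: Friedman test over windows × methods; when significant,
   Nemenyi pairwise comparisons, with decisions reported both at α and at
   the Bonferroni-adjusted per-pair level α/(k(k−1)/2) (0.05/15 = 0.003
   for six methods).

Filtering is applied to the *extractor outputs* (and the cPPG), not to
the raw RGB: the chrominance methods divide by channel means, which must
remain positive, so they must see the unfiltered colour scale.

## The extractors

All outputs are mean-removed and sign-oriented so systole points upward
(non-negative correlation with the negated green channel; blood absorbs
light, so raw intensity dips at systole).

* **GREEN** — the negated, mean-removed green channel.
* **CHROM** — with mean-normalized channels `Rn, Gn, Bn`:
  `Xs = 3Rn − 2Gn`, `Ys = 1.5Rn + Gn − 1.5Bn`,
  `S = Xs − (σ(Xs)/σ(Ys))·Ys`. Identical relative modulation of all
  channels gives `Xs = Ys`, so pure intensity variation cancels exactly;
  `σ(Ys) = 0` degenerates to `Xs`.
* **POS** — a sliding 1.6-s window (slide of one frame); per segment
  `S1 = Gn − Bn`, `S2 = −2Rn + Gn + Bn`,
  `h = S1 + (σ(S1)/σ(S2))·S2`, mean-removed and overlap-added.
* **LGI** — SVD of the mean-removed 3×T channel matrix; projection onto
  the complement of the leading singular direction (`I − u₁u₁ᵀ`), scaled
  by the leading singular value so the output is invariant to a global
  gain; the projected component with maximal 0.65–4 Hz Welch power is
  returned.
* **ICA** — whitening (rank-reduced when channels are collinear, as
  happens for noiseless traces) followed by joint approximate
  diagonalization of fourth-order cumulant matrices (JADE) via Jacobi
  rotations. JADE was chosen over fixed-point FastICA because the
  fixed-point iteration oscillates without converging on a few percent of
  short, noisy 300-sample windows, while the Jacobi sweep is
  deterministic algebra with no random initialisation; the component with
  maximal in-band Welch peak power is selected, ties broken by lowest
  index.

## The fusion model

The architecture follows a tapering stack: four LSTM blocks returning
full sequences, with state sizes decreasing from 90 to 1
(default `c(90, 60, 30, 1)`), a dropout layer after each block, and a
time-distributed affine head emitting one value per time step. The loss is

```
loss = w_rmse · RMSE(pred, target) + w_r · (1 − r(pred, target))
```

with default weights (1, 1); a constant (degenerate) prediction scores
the correlation term at its maximal penalty 1 with zero gradient.
Training uses mini-batch Adam, a reduce-on-plateau schedule (factor 0.5,
patience 5 epochs, floor 1e−5) monitored on a held-out validation split,
early stopping, and optional global gradient-norm clipping. The entire
procedure — weight initialisation, dropout masks, epoch shuffles — draws
from seeded generators, so a fixed seed reproduces the trained weights
bit for bit on the same machine.

Open choices and how they were settled:

* Intermediate state sizes are only constrained to taper from 90 to 1;
  `c(90, 60, 30, 1)` is the default and configurable.
* The last block has state size 1; the affine head is applied per time
  step on that block's sequence output, producing the 300-step waveform.
* The model input is the region-combined 4-channel stack (not per-region
  stacks); regions are averaged before extraction.
* Targets are min–max-normalized cPPG windows — the same normalization as
  the inputs — because the loss mixes a scale-dependent term (RMSE) with
  a scale-free one (r).
* Cross-validation folds are grouped by source video so that no video
  contributes windows to both sides of a split; `by_video = FALSE`
  restores naive window-level splitting.
* For evaluation, the fused output window is min–max normalized exactly
  like every competing method, so DTW and RMSE compare morphology on a
  common [0, 1] scale instead of penalizing the regression's amplitude
  shrinkage.
* Dropout, learning rate, batch size and epoch budget are exposed in
  `fusion_config()`. The package defaults are neutral (dropout 0.2,
  lr 1e−3, batch 32); the documented benchmark
  (`run_synthetic_benchmark()`) uses dropout 0.1, lr 2e−3, plateau
  patience 10, batch 16 and 100 epochs, the smallest budget at which the
  model generalises from ~56 training windows.

## The synthetic data generator

Every stage is trainable and testable offline through
`synth_config()`/`make_dataset()`:

* **Pulse waveform**: each beat is two Gaussian lobes — systolic
  (SD 8 % of the beat period) and diastolic (relative amplitude 0.4,
  delayed 0.35 of the period) — with beat-to-beat heart-rate jitter drawn
  from a truncated normal. Unit peak amplitude; 39–240 BPM enforced.
* **Observation model** per channel:
  `baseline_c · (1 + drift + wander − gain_c · ppg + ε_c)`.
  Illumination drift and baseline wander are common-mode (a camera sees
  motion and lighting in all channels together); the white noise ε is
  per-channel; the pulsatile term is subtractive and strongest in green,
  as in real skin reflectance. The cPPG is generated at 60 Hz and
  resampled down by the preprocessing module, exercising the real
  resampling path.
* **Activity presets** (rest, talk, translation, rotation, gym) grade
  noise and wander upward, with motion wander placed *inside* the
  heart-rate band (0.7–1.1 Hz): in-band common-mode wander is precisely
  the artifact the chrominance projections exist to cancel, so the
  presets reproduce the field's characteristic ordering — the green
  baseline collapses under motion while CHROM/POS/LGI stay usable. The
  presets were calibrated so classical-method per-activity *r* spans
  roughly 0.85 (rest), 0.7 (talk), 0.5 (translation/rotation) and 0.3
  (gym), a realistic difficulty gradient. They are analogues of those
  recording regimes, not calibrated replicas of any real video corpus.
* **Frames**: optionally, each RGB sample can be rendered as a small
  uniform image with 30 landmark coordinates (jittered for motion
  activities), which round-trips exactly through the patch-mean stage at
  zero pixel noise.

What the generator deliberately omits: photorealistic faces, skin-tone
optics, camera compression, non-common-mode motion artifacts
(specularities, occlusions), and sensor-specific cPPG lag. Passing the
synthetic benchmark therefore shows the pipeline's machinery is correct
and that fusion denoises redundant noisy observations; it does not prove
performance on real video.

## Numerical choices

* "Detrend" is linear least squares (the 0.65 Hz high-pass edge already
  suppresses slow wander; the detrend mainly stabilises filter
  transients). Configurable off by simply skipping the call.
* The bandpass is a sixth-order Butterworth in the convention of the
  field's standard tooling (six poles per band edge, as
  `scipy.signal.butter(6, band)` would build), applied forward–backward
  (zero-phase, since the evaluation is morphological and phase
  distortion would corrupt DTW and *r*), with odd-reflection padding
  absorbing edge transients. Its empirical magnitude response on
  sinusoids at 30 Hz: ≥ 0.99 across 1–3 Hz, ≤ 0.001 at 0.1 Hz and 7 Hz.
* Welch PSD: Hann window, 256-sample segments (or the full series when
  shorter), 50 % overlap, zero-padded to 4096 bins — ≈ 0.44 BPM peak
  resolution on a 10-s, 30-fps window. The heart-rate peak is searched
  only inside 0.65–4 Hz (= 39–240 BPM); ties resolve to the lowest
  frequency; an all-zero band returns `NA` rather than a fabricated rate.
* DTW uses squared-difference local cost and reports the square root of
  the optimal path's total cost, with no warping-window constraint
  (windows are short); a Sakoe–Chiba band is not applied by default.
* The Friedman statistic uses the plain chi-square form with average
  ranks for ties (no tie-correction factor); on tie-free data it is
  identical to the reference implementation in `stats`. The Nemenyi
  critical distance uses `q = qtukey(1−α, k, Inf)/√2`.
* The low-variance landmark rule is relative by default — drop landmarks
  below 1e−4 × the median per-channel variance (robust to overall scale)
  — with an absolute override.
* Min–max normalization maps constant windows to 0.5 and flags them;
  degenerate windows are excluded from metric aggregates with their count
  reported, never scored as zeros.

## Problem sizes

The documented benchmark uses 35 synthetic videos (7 per activity) of
21 s each — 70 ten-second windows — under grouped 5-fold
cross-validation, training from scratch per fold (~5 minutes on one CPU).
The statistical-calibration suite uses 2000 simulated null matrices
(20 blocks × 4 methods). These sizes were chosen as the smallest at which
the fusion model generalises and the type-I-error estimate is stable.

## Known limitations

* The fusion model is trained and validated on synthetic data only; no
  claim is made about transfer to real video without retraining.
* ICA component selection by in-band peak power cannot distinguish a
  pulse from a motion artifact that is periodic *within* the heart-rate
  band; such windows degrade the ICA channel (visibly in the motion
  presets) and are left to the fusion stage to down-weight.
* |ΔHR| on noisy windows occasionally locks onto the second harmonic of
  the beat waveform; this is a property of peak-picking HR estimation,
  shared by the Welch and autocorrelation variants.
* Bit-for-bit training reproducibility holds for a fixed BLAS and thread
  count; across platforms, expect loss agreement only to ~1e−4.
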