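---
title: "Wavelet features and neural-network classification of simulated gyroscope signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet features and neural-network classification of simulated gyroscope signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyrowave)
```

This vignette documents the models behind `gyrowave`, the parameters that
matter, and the design decisions taken where several defensible options
existed. It is the package's reference for *why* things are the way they
are; the README shows *how* to run them.

## 1. The sensing model

A single-axis vibratory gyroscope outputs a DC voltage proportional to the
angular rate about its axis: 0 °/s maps to 2.5 V and ±90 °/s to
4.5 V / 0.5 V, clamping at those rails beyond the measurable range
(`rate_to_voltage()`). An 8-bit converter digitizes the voltage over a
0–5 V full scale at 2668 Hz; the stream is decimated by 20 to an effective
133.4 Hz. Modeling choices:

* **ADC full scale.** The signal range (0.5–4.5 V) must sit inside the
  converter range; 0–5 V is the conventional choice for a 5 V supply.
  Quantization is uniform mid-tread over 256 codes with half-way values
  rounding up (`quantize_adc()`); the code-128 reconstruction of a 2.5 V
  input is 2.5098 V.
* **Decimation without an anti-alias filter.** `downsample_signal()` keeps
  every 20th sample. The simulated kinematics are band-limited far below
  the decimated Nyquist (66.7 Hz) — burst harmonics < 2 Hz, tremor at
  9 Hz — so plain decimation only folds wideband sensor noise, which is
  part of what a real decimating acquisition system without analog
  filtering would show.
* **Segment length.** A "12-second" window is defined as exactly 1600
  decimated samples (11.99 s at 133.4 Hz); the sample count, not the
  nominal duration, is the contract used everywhere downstream.

## 2. The synthetic recording study

`build_dataset()` emulates a single-subject recording session: 8 motions ×
8 intervals of 72 s × 2 channels, each interval cut into six 1600-sample
segments per channel — 768 labeled single-channel segments, paired by
(motion, interval, segment) into 384 two-channel patterns
(`pair_patterns()`). A note on pattern counting: a session of this layout
can be counted either as 768 single-channel segments or as 384 two-channel
patterns. Since every feature set concatenates both channels, the
classification unit is the pattern, and all splits and accuracies are over
the 384 patterns; the 768 count describes the segment inventory.

Each motion class is a template: per-channel burst amplitudes (°/s), a
weight vector for the first three harmonics of the within-burst
oscillation (two fundamental cycles per repetition under a raised-cosine
envelope, normalized to unit peak), and a direction sign. The repetition
period is drawn once per interval from U(5, 7) s — hence 10–14 repetitions
per 72 s — with per-repetition amplitude jitter (sd 0.05, clipped to
±15 %) and phase jitter (sd 0.15 rad) shared between the channels, which
observe the same limb.

Two disturbances are added:

* **Action tremor.** A narrow-band (≈1 Hz wide, random phase-walk) 9 Hz
  oscillation, amplitude 6 % of the channel's movement amplitude, gated by
  the movement envelope. Physiological tremor sits at 8–12 Hz; its
  presence gives the high-frequency wavelet sub-bands motion-correlated
  content, as real limb recordings have. Without it, detail-band variances
  would reflect sensor noise only.
* **Sensor noise.** White Gaussian noise whose standard deviation is a
  *device* property, identical for every channel and class: `snr_db`
  (default 20 dB) is referenced to a fixed nominal movement intensity of
  30 °/s RMS, giving σ = 3 °/s at the default, with a 1 °/s floor. An
  earlier formulation that scaled noise with each channel's own signal
  power was rejected: it made the noise variance a clean proxy of class
  power, so *adding* noise *improved* classification — an artifact, not
  physics. With device-referenced noise, accuracy increases with SNR, as
  it should (property-tested from 5 dB to 30 dB).

The amplitude matrix encodes the qualitative class structure: M1
(standing) is noise-only and trivially separable; M4/M5 (straight-leg
forward/backward) and M2/M8 (lower-leg backward/upward) are
direction-mirrored pairs. Variance- and energy-based features are blind to
movement direction, so these pairs are deliberately the closest class
pairs in feature space — their amplitude profiles differ by only ~1.5× in
variance scale, while all other class pairs are far better separated. The
test suite verifies the intended structure on the default dataset (seed
1): the training third is learned perfectly, held-out accuracy exceeds
90 %, M1 is never misclassified, and the two engineered pairs hold at
least half of all off-diagonal confusion mass. These figures characterize
the simulator; real recordings would add inter-session and postural
variability no template model reproduces, so passing them says the
pipeline recovers planted structure, not that it would reach the same
accuracy on a human subject.

All randomness flows from one integer seed through a deterministic
sub-seed derivation per (motion, interval), so datasets are byte-identical
across runs and platforms with the same seed.

## 3. The wavelet layer

`dwt_decompose()` implements the dyadic analysis filter bank with
**periodic boundary extension** and ceil-halving coefficient lengths:
`D_j` has ⌈N/2ʲ⌉ coefficients, so a 1600-sample segment at level 5 gives
lengths (50, 50, 100, 200, 400, 800) for (A₅, D₅…D₁) — exactly N/2ʲ where
N is dyadically divisible — and stays well-defined at levels 6–8 (25, 13,
7), where an odd-length stage is extended by repeating its last sample.
Periodization was chosen over symmetric or zero-padded extension because
it preserves both the exact N/2ʲ lengths and Parseval energy equality for
orthogonal families, which the energy-distribution features rely on.

Filters for the catalogue (Haar; Daubechies 2–32; Symlets 2–8; Coiflets
1–5; spline biorthogonal and reverse-biorthogonal 1.1…6.8; discrete Meyer)
are tabulated constants shipped as plain text, with the companion filters
derived from the standard modulation relations (`rec_hi[k] = (−1)ᵏ
dec_lo[k]`, `dec_hi[k] = (−1)ᵏ⁺¹ rec_lo[k]`; reverse-biorthogonal = role
swap of the biorthogonal pair). The tables are not trusted blindly: the
suite checks perfect reconstruction to 1e−8 for every exactly-PR wavelet
at levels 1–5, Parseval to 1e−6 for the orthogonal families, the
vanishing-moment pattern of the Daubechies high-pass filters, and the
biorthogonal/reverse-biorthogonal swap identity. The **discrete Meyer**
wavelet is a 62-tap FIR approximation of an IIR ideal; it is not exactly
invertible (max-abs round-trip error ≈1e−2, inherent to the approximation,
matching reference implementations) and is tested at that documented
tolerance.

Support widths follow the conventional tables: filter length − 1 for
compactly supported orthogonal wavelets (31/31 for Daubechies 16), and
2·order + 1 per part from the two spline orders for the biorthogonal
families (3/7 for reverse-biorthogonal 3.1, whose low computational cost
at equal accuracy is the usual argument for preferring it).

## 4. Features and normalization

Twelve feature sets (kinds `a`–`l`, `feature_set_kinds()`) are assembled
per channel and concatenated above-knee first. Numerical conventions:

* **Variance** is the unbiased (n−1) sample variance; a variance over a
  singleton coefficient vector is an error, caught at feature time (this
  only occurs for segments far shorter than the protocol's).
* **EDR of an all-zero segment** is undefined (0/0) and raises an error
  rather than returning a fallback; the generator's noise floor guarantees
  nonzero energy, so this only signals malformed input.
* **"Normalized"** means training-set min–max scaling to [0, 1]
  (`fit_normalizer()`), the simplest scheme consistent with a bounded
  sigmoid-network input; statistics come from the training split only, and
  test values are clipped into [0, 1]. A training-constant feature carries
  no information and maps to 0 with a warning. Alternatives (z-scoring,
  global scaling) were not pursued; the choice is a convention, recorded
  here because nothing forces it.

## 5. The classifier

A three-layer network (log-sigmoid hidden, linear output, one-hot targets,
argmax decisions with ties to the lowest class index) is trained by
Levenberg–Marquardt on the sum of squared output errors: steps solve
(JᵀJ + λI)Δw = Jᵀe with the full analytic Jacobian of all per-pattern,
per-output residuals (finite-difference-verified to 1e−5). λ starts at
1e−3, ×10 on rejection, ×0.1 on acceptance; a step is accepted only if the
SSE decreases, so the recorded history is monotone. Stopping: MSE ≤ 1e−4,
200 accepted epochs, or λ > 1e10. These defaults are ordinary LM practice;
the MSE goal is loose enough that classification accuracy, not regression
error, determines when capacity matters, and both stopping criteria are
exposed through `training_options()`.

Initialization is the uniform fan-in/fan-out rule (±√(6/(fan_in +
fan_out)), zero biases), deterministic per seed. `enlarge_hidden()` grows
the hidden layer (2, 4, …, 32 by default) and returns the smallest size
that classifies the training set perfectly, else the best size tried —
`run_single()` takes a fixed `n_hidden` (default 8, the 12:8:8 topology)
for speed, with `n_hidden = NULL` switching to the full search.

## 6. Experiments

`split_dataset()` stratifies by class by default: with 384 patterns and a
one-third fraction, every class contributes exactly 16 training patterns.
Plain random splitting is available behind a flag, but with 8 classes and
128 training slots stratification guarantees trainability and removes a
nuisance source of variance. `confusion_over_runs()` repeats training 10
times (the conventional repetition count) in two modes — `fixed_split`
(re-initialize only) and `resplit` (redraw the split too) — and reports
entry-wise mean ± sd confusion matrices in percent; per-iteration
initialization seeds can be overridden, and freezing them in `fixed_split`
mode removes all randomness (sd ≡ 0), which doubles as a determinism test.
Whether the hidden-size search should also be repeated per iteration is
ambiguous; the implementation fixes the topology across iterations and
leaves per-iteration enlarging to the caller via `n_hidden = NULL`.

Problem sizes were chosen for a desk machine: the full default study (768
segments, 24.6 M raw samples) simulates in seconds; one 12:8:8 training on
128 patterns takes a few seconds; the level and wavelet-family scans in
the test suite run on reduced protocols (fewer intervals, shorter
segments) that exercise identical code paths.

## 7. Known limitations

* The generator models one subject's consistent executions; no
  inter-subject variability, sensor misplacement, drift or bias.
* Harmonic weights barely influence variance features (all burst harmonics
  fall inside the level-5 approximation band at 133.4 Hz), so class
  separation rests on amplitude profiles and tremor; this mirrors the
  insensitivity of variance features to waveform detail.
* The discrete Meyer wavelet's approximation error (above) bounds its
  energy-feature fidelity.
* Accuracy figures obtained on synthetic data characterize the simulator's
  difficulty setting, not any real recording; they should be read as
  regression guarantees for the pipeline.
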