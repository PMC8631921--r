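---
title: "Surface-EMG finger-gesture recognition: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-EMG finger-gesture recognition: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`semgfgr` implements a complete surface-electromyography (sEMG)
finger-gesture recognition pipeline: a simulator for a six-channel
wireless sEMG acquisition chain, sliding-window segmentation,
continuous-wavelet-transform (CWT) scalogram features under six mother
wavelet families, a compact convolutional classifier, and accuracy-rate
statistics with model-selection grids over kernel size and wavelet
family. This vignette explains the underlying models, the numerical
choices, and what the synthetic data can and cannot establish.

## The acquisition model

Surface EMG is a weak, noise-like bioelectric signal: amplitudes of
0–10 mV peak-to-peak (0–1.5 mV RMS), energy essentially confined below
1 kHz with the dominant contribution between 50 and 150 Hz, and an
amplitude distribution well described as zero-mean Gaussian. The
simulated sensor follows a high-precision wireless design: 2 kHz
sampling, 16-bit conversion, a ×1000 conditioning gain with
second-order band-pass filtering over 5–1000 Hz, and an input-referred
noise floor of 1.5 µV RMS (`acquisition_config()`).

`theoretical_gain()` evaluates the conditioning circuit's printed gain
expression
\[
G = \Big(\tfrac{49.4\times 10^3}{R_G} + R_{c1} + 1\Big)\,
    \frac{R_3 R_{c3}}{R_{c2}R_{c3} + R_2 R_{c2} + R_2 R_{c3} + R_2 R_3},
\]
with an open-circuit gain resistor contributing zero to the first
factor. The \(R_{c1}\) term adds an impedance to a dimensionless gain
and is dimensionally suspect; it is evaluated as given (set
\(R_{c1}=0\) for the conventional instrumentation-amplifier reading).
The circuit-level expression takes component values as inputs; the
simulator itself uses the net figure of ×1000 as its nominal gain,
since no component values accompany the expression.

Digital realization: the band-pass is a single second-order Butterworth
section. The analog upper corner (1000 Hz) coincides with the Nyquist
frequency at 2 kHz sampling, where a bilinear-transform corner cannot
be placed; the digital corner is therefore capped at 0.99 × Nyquist.
The mid-band response is unaffected (the measured 100 Hz gain is within
0.3 % of nominal). The ADC is a mid-tread uniform quantizer over ±5 mV
(electrode-referred) with clipping to the end codes; clipping is
defined behaviour and its frequency is reported on the result.

## The synthetic gesture model

`simulate_trial()` synthesizes one gesture execution per channel as

    band-limited Gaussian carrier (unit RMS) × burst envelope (mV RMS)
      + white sensor noise  →  conditioning band-pass  →  ADC round trip

The carrier is white Gaussian noise shaped by a Butterworth band-pass
over the gesture's dominant-energy band; the envelope is a sum of Hann
bursts with per-channel amplitudes from the gesture's activation
matrix. The default eight-gesture set encodes class structure along two
physiologically motivated axes:

* **Channel topography.** Flexion gestures (TF, IF, MF) load the three
  flexor-side channels 1–3, extension gestures (TE, IE, ME) the
  extensor-side channels 4–6, with overlapping amplitude profiles
  (0.05–0.9 mV RMS) so no single channel is decisive.
* **Spectral signature.** Swing gestures (TS, IS) reuse the channel
  pattern of the corresponding flexion but carry a higher firing band,
  105–140 Hz against 60–95 Hz — both inside the physiological 50–150 Hz
  dominant range. The flexion/swing pairs are therefore separable only
  through time–frequency structure, which is precisely the property the
  scalogram featurization is supposed to expose; a classifier fed raw
  time-domain windows must resolve the band difference through its
  limited receptive field.

These parameter values were fixed once, from the published amplitude
and bandwidth ranges, as a realistic and learnable-but-nontrivial
configuration; they are deliberately not tuned against classifier
results. Per-subject variability is a lognormal channel-gain jitter
(sd 0.15 on the log scale), drawn once per subject.

What the generator does **not** emulate: motor-unit action-potential
shapes and firing statistics, amplitude non-stationarity within a
burst, electrode lift/shift artifacts, power-line interference,
crosstalk between channels, inter-session variability and fatigue.
Consequently, passing end-to-end tests demonstrates that the pipeline's
mechanics are correct and that scalograms recover the class structure
the generator encodes — not that the published real-data accuracies
would be reproduced on recordings.

## Segmentation

Trials are cut into 264-sample (132 ms at 2 kHz) windows advanced by
100 samples; trailing partial windows are discarded and windows never
span trial boundaries. The default trial length of 1364 samples is
chosen so that this yields exactly 12 windows per trial, reproducing
the published dataset bookkeeping (12 windows/trial × 25 trials ×
8 gestures × 5 subjects = 12 000 windows; 2400 per subject, split
1920/480). Segmentation is content-agnostic: no onset detection or
rest-period removal is attempted.

## Wavelets and the CWT

The transform implemented is
\[
X(a, b) = \frac{1}{\sqrt{b}} \int x(t)\, \psi\!\Big(\frac{t-a}{b}\Big)\, dt ,
\]
discretized on the signal's sample grid with one translation per sample
and zero extension beyond the window. Six mother-wavelet families are
provided: Mexican hat (`mexh`), first-derivative Gaussian (`gaus`),
complex Morlet (`cmor`), Shannon (`shan`), frequency B-spline (`fbsp`)
and first-order complex Gaussian (`cgau`).

Numerical choices worth knowing:

* **Normalization constants.** The closed-form constants quoted in
  common references for `mexh`, `gaus` and `cgau` are typographically
  unreliable; the package resolves them by unit-energy quadrature at
  construction (for the Mexican hat this reproduces
  \(2/(\sqrt{3}\,\pi^{1/4}) \approx 0.8673\)). Scalogram magnitudes are
  invariant to the sign (and, for model selection, the size) of these
  constants.
* **CGAU.** The undifferentiated product form
  \(e^{-it}e^{-t^2}\) sometimes quoted for this family has a non-zero
  mean and fails admissibility; the package implements the standard
  first-order complex Gaussian, the derivative of that product, which
  is admissible.
* **Default parameters.** `cmor`/`shan`/`fbsp` use \(f_b = 1.5\),
  \(f_c = 1.0\), \(m = 2\). With these values the Shannon wavelet's
  center frequency lies outside its pass-band half-width, so its mean
  is exactly zero.
* **Scale grid.** 64 scales, log-spaced in pseudo-frequency between 5
  and 1000 Hz (count published; spacing and endpoints are this
  package's choice, config-exposed). Pseudo-frequency maps to scale via
  \(f = f_c^{\mathrm{eff}} f_s / b\), with \(f_c^{\mathrm{eff}}\)
  located numerically at the peak of the sampled wavelet's Fourier
  magnitude (both spectral halves are searched; a modulated wavelet may
  be centred at a negative frequency, and the map uses the magnitude).
* **Boundary policy.** Zero extension. Oracle comparisons in the test
  suite restrict shift-covariance checks to interior columns at least
  one (decay-thresholded) wavelet support away from the edges; at the
  largest scales the dilated wavelet spans the whole 264-sample window
  and every coefficient is boundary-affected — a property inherent to
  132 ms windows at 5 Hz pseudo-frequency, not an implementation
  artifact.
* **Admissibility diagnostics.** `admissibility_check()` reports the
  sampled admissibility integral
  \(\int |\hat\psi(\omega)|^2/\omega\, d\omega\) and a zero-mean
  residual \(|\int \psi\,dt|\) relative to the L1 norm (tolerance
  \(10^{-6}\)). For the Shannon family the sinc envelope decays only
  like \(1/t\), so a plainly truncated integral cannot reach that
  tolerance on any practical grid; the residual is computed by
  tail-averaging the cumulative trapezoid integral over the last beat
  periods, which cancels the oscillatory truncation term. The Morlet's
  residual is its true analytic mean \(e^{-\pi^2 f_b}\approx
  3.7\times10^{-7}\) — the Morlet is only approximately admissible, and
  sits just inside the tolerance at the default bandwidth.

The fast path evaluates all scales by FFT convolution with precomputed
frequency-domain kernels; the test suite pins it against a direct
Riemann-sum evaluation of the integral (relative error below
\(10^{-6}\), observed at machine precision).

Scalograms are plain (not squared) coefficient magnitudes — squared
magnitude is available as a flag — stacked as a
(6 channels × 64 scales × 264 samples) tensor.

## The classifier

The network is deliberately compact: five convolutional stages with
16, 32, 32, 64 feature maps (strides 1, 2, 1, 2, ReLU), channelwise
dropout \(P = 0.5\) after stage 2, and a final convolution onto the
eight class maps followed by global average pooling in place of a
fully connected head. Same-style padding (`k %/% 2`) keeps stride-1
stages size-preserving; the global average makes the head independent
of the input's spatial size, so raw time-domain windows (1 × 264) and
scalograms (64 × 264) feed the identical architecture. Convolutions are
im2col + GEMM with analytically verified backward passes (the suite
checks them against central differences away from ReLU kinks).

Training minimizes softmax cross-entropy with one-hot targets
(\(\mathrm{Loss} = -\sum_i y_i \log y_i'\)) using Adam
(defaults: learning rate \(10^{-3}\), optional per-epoch exponential
decay, batch 32, up to 150 epochs, early-stopping patience 20). The
optimizer family and hyperparameters are this package's choices —
the published description fixes only the architecture, the loss and
the dropout placement. Feature normalization is owned by the trained
model: per-channel statistics are fit on the training portion only and
stored with the model. Non-negative magnitude features get a
logarithmic compression (`log1p(x / ref)` with `ref` the channel's
median positive magnitude) before standardization, which tames the wide
dynamic range of wavelet magnitudes across scales; signed time-domain
features get a plain z-score. Both transforms are invertible from the
stored record. Training is a pure function of its seed: initialization,
internal stratified train/monitor split, shuffling and dropout masks
all derive from it, and two runs with the same seed produce identical
parameter trajectories.

## Evaluation statistics

For one run over \(t\) test windows the accuracy rate is
\(AR = t^{-1}\sum_i \Psi(w, f(x_i))\) with the 0/1 agreement indicator
\(\Psi\). A set of \(n\) runs is summarized by
\(MAR = n^{-1}\sum_k AR_k\) and the **population** standard deviation
\(SD\text{-}AR = \sqrt{n^{-1}\sum_k (AR_k - MAR)^2}\). The 1/n
convention is pinned by the published summary rows, which the test
suite reproduces to two decimals; the sample (1/(n−1)) convention does
not reproduce them. Reporting is percent-scale with two-decimal
rounding; internal arithmetic is kept in fractions.

The grid runner (`run_grid()`) trains one model per (kernel size,
wavelet family, subject) cell, each with a seed derived from the master
seed by a documented integer hash (`derive_seed()`), and summarizes
each configuration with MAR/SD-AR across subjects (the \(n\) of the
summary is the subject count; this is recorded in the output metadata).
Failed configurations are recorded as failed rows, never skipped
silently.

## Dataset container and splits

Trials are stored as plain-text containers: a JSON manifest plus one
CSV per trial. Trials whose samples sit exactly on the ADC grid — the
simulator's always do — are stored as integer ADC codes with the LSB in
the manifest, making the round trip bit-exact without binary formats.
Manifest counts are validated on load and the first offending record is
named in the error.

The train/test split is window-level, stratified by gesture within
subject: 2400 × 0.8 = 1920 matches the published per-subject counts
exactly only under window-level splitting. Because consecutive windows
from one trial overlap by 164 samples, window-level splitting leaks
trial content between train and test; this is inherent to that
bookkeeping and is stated here prominently. Nothing in the package
prevents splitting at trial granularity instead: pass trial-level
labels to `make_split()` (one entry per trial) and expand the resulting
trial indices to their windows.

## Problem sizes in the test suite

The structural bookkeeping checks run the full default design
(5 subjects × 8 gestures × 25 trials, 12 000 windows). The end-to-end
classification experiments use a reduced design chosen as this
package's experiment size: one subject, 6 trials per gesture
(576 windows, split 464/112), Mexican-hat scalograms, and a training
budget of 48 epochs at batch 16 with exponential learning-rate decay
(2 × 10⁻³, factor 0.97 per epoch).
At this size the experiment completes in minutes on one core while
leaving a clear margin between scalogram and time-domain performance;
scaling the design back up only narrows the variance of the measured
accuracies. The grid-runner tests use even smaller trials (2 subjects,
2 trials per gesture, 464-sample trials, 16 scales) because they check
protocol properties — row counts, determinism, summary consistency —
rather than accuracy levels.

## Known limitations

* The simulator's class structure is stylized; real sEMG class overlap
  is driven by anatomy and electrode placement, not by designed
  activation matrices. Published real-data accuracies are out of reach
  of any synthetic reconstruction and are not reproduction targets.
* The CWT at the lowest pseudo-frequencies (near 5 Hz) is dominated by
  boundary effects within a 132 ms window.
* The CNN runs on the CPU in double precision; it is sized for this
  problem (≈38 k parameters at kernel 3), not for large-scale use.
* `SHAN`'s slowly decaying envelope makes its scalograms sensitive to
  the zero-extension boundary over the whole window; it is retained for
  completeness of the family comparison.
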