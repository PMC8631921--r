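# semgfgr

Surface-electromyography (sEMG) finger-gesture recognition with
continuous-wavelet-transform scalograms and a compact convolutional
network, together with a physically grounded simulator for the
six-channel wireless acquisition chain that such experiments run on.
The package is for biosignal-processing researchers and students who
want a fully reproducible, end-to-end reference pipeline — from raw
multichannel millivolt traces to per-subject accuracy tables — without
access to proprietary recordings or a deep-learning runtime.

## The method

Eight finger gestures (thumb/index/middle flexion, extension and
thumb/index swing: TF, TE, TS, IF, IE, IS, MF, ME) are classified from
six forearm sEMG channels sampled at 2 kHz:

1. **Acquisition.** Each channel passes a conditioning chain with
   nominal gain ×1000, a second-order 5–1000 Hz band-pass and a 16-bit
   ADC (mid-tread, ±5 mV electrode-referred). The circuit-level gain is
   `G = (49.4e3/R_G + R_c1 + 1) · R_3 R_c3 / (R_c2 R_c3 + R_2 R_c2 + R_2 R_c3 + R_2 R_3)`.
   The built-in simulator reproduces the signal statistics: zero-mean
   Gaussian amplitudes, 0–10 mV peak-to-peak, energy below 1 kHz with
   its dominant part in 50–150 Hz.
2. **Segmentation.** Sliding windows of 264 samples (132 ms) advanced
   by 100 samples; a 1364-sample trial yields 12 windows, so the
   default design (5 subjects × 8 gestures × 25 trials) gives 12 000
   windows, split 1920/480 per subject.
3. **Features.** The CWT
   `X(a,b) = b^{-1/2} ∫ x(t) ψ((t−a)/b) dt`
   on 64 log-spaced scales (pseudo-frequencies 5–1000 Hz) under six
   admissible mother wavelets (`mexh`, `gaus`, `cmor`, `shan`, `fbsp`,
   `cgau`); coefficient magnitudes form a 6 × 64 × 264 scalogram
   tensor. An STFT spectrogram is provided as the classical
   fixed-resolution alternative.
4. **Classifier.** A compact CNN: conv(16, s1) → conv(32, s2) →
   dropout 0.5 → conv(32, s1) → conv(64, s2) → conv(n_classes) →
   global average pooling (no fully connected head), trained with
   softmax cross-entropy `Loss = −Σ y_i log y_i'` and Adam.
   Convolutions are im2col + GEMM in C++ (RcppArmadillo), with
   analytically verified gradients.
5. **Evaluation.** Per-run accuracy rate `AR = t^{-1} Σ Ψ(w, f(x_i))`,
   summarized across runs by `MAR` (mean) and `SD-AR` (population 1/n
   standard deviation), plus confusion matrices and model-selection
   grids over kernel size {3,5,7,9} and wavelet family.

## Worked example

Simulate a small two-subject dataset, run the grid protocol for one
configuration (Mexican-hat scalograms, 3×3 kernels), and summarize
per-subject accuracy:

```r
library(semgfgr)
cfg <- acquisition_config()            # 2 kHz, 16 bit, x1000, 5-1000 Hz, 6 ch
trials <- simulate_dataset(cfg, n_subjects = 2, trials_per_gesture = 3,
                           duration_samples = 664, master_seed = 42)
res <- run_grid(trials, kernels = 3, wavelets = "mexh", master_seed = 42,
                train_cfg = train_config(learning_rate = 2e-3, lr_decay = 0.97,
                                         batch_size = 16, max_epochs = 15,
                                         patience = 15))
res$runs
#>   kernel wavelet subject      seed ar_percent status
#> 1      3    mexh       1 916802169   66.66667     ok
#> 2      3    mexh       2 916802170   66.66667     ok
res$summary
#>   kernel wavelet      mar sd_ar n
#> 1      3    mexh 66.66667     0 2
```

Each row is one per-subject model: windows are split 80/20 stratified
by gesture within subject, a CNN is trained on that subject's training
windows with a seed derived from the master seed, and `ar_percent` is
the accuracy rate on the held-out windows. `mar`/`sd_ar` summarize the
configuration across subjects (population standard deviation). At this
deliberately tiny size (3 short trials per gesture, 15 epochs) the
absolute accuracies are modest; the end-to-end acceptance experiment in
`tests/testthat/test-acceptance.R` runs the calibrated size (6 full
trials per gesture, 48 epochs) where scalogram features reach ≥ 95 %
held-out accuracy and beat raw time-domain input under the identical
network and seed.

A command-line interface wrapping the same functions ships under
`inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "semg-fgr", package = "semgfgr"))')" \
  simulate --subjects 2 --trials 3 --seed 42 --out /tmp/ds
```

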