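---
title: "Denoising electrode-motion artifacts with a feature-shuffle attention autoencoder"
author: "ecgfmha"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising electrode-motion artifacts with a feature-shuffle attention autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgfmha)
```

## The problem

Ambulatory and wearable ECG recordings are contaminated by several artifact
classes: baseline wander (sub-0.5 Hz drift), muscle activity (broadband EMG),
power-line pickup (50/60 Hz), and — hardest of all — electrode-motion (EM)
artifacts. EM transients arise from mechanical disturbance of the
electrode–skin interface; they are large, nonstationary, spectrally overlap
the cardiac waves themselves, and can mimic ectopic beats. Linear filters
cannot separate them from signal, which motivates a learned denoiser.

`ecgfmha` implements a feature-shuffle multi-head attention autoencoder
(FMHA-AE): a 1-D encoder–decoder network that maps a noisy 1024-sample ECG
segment to its clean counterpart, together with everything needed to train
and evaluate it on synthetic data (and, optionally, on the MIT-BIH
databases via the bundled WFDB reader).

## The architecture

All feature maps are `C x N` arrays (channels by samples). The building
blocks:

* **Residual block** — two same-channel 1-D convolutions of length 5
  (padding 2), `y = ReLU(conv2(ReLU(conv1(x))) + x)`. Used at the start of
  every stage and in the input/output layers.
* **Feature unshuffle / shuffle** — the lossless 1-D analogue of pixel
  (un)shuffle: `feature_unshuffle()` de-interleaves each channel's even and
  odd samples into two channels (`C x N -> 2C x N/2`), `feature_shuffle()`
  is its exact inverse. Down- and up-sampling therefore lose no
  information; a following point-wise (1x1) convolution restores the
  channel count, so each encoder stage halves the length at constant width
  and each decoder stage doubles it.
* **Multi-head self-attention (MHSA)** — the `N` time steps are tokens of
  dimension `C`; per head `i`, `head_i = softmax(Q_i K_i' / sqrt(d_k)) V_i`
  with `d_k = C/h`, heads concatenated and projected by `W_O`. Attention
  maps are `N x N`, i.e. across time.
* **Channel-attention shortcut** — the six skip paths between matching
  encoder/decoder resolutions use the same projection + FFN structure, but
  the attention map is computed *between channels*:
  `A_i = softmax(Q_i' K_i / sqrt(N))`, a `d_k x d_k` matrix. Consequently a
  shortcut block's parameter count is independent of its sequence length
  (198,272 at the default width, at every stage).
* **Multi-head cross-attention (MHCA)** — decoder queries attend to the raw
  encoder bottleneck (the deepest encoder output, `128 x 8` by default),
  which gives every decoder stage direct access to the global summary of
  the segment.
* **Feed-forward network** — position-wise `max(0, X W_1 + b_1) W_2 + b_2`
  with hidden width `d_ff = 4C`.

Attention and FFN sub-blocks are wired post-norm (`y = LN(x + SubBlock(x))`,
normalization over the channel axis, epsilon `1e-5`), the convention of the
original transformer. There is no positional encoding: the convolutional
blocks carry locality, and the per-block parameter accounting (below) leaves
no room for embedding parameters. The shortcut output is merged into the
decoder path by parameter-free element-wise addition at the matching
resolution; the bottleneck-side decoder stage is the one stage without a
shortcut, matching the six-shortcut count at depth seven.

`parameter_table()` prints the accounting for any configuration. At the
default (`C = 128`, depth 7, `h = 4`, `d_ff = 512`, kernel 5):

| block | parameters | composition |
|---|---|---|
| input layer | 164,352 | 1x1 conv 1→128 (256) + residual block (164,096) |
| encoder stage | 395,264 | residual block + 1x1 conv 256→128 (32,896) + 4 projections (66,048) + FFN (131,712) + 2 LN (512) |
| shortcut | 198,272 | 4 projections + FFN + 2 LN |
| decoder stage | 395,392 | residual block + 1x1 conv 128→256 (33,024) + 4 projections + FFN + 2 LN |
| output layer | 164,225 | residual block + 1x1 conv 128→1 (129) |

for a total of 7,052,801 trainable scalars. Every convolution and linear
projection carries a bias — required for these counts to close. This
decomposition is normative for the package: `count_parameters()` counts the
actual tensors of the compiled network, and the test suite pins each block
to the numbers above.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `channels` | 128 | width `C` after input expansion (ablation axis: 64/128/256) |
| `depth` | 7 | encoder/decoder stages; length must divide by `2^depth` |
| `heads` | 4 | attention heads (ablation axis: 2/4/8/16); `C/h` integral |
| `d_ff` | `4*C` | FFN hidden width |
| `kernel` | 5 | residual-block convolution length |
| `segment_length` | 1024 | samples per segment (about 2.8 s at 360 Hz, 2–4 beats) |
| `lr`, `lr_step`, `lr_gamma` | 1e-4, 200, 0.5 | Adam step-decay schedule |
| `batch_size`, `epochs` | 32, 1000 | full-scale training recipe |

The decay fires at epoch boundaries as `lr0 * gamma^floor(epoch/step)` with
zero-based epochs, so the rate first halves entering epoch 200.

## Numerical implementation

The network forward pass, reverse-mode gradients and the Adam loop are
compiled code (RcppArmadillo). Design points worth knowing:

* **Precision.** Training runs in single precision — the standard precision
  for this model class, and what BLAS `sgemm` throughput rewards — while a
  templated double-precision path exists for verification. The softmax uses
  a vectorizable polynomial `expf` approximation (relative error ~2e-6,
  far below float accumulation error) in single precision and exact
  `std::exp` in double.
* **Verification.** Every block also exists as an exported pure-R function
  (`residual_block()`, `mhsa()`, `mhca()`, `channel_mhsa()`, `ffn()`,
  `layer_norm()`, `encoder_block()`, `decoder_block()`), and
  `fmha_forward_ref()` composes them into a reference forward pass. The
  tests require the compiled double-precision pass to match the reference
  to 1e-10, the analytic gradient to match central differences on probes
  of every tensor, and the gradient to be nonzero on every tensor (no dead
  branches).
* **Determinism.** Weight initialization (fan-in uniform,
  `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; LN gains 1, shifts 0) is driven by
  `fmha_config()$seed` through R's RNG; mini-batch shuffling uses its own
  fixed 64-bit generator seeded by `fit_fmha()`'s `seed`. Two runs with the
  same seeds produce bit-identical weights and loss histories.
* **Degenerate inputs.** All-zero segments are rejected at normalization
  (`max|x| = 0`) and at mixing (silent noise or silent clean signal);
  non-finite training loss aborts with a diagnostic rather than continuing.

## Data preparation protocol

Signals are cut into non-overlapping 1024-sample segments (trailing
remainder discarded), DC-removed, and scaled into `[-1, 1]`. Normalization
is symmetric max-absolute scaling *per segment*: together with DC removal it
guarantees zero mean and unit peak simultaneously, whereas min–max scaling
would re-introduce an offset. Noise is mixed after preprocessing with
`mix_at_snr()`, which solves for the noise gain in closed form so the
realized input SNR equals the nominal level exactly (the tests demand
1e-6 dB). Because mixing can push the noisy trace outside `[-1, 1]` at low
SNR, each pair is then rescaled by the noisy segment's peak when that peak
exceeds one; scaling clean and noisy by the same constant leaves the SNR
ratio — a homogeneous function of degree zero — untouched, so the nominal
label stays exact. The train/test split is random, seeded, and sized
`ceiling(0.8 n)` / the remainder. When real pre-mixed noise-stress records
are loaded via `read_wfdb()`, no re-mixing is done and the record's nominal
level is trusted.

## What the synthetic generator does and does not emulate

`synth_ecg()` builds a quasi-periodic PQRST train as a sum of five Gaussian
bumps per beat (amplitudes 0.10/−0.15/1.00/−0.25/0.30 mV; offsets
−0.20/−0.05/0/0.05/0.30 s; widths 40/10/15/10/70 ms) on a beat grid with
5% RR jitter and a heart rate drawn once from 60–100 bpm. The morphology is
deliberately analytic — beat counts and peak positions have closed-form
oracles, which is what makes the generator testable. Electrode motion is
emulated as sub-10 Hz filtered Gaussian noise plus sparse smoothed baseline
steps with Poisson arrivals and R-wave-scale amplitudes (the component that
mimics ectopic beats); baseline wander as a sub-0.5 Hz sinusoid mixture;
muscle artifact as 20–150 Hz band-passed noise; mains pickup as a 60 Hz
sinusoid. Each class consumes its own random stream split from the master
seed, so adding one noise type never perturbs another's draws.

What this does **not** capture: real beat-morphology variability and
arrhythmia, heart-rate dynamics, the precise spectra of electrode-pop
transients, or multi-lead correlation. A passing suite therefore shows the
architecture, optimizer and protocol are implemented correctly and that the
model learns to suppress EM-like noise — it does not certify clinical
performance on real recordings, which requires the full MIT-BIH protocol
(`inst/scripts/full_reproduction.R`).

## Classical baselines

Three non-learned comparators with a common 0.67–40 Hz band:

* **FIR**: window-method band-pass, 101 taps with a Hanning window (an odd
  tap count gives a symmetric type-I design; "order 101" is read as the tap
  count), applied with group-delay compensation. A design this short has a
  transition width of several hertz at 360 Hz, so its 0.67 Hz high-pass
  edge is unresolved: sub-hertz drift is only mildly attenuated
  (|H(0.1 Hz)| ≈ 0.86, confirmed against an external filter-design
  oracle). That is an inherent property of the specified filter length,
  and the FIR tests assert it as such.
* **IIR**: fourth-order Butterworth band-pass applied zero-phase — a causal
  pass would shear the QRS complex. The direct 8th-order polynomial is
  badly conditioned with a band edge this close to DC, so the filter runs
  as a cascade of second-order sections (conjugate pole pair plus a
  `z^2 - 1` numerator each) in compiled code, with steady-state initial
  conditions per section and even-mirror edge padding sized to the slowest
  pole's time constant. Even padding matters: the usual point-symmetric
  (odd) extension adds a `2 x_end` DC plateau to the pads, which the
  near-DC edge turns into a slow transient that rings far into the data
  tail. Stability is checked via the pole radii.
* **DWT**: nine-level db6 decomposition with the two highest-frequency
  detail bands and the lowest-frequency approximation nullified, symmetric
  (half-point) boundary extension. No wavelet package is declared: the
  multilevel transform is implemented in the package
  (`dwt_multilevel()` / `idwt_multilevel()`), and the tests pin it against
  an externally computed reference decomposition and require exact
  reconstruction.

All three are linear, length-preserving operators; on purely out-of-band
noise (drift, mains) they achieve positive SNR improvement, which the suite
verifies.

## Problem sizes in the test suite

The published training recipe (1000 epochs on ~7000 MIT-BIH segment pairs,
a 7 M-parameter model) is hours of GPU work and is shipped only as the
optional full-reproduction script. The suite instead trains a desk-scale
instance — width 32, depth 4, heads 4, `d_ff` 128, the published batch size
32 and learning rate — for 20 epochs on 600 synthetic EM pairs at 0 dB with
the standard 80:20 split, and requires a mean SNR improvement above +3 dB on
the held-out fifth, a monotone-trending loss history, and bit-identical
re-runs under fixed seeds. 600 pairs is the package's chosen desk scale: it
is the smallest round size at which the benchmark's headroom over the +3 dB
bar is comfortable while a complete suite run stays in the minutes range on
one CPU core; growing `n_segments` (the generator takes any size) tightens
the result but only lengthens the run. The remaining tests run tiny
configurations (widths 8–16, lengths 32–256) because the properties they
check — oracle equivalence, gradient correctness, shape and count
contracts — are size-independent.

## Known limitations

* Single-lead only; no multi-lead correlation modeling.
* The PRD metric includes the square root (an all-zero reconstruction
  scores exactly 100%), the standard reading of the acronym.
* Aggregation over a test set is a uniform mean over segments within each
  nominal level, then a uniform mean over levels for the average column.
* The compiled core targets x86-64 with AVX2/FMA; exotic hosts fall back to
  compiling, but the suite's runtimes assume vectorized builds.
* `read_wfdb()` handles formats 212 and 16 (the MIT-BIH encodings) only.
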