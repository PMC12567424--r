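# ecgfmha

Removal of electrode-motion (EM) artifacts from single-lead ECG with a
**feature-shuffle multi-head attention autoencoder (FMHA-AE)**, for signal
processing researchers and engineers working on noise-robust ECG analysis.

EM artifacts — large, nonstationary transients from electrode–skin interface
shifts — overlap the cardiac waves in frequency and can mimic ectopic beats,
so fixed filters cannot remove them. FMHA-AE instead learns the mapping from
noisy to clean 1024-sample segments with an encoder–decoder network built
from:

* residual convolution blocks, `y = ReLU(conv2(ReLU(conv1(x))) + x)`
  (length-5 kernels, padding 2);
* lossless 1-D **feature unshuffle/shuffle** resampling
  (`C x N <-> 2C x N/2`, even/odd de-interleave and its inverse) paired with
  point-wise convolutions, so each of the 7 encoder stages halves the
  length and each of the 7 decoder stages doubles it at constant width;
* **multi-head self-attention** over time steps in the encoder,
  `head_i = softmax(Q_i K_i^T / sqrt(d_k)) V_i`, `d_k = C/h`;
* **channel-attention shortcuts** (six, one per intermediate resolution),
  whose `d_k x d_k` attention maps are computed between channels and whose
  parameter count is independent of sequence length;
* **multi-head cross-attention** in the decoder, with queries from the
  decoder path and keys/values from the `128 x 8` encoder bottleneck.

Training minimizes the MSE between the reconstruction and the clean target
(Adam, batch 32, learning rate 1e-4 halved every 200 epochs). Performance
is reported as SNR improvement
`SNR_imp = 10 log10(SNR_out) - 10 log10(SNR_in)` (dB), percentage
root-mean-square difference (PRD, %) and RMSE, per nominal input SNR level
(−6 … 24 dB).

The package also ships the surrounding protocol: synthetic ECG and artifact
generators (so everything is testable offline), segmentation / DC-removal /
normalization / exact-SNR noise mixing, a minimal WFDB reader for the
MIT-BIH databases, and the classical FIR / IIR / db6-wavelet baseline
denoisers. The network's forward/backward passes and Adam loop are compiled
(RcppArmadillo); every block also exists as an exported pure-R reference
implementation that the compiled path is tested against.

## Worked example

Train a small instance on synthetic electrode-motion noise at 0 dB and
evaluate it on held-out pairs:

```r
library(ecgfmha)

pairs <- generate_dataset(600, snr_levels = 0, seed = 11)   # 1024-sample pairs
sp    <- split_dataset(pairs, 0.8, seed = 12)

model <- fmha_init(fmha_config(channels = 32, depth = 4, heads = 4,
                               d_ff = 128, segment_length = 1024, seed = 21))
fit   <- fit_fmha(model, sp$train, epochs = 20, batch_size = 32, seed = 22)
fit
evaluate_denoiser(fit, sp$test)
```

```
Fitted FMHA-AE denoiser
FMHA-AE model: C = 32, depth = 4, heads = 4, d_ff = 128, segment 1024
  259,649 trainable parameters in 236 tensors
  trained 20 epochs on 480 pairs (batch 32, Adam, lr 0.0001 halved every 200 epochs)
  final training MSE: 0.00443908
Denoising metrics by nominal input SNR
 Input SNR   n SNR_imp (dB) PRD (%)   RMSE
      0 dB 120        9.486  34.066 0.0623
      Avg. 120        9.486  34.066 0.0623
```

A mean SNR improvement of +9.5 dB at 0 dB input means the trained network
reduces the noise energy about nine-fold relative to the noisy input;
PRD and RMSE measure the remaining reconstruction error against the clean
signal.
The identity mapping scores 0 dB / 100 % on the same pairs, and the
classical baselines (`filter_spec("fir")`, `"iir"`, `"dwt"` passed to
`evaluate_denoiser()`) barely improve EM noise because it shares the
signal band — the motivation for the learned model.

The published-size architecture is the default configuration:

```r
parameter_table(fmha_config())   # 164,352 / 395,264 / 198,272 / 395,392 / 164,225
count_parameters(fmha_config())  # 7,052,801
```

`inst/cli/ecgfmha` exposes `simulate`, `train`, `denoise`, `evaluate` and
`count-params` subcommands for shell use, and
`inst/scripts/full_reproduction.R` documents the full-scale MIT-BIH
protocol (requires the PhysioNet databases and long CPU/GPU time).

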