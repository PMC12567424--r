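# Independent brute-force oracles used across the suite. These are written
# directly from the index formulas / definitions and never share code with
# the implementation they check.

# even/odd de-interleave by explicit loops over the zero-based index mapping
unshuffle_oracle <- function(x) {
  ch <- nrow(x); n <- ncol(x)
  out <- matrix(0, 2 * ch, n / 2)
  for (k in 0:(ch - 1)) for (j in 0:(n / 2 - 1)) {
    out[2 * k + 1, j + 1] <- x[k + 1, 2 * j + 1]
    out[2 * k + 2, j + 1] <- x[k + 1, 2 * j + 2]
  }
  out
}

shuffle_oracle <- function(x) {
  ch2 <- nrow(x); n2 <- ncol(x)
  out <- matrix(0, ch2 / 2, 2 * n2)
  for (k in 0:(ch2 / 2 - 1)) for (i in 0:(2 * n2 - 1)) {
    out[k + 1, i + 1] <- if (i %% 2 == 0) x[2 * k + 1, i / 2 + 1]
                         else x[2 * k + 2, (i - 1) / 2 + 1]
  }
  out
}

# scalar-loop metric oracles
snr_ratio_oracle <- function(clean, other) {
  num <- 0; den <- 0
  for (i in seq_along(clean)) {
    num <- num + clean[i]^2
    den <- den + (clean[i] - other[i])^2
  }
  num / den
}

prd_oracle <- function(clean, denoised) {
  num <- 0; den <- 0
  for (i in seq_along(clean)) {
    num <- num + (clean[i] - denoised[i])^2
    den <- den + clean[i]^2
  }
  100 * sqrt(num / den)
}

rmse_oracle <- function(clean, denoised) {
  s <- 0
  for (i in seq_along(clean)) s <- s + (clean[i] - denoised[i])^2
  sqrt(s / length(clean))
}

# three-nested-loop multi-head attention (tokens in rows of X)
attention_oracle <- function(X, K_src, params, heads, scale_len = NULL) {
  L <- nrow(X); C <- ncol(X); dk <- C / heads
  Q <- sweep(X %*% params$Wq, 2, params$bq, "+")
  K <- sweep(K_src %*% params$Wk, 2, params$bk, "+")
  V <- sweep(K_src %*% params$Wv, 2, params$bv, "+")
  out <- matrix(0, L, C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    S <- matrix(0, L, nrow(K_src))
    for (i in seq_len(L)) for (j in seq_len(nrow(K_src))) {
      acc <- 0
      for (d in cols) acc <- acc + Q[i, d] * K[j, d]
      S[i, j] <- acc / sqrt(dk)
    }
    A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
    for (i in seq_len(L)) for (d in seq_along(cols)) {
      acc <- 0
      for (j in seq_len(nrow(K_src))) acc <- acc + A[i, j] * V[j, cols[d]]
      out[i, cols[d]] <- acc
    }
  }
  sweep(out %*% params$Wo, 2, params$bo, "+")
}

# random attention/ffn weight helpers for block-level tests
rand_attn_params <- function(C) {
  list(Wq = matrix(rnorm(C * C), C), bq = rnorm(C),
       Wk = matrix(rnorm(C * C), C), bk = rnorm(C),
       Wv = matrix(rnorm(C * C), C), bv = rnorm(C),
       Wo = matrix(rnorm(C * C), C), bo = rnorm(C))
}

rand_ffn_params <- function(C, dff) {
  list(W1 = matrix(rnorm(C * dff), C), b1 = rnorm(dff),
       W2 = matrix(rnorm(dff * C), dff), b2 = rnorm(C))
}

# fraction of periodogram power at or below a cutoff frequency
spectral_fraction_below <- function(x, cutoff_hz, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sum(p[half & freqs <= cutoff_hz]) / sum(p[half])
}

spectral_fraction_band <- function(x, lo_hz, hi_hz, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sum(p[half & freqs >= lo_hz & freqs <= hi_hz]) / sum(p[half])
}

rms <- function(x) sqrt(mean(x^2))

# low-band energy of the Hann-windowed periodogram (windowing suppresses
# spectral leakage from in-band tones into the lowest bins)
windowed_low_energy <- function(x, cutoff_hz, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  p <- Mod(stats::fft(x * w))^2
  freqs <- (seq_len(n) - 1) * fs / n
  sum(p[freqs <= cutoff_hz])
}

count_major_peaks <- function(x, rel = 0.5) {
  thr <- rel * max(x)
  n <- length(x)
  sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] & x[2:(n - 1)] > thr)
}
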