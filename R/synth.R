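#' Default PQRST wave parameters
#'
#' Gaussian bump parameters of the synthetic heartbeat: amplitude (mV),
#' center offset from the R peak (s) and width (s) of the P, Q, R, S and T
#' waves.
#'
#' @return A data frame with columns `wave`, `amplitude`, `center`, `width`.
#' @export
ecg_waves <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amplitude = c(0.10, -0.15, 1.00, -0.25, 0.30),
             center = c(-0.20, -0.05, 0.00, 0.05, 0.30),
             width = c(0.040, 0.010, 0.015, 0.010, 0.070),
             stringsAsFactors = FALSE)
}

#' Synthesize a clean quasi-periodic ECG
#'
#' Sum-of-Gaussians PQRST morphology on a jittered beat grid: each beat is a
#' fixed set of Gaussian bumps ([ecg_waves()]) centered on R-peak times whose
#' intervals are `60/heart_rate` seconds perturbed by multiplicative Gaussian
#' jitter. The morphology is deliberately analytic so that beat counts and
#' peak locations have closed-form oracles.
#'
#' @param duration Signal duration in seconds.
#' @param sampling_rate Sampling rate in Hz (default 360).
#' @param heart_rate Beats per minute; `NULL` (default) draws one rate
#'   uniformly from 60-100 bpm.
#' @param rr_jitter Fractional standard deviation of the beat-to-beat
#'   interval (default 0.05; 0 gives a strictly periodic train).
#' @param waves Wave parameter table, see [ecg_waves()].
#' @param seed Integer seed; the same seed reproduces the signal exactly.
#' @return Numeric vector of `duration * sampling_rate` samples (mV).
#' @export
synth_ecg <- function(duration, sampling_rate = 360, heart_rate = NULL,
                      rr_jitter = 0.05, waves = ecg_waves(), seed = NULL) {
  n <- floor(duration * sampling_rate)
  .with_seed(seed, {
    hr <- if (is.null(heart_rate)) runif(1, 60, 100) else heart_rate
    rr <- 60 / hr
    if (duration < rr)
      stop("duration (", duration, " s) is shorter than one beat (", round(rr, 2), " s)")
    nbeat <- ceiling(duration / rr) + 2L
    intervals <- rr * pmax(1 + rr_jitter * rnorm(nbeat), 0.3)
    beats <- cumsum(c(rr / 2, intervals[-1L]))   # first R peak half a beat in
    t <- (seq_len(n) - 1L) / sampling_rate
    x <- numeric(n)
    for (b in beats) {
      if (b - 0.5 > duration) break
      for (w in seq_len(nrow(waves))) {
        mu <- b + waves$center[w]
        x <- x + waves$amplitude[w] * exp(-(t - mu)^2 / (2 * waves$width[w]^2))
      }
    }
    x
  })
}

# zero-phase low-pass via a Butterworth design; falls back to the identity
# when the band is the whole spectrum
.lowpass <- function(x, cutoff_hz, fs, order = 4L) {
  wc <- cutoff_hz / (fs / 2)
  if (wc >= 1) return(x)
  bt <- signal::butter(order, wc, type = "low")
  signal::filtfilt(bt, x)
}

#' Synthesize electrode-motion artifact
#'
#' Emulates the dominant character of electrode-motion noise: large,
#' nonstationary low-frequency transients. Two additive parts: (a) Gaussian
#' noise low-pass filtered below 10 Hz, and (b) sparse smoothed baseline
#' steps with Poisson arrivals and amplitudes comparable to the R wave --
#' the step component is what lets this artifact mimic ectopic beats.
#'
#' @param duration Duration in seconds.
#' @param sampling_rate Hz.
#' @param sd Standard deviation of the filtered Gaussian component (mV).
#' @param step_rate Mean number of baseline steps per second.
#' @param step_amplitude Step amplitude scale (mV, sd of a Gaussian draw).
#' @param seed Integer seed.
#' @return Numeric vector of `duration * sampling_rate` samples.
#' @export
synth_em_noise <- function(duration, sampling_rate = 360, sd = 1,
                           step_rate = 0.5, step_amplitude = 1, seed = NULL) {
  n <- floor(duration * sampling_rate)
  .with_seed(seed, {
    base <- if (sd > 0) .lowpass(rnorm(n, sd = sd), 10, sampling_rate) else numeric(n)
    steps <- numeric(n)
    k <- rpois(1, step_rate * duration)
    if (k > 0 && step_amplitude > 0) {
      at <- sort(runif(k, 0, duration))
      amp <- rnorm(k, sd = step_amplitude)
      t <- (seq_len(n) - 1L) / sampling_rate
      tau <- 0.05                               # 50 ms rise time
      for (i in seq_len(k))
        steps <- steps + amp[i] / (1 + exp(-(t - at[i]) / tau))
      steps <- steps - mean(steps)
    }
    base + steps
  })
}

#' Synthesize baseline wander
#'
#' Mixture of three sub-0.5 Hz sinusoids with random frequencies, phases and
#' amplitudes -- the slow respiratory/posture drift superimposed on
#' ambulatory ECG.
#'
#' @inheritParams synth_em_noise
#' @param amplitude Overall amplitude scale (mV).
#' @return Numeric vector.
#' @export
synth_bw_noise <- function(duration, sampling_rate = 360, amplitude = 1, seed = NULL) {
  n <- floor(duration * sampling_rate)
  .with_seed(seed, {
    t <- (seq_len(n) - 1L) / sampling_rate
    f <- runif(3, 0.05, 0.45); ph <- runif(3, 0, 2 * pi); a <- runif(3, 0.3, 1)
    amplitude * colSums(a * sin(outer(f, t, function(fr, tt) 2 * pi * fr * tt) +
                                  ph))
  })
}

#' Synthesize muscle artifact
#'
#' Broadband EMG-like contamination: Gaussian noise band-passed to
#' 20-150 Hz (truncated below the Nyquist frequency).
#'
#' @inheritParams synth_bw_noise
#' @return Numeric vector.
#' @export
synth_ma_noise <- function(duration, sampling_rate = 360, amplitude = 1, seed = NULL) {
  n <- floor(duration * sampling_rate)
  .with_seed(seed, {
    if (amplitude == 0) return(numeric(n))
    hi <- min(150, 0.95 * sampling_rate / 2)
    bt <- signal::butter(4, c(20, hi) / (sampling_rate / 2), type = "pass")
    amplitude * signal::filtfilt(bt, rnorm(n))
  })
}

#' Synthesize power-line interference
#'
#' A mains-frequency sinusoid with random phase.
#'
#' @inheritParams synth_bw_noise
#' @param mains_hz Mains frequency (default 60 Hz).
#' @return Numeric vector.
#' @export
synth_pli_noise <- function(duration, sampling_rate = 360, amplitude = 1,
                            mains_hz = 60, seed = NULL) {
  n <- floor(duration * sampling_rate)
  .with_seed(seed, {
    ph <- runif(1, 0, 2 * pi)
    amplitude * sin(2 * pi * mains_hz * (seq_len(n) - 1L) / sampling_rate + ph)
  })
}

#' Generate a synthetic noisy/clean dataset
#'
#' Builds [segment_pairs()] entirely from synthetic signals: clean ECG
#' segments (preprocessed with [remove_dc()] and [normalize_segment()])
#' contaminated with electrode-motion noise at each requested nominal SNR
#' via [mix_at_snr()], balanced across levels. After mixing, each pair is
#' rescaled by the noisy segment's max-absolute value when it exceeds one,
#' which keeps both traces inside `[-1, 1]` without changing the realized
#' SNR (a common rescaling of clean and noisy leaves the ratio intact).
#'
#' Clean signals and each artifact class consume separate random streams
#' split deterministically from `seed`, so enabling one noise type never
#' perturbs another's draws.
#'
#' @param n_segments Total number of pairs (split as evenly as possible
#'   across `snr_levels`).
#' @param snr_levels Nominal input SNRs in dB.
#' @param seed Master integer seed.
#' @param segment_length Samples per segment.
#' @param sampling_rate Hz.
#' @return A [segment_pairs()] object of `n_segments` pairs.
#' @export
generate_dataset <- function(n_segments, snr_levels = c(-6, 0, 6, 12, 18, 24),
                             seed = 1L, segment_length = 1024L,
                             sampling_rate = 360) {
  if (n_segments < 1L) stop("n_segments must be at least 1")
  nl <- length(snr_levels)
  per <- rep(n_segments %/% nl, nl) + (seq_len(nl) <= n_segments %% nl)
  dur <- segment_length / sampling_rate
  seed <- as.integer(seed)
  clean_seed <- (seed * 11L + 1L) %% .Machine$integer.max
  em_seed <- (seed * 11L + 2L) %% .Machine$integer.max
  # synthesize a little beyond the segment so even the slowest jittered
  # heart rate fits at least one full beat
  dur_gen <- dur + 2
  cleans <- .with_seed(clean_seed, {
    m <- matrix(0, segment_length, n_segments)
    for (i in seq_len(n_segments)) {
      x <- synth_ecg(dur_gen, sampling_rate)[seq_len(segment_length)]
      m[, i] <- normalize_segment(remove_dc(x))
    }
    m
  })
  noises <- .with_seed(em_seed, {
    m <- matrix(0, segment_length, n_segments)
    for (i in seq_len(n_segments))
      m[, i] <- synth_em_noise(dur, sampling_rate)[seq_len(segment_length)]
    m
  })
  lv <- rep(snr_levels, per)
  noisy <- matrix(0, segment_length, n_segments)
  clean <- cleans
  for (i in seq_len(n_segments)) {
    y <- mix_at_snr(cleans[, i], noises[, i], lv[i])
    s <- max(1, max(abs(y)))
    noisy[, i] <- y / s
    clean[, i] <- cleans[, i] / s
  }
  segment_pairs(noisy, clean, lv,
                sprintf("synthetic:seed=%d:%d", seed, seq_len(n_segments)))
}
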