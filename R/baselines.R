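#' Classical denoiser specification
#'
#' Parameters of the three non-learned baseline denoisers: a band-pass FIR
#' filter (window method, Hanning window), a band-pass Butterworth IIR
#' filter applied forward-backward, and a db6 discrete-wavelet-transform
#' shrinkage that nullifies the highest, second-highest and lowest frequency
#' bands.
#'
#' @param method `"fir"`, `"iir"` or `"dwt"`.
#' @param sampling_rate Sampling rate in Hz.
#' @param highpass_cutoff High-pass corner in Hz (default 0.67).
#' @param lowpass_cutoff Low-pass corner in Hz (default 40).
#' @param fir_taps FIR length in taps (odd; default 101, a symmetric type-I
#'   band-pass).
#' @param iir_order Butterworth order per band edge (default 4).
#' @param wavelet Wavelet name; only `"db6"` is implemented.
#' @param levels Decomposition depth (default 9).
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(method = c("fir", "iir", "dwt"), sampling_rate = 360,
                        highpass_cutoff = 0.67, lowpass_cutoff = 40,
                        fir_taps = 101L, iir_order = 4L,
                        wavelet = "db6", levels = 9L) {
  method <- match.arg(method)
  if (!(highpass_cutoff > 0 && highpass_cutoff < lowpass_cutoff &&
        lowpass_cutoff < sampling_rate / 2))
    stop("need 0 < highpass (", highpass_cutoff, ") < lowpass (", lowpass_cutoff,
         ") < Nyquist (", sampling_rate / 2, ")")
  if (wavelet != "db6") stop("only the db6 wavelet is implemented")
  structure(list(method = method, sampling_rate = sampling_rate,
                 highpass_cutoff = highpass_cutoff, lowpass_cutoff = lowpass_cutoff,
                 fir_taps = as.integer(fir_taps), iir_order = as.integer(iir_order),
                 wavelet = wavelet, levels = as.integer(levels)),
            class = "filter_spec")
}

#' FIR band-pass denoiser
#'
#' Linear-phase band-pass filter designed by the window method with a
#' Hanning window (101 taps by default, pass band 0.67-40 Hz), applied with
#' group-delay compensation so the output is aligned with, and as long as,
#' the input.
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec()]; defaults to the standard FIR settings.
#' @return Filtered signal, same length as `x`.
#' @export
fir_denoise <- function(x, spec = filter_spec("fir")) {
  taps <- spec$fir_taps
  if (length(x) <= taps)
    stop("signal (", length(x), " samples) must be longer than the filter (",
         taps, " taps)")
  nyq <- spec$sampling_rate / 2
  h <- signal::fir1(taps - 1L, c(spec$highpass_cutoff, spec$lowpass_cutoff) / nyq,
                    type = "pass", window = signal::hanning(taps))
  gd <- (taps - 1L) %/% 2L
  y <- signal::filter(as.numeric(h), 1, c(x, numeric(gd)))
  as.numeric(y[(gd + 1L):(gd + length(x))])
}

#' Butterworth band-pass denoiser (zero phase)
#'
#' Fourth-order Butterworth band-pass (0.67-40 Hz by default) applied
#' forward-backward with `signal::filtfilt()`, giving zero phase distortion
#' of the QRS complex.
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
iir_denoise <- function(x, spec = filter_spec("iir")) {
  if (length(x) == 0L) stop("empty signal")
  nyq <- spec$sampling_rate / 2
  wc <- c(spec$highpass_cutoff, spec$lowpass_cutoff) / nyq
  zp <- signal::as.Zpg(signal::butter(spec$iir_order, wc, type = "pass"))
  p <- zp$pole
  if (any(Mod(p) >= 1 - 1e-12))
    stop("unstable Butterworth design at sampling rate ", spec$sampling_rate, " Hz")
  pos <- p[Im(p) > 1e-12]
  if (length(pos) * 2L != length(p)) {
    # poles not all in conjugate pairs: apply the direct form
    bt <- signal::butter(spec$iir_order, wc, type = "pass")
    return(as.numeric(signal::filtfilt(bt, x)))
  }
  # cascade of second-order sections: one conjugate pole pair per biquad,
  # numerator (z-1)(z+1) (band-pass zeros at DC and Nyquist), gain spread
  # evenly. Much better conditioned than the direct 2n-order polynomial
  # when the low band edge sits close to DC; applied zero-phase with
  # odd-reflection padding long enough for the slowest pole's transient.
  g <- Re(zp$gain)
  gs <- abs(g)^(1 / length(pos))
  sos <- t(vapply(seq_along(pos), function(i)
    c(c(1, 0, -1) * gs * (if (i == 1L) sign(g) else 1),
      -2 * Re(pos[i]), Mod(pos[i])^2), numeric(5)))
  padlen <- min(length(x) - 1L, ceiling(12 / (1 - max(Mod(p)))), 5000L)
  as.numeric(sos_filtfilt_cpp(sos, x, as.integer(padlen)))
}

# db6 analysis/synthesis filters
.db6 <- list(
  dec_lo = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
             -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
             -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
             0.7511339080210954, 0.49462389039845306, 0.11154074335010947),
  dec_hi = c(-0.11154074335010947, 0.49462389039845306, -0.7511339080210954,
             0.31525035170919763, 0.22626469396543983, -0.12976686756726194,
             -0.09750160558732304, 0.027522865530305727, 0.03158203931748603,
             0.0005538422011614961, -0.004777257510945511, -0.0010773010853084796),
  rec_lo = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
             0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
             0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
             0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  rec_hi = c(-0.0010773010853084796, -0.004777257510945511, 0.0005538422011614961,
             0.03158203931748603, 0.027522865530305727, -0.09750160558732304,
             -0.12976686756726194, 0.22626469396543983, 0.31525035170919763,
             -0.7511339080210954, 0.49462389039845306, -0.11154074335010947))

# one analysis step with symmetric (half-point) boundary extension
.dwt_step <- function(x, lo, hi) {
  fl <- length(lo); n <- length(x)
  e <- fl - 1L
  # half-point symmetric extension: fold positions into the period-2n pattern
  m <- seq.int(-e, n + e - 1L) %% (2L * n)
  ext <- x[ifelse(m < n, m + 1L, 2L * n - m)]
  outlen <- (n + fl - 1L) %/% 2L
  idx <- seq.int(fl + 1L, by = 2L, length.out = outlen)
  a <- convolve(ext, rev(lo), type = "open")[idx]
  d <- convolve(ext, rev(hi), type = "open")[idx]
  list(a = a, d = d)
}

# one synthesis step, cropping to the stored target length
.idwt_step <- function(a, d, lo, hi, target_len) {
  fl <- length(lo); la <- length(a)
  up_a <- numeric(2L * la); up_d <- numeric(2L * la)
  up_a[seq(1L, 2L * la, 2L)] <- a
  up_d[seq(1L, 2L * la, 2L)] <- d
  y <- convolve(up_a, rev(lo), type = "open") + convolve(up_d, rev(hi), type = "open")
  drop <- fl - 2L
  y[(drop + 1L):(drop + target_len)]
}

#' Multilevel db6 wavelet decomposition
#'
#' Repeatedly splits the approximation band with the db6 analysis filters
#' (symmetric boundary extension). Exact inverse: [idwt_multilevel()].
#'
#' @param x Numeric signal.
#' @param levels Decomposition depth.
#' @return A list with `approx` (deepest approximation), `details` (list,
#'   `details[[1]]` = finest/highest-frequency band), and the per-level
#'   input `lengths` needed for reconstruction.
#' @export
dwt_multilevel <- function(x, levels = 9L) {
  a <- as.numeric(x)
  details <- vector("list", levels)
  lens <- integer(levels)
  for (l in seq_len(levels)) {
    lens[l] <- length(a)
    st <- .dwt_step(a, .db6$dec_lo, .db6$dec_hi)
    a <- st$a
    details[[l]] <- st$d
  }
  list(approx = a, details = details, lengths = lens)
}

#' @rdname dwt_multilevel
#' @param decomposition A list as returned by `dwt_multilevel()`.
#' @export
idwt_multilevel <- function(decomposition) {
  a <- decomposition$approx
  levels <- length(decomposition$details)
  for (l in rev(seq_len(levels)))
    a <- .idwt_step(a, decomposition$details[[l]], .db6$rec_lo, .db6$rec_hi,
                    decomposition$lengths[l])
  a
}

#' Wavelet-shrinkage denoiser (db6, nine levels)
#'
#' Nine-level db6 decomposition in which the highest and second-highest
#' frequency detail bands and the lowest-frequency approximation band are
#' set to zero before reconstruction: high-frequency noise and baseline
#' drift are removed while the mid bands carrying the ECG morphology are
#' untouched.
#'
#' @param x Numeric signal (a length of at least `2^levels` is recommended;
#'   shorter signals are processed at a reduced depth with a warning).
#' @param spec A [filter_spec()].
#' @return Denoised signal, same length as `x`.
#' @export
dwt_denoise <- function(x, spec = filter_spec("dwt")) {
  levels <- spec$levels
  max_lev <- max(1L, floor(log2(max(length(x), 2L))))
  if (levels > max_lev) {
    warning("signal of length ", length(x), " supports only ", max_lev,
            " levels; reducing from ", levels)
    levels <- max_lev
  }
  dec <- dwt_multilevel(x, levels)
  dec$details[[1L]][] <- 0
  if (levels >= 2L) dec$details[[2L]][] <- 0
  dec$approx[] <- 0
  idwt_multilevel(dec)
}
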