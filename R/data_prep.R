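#' Cut a signal into consecutive non-overlapping segments
#'
#' @param signal Numeric vector.
#' @param segment_length Samples per segment (default 1024).
#' @return A `segment_length x n` matrix, one segment per column. Trailing
#'   samples that do not fill a whole segment are discarded. A signal shorter
#'   than one segment yields a zero-column matrix with a warning.
#' @export
segment_signal <- function(signal, segment_length = 1024L) {
  segment_length <- as.integer(segment_length)
  n <- length(signal) %/% segment_length
  if (n == 0L) {
    warning("signal (", length(signal), " samples) is shorter than one segment (",
            segment_length, "); returning no segments")
    return(matrix(numeric(0), segment_length, 0L))
  }
  matrix(signal[seq_len(n * segment_length)], segment_length, n)
}

#' Remove the DC offset of a segment
#'
#' @param segment Numeric vector.
#' @return The segment with its mean subtracted.
#' @export
remove_dc <- function(segment) {
  if (length(segment) == 0L) stop("empty segment")
  segment - mean(segment)
}

#' Scale a segment into `[-1, 1]`
#'
#' Symmetric max-absolute scaling: the segment is divided by its largest
#' absolute value, so the output lies in `[-1, 1]`, touches one of the
#' bounds, and keeps its shape (and, after [remove_dc()], its zero mean).
#'
#' @param segment Numeric vector, not all zeros.
#' @return The scaled segment.
#' @export
normalize_segment <- function(segment) {
  m <- max(abs(segment))
  if (m == 0) stop("cannot normalize an all-zero segment")
  segment / m
}

#' Mix noise into a clean signal at an exact SNR
#'
#' Scales the noise so that the realized input SNR,
#' `10*log10(sum(clean^2) / sum((a*noise)^2))`, equals `target_snr_db`
#' exactly, and returns `clean + a * noise`.
#'
#' @param clean Clean signal.
#' @param noise Noise signal, same length.
#' @param target_snr_db Desired input SNR in dB (e.g. -6, 0, 6, 12, 18, 24).
#' @return The noisy signal.
#' @export
mix_at_snr <- function(clean, noise, target_snr_db) {
  .check_pair(clean, noise)
  pc <- sum(clean^2); pn <- sum(noise^2)
  if (pn == 0) stop("noise is silent; cannot scale it to a target SNR")
  if (pc == 0) stop("clean signal is silent; SNR undefined")
  a <- sqrt(pc / (pn * 10^(target_snr_db / 10)))
  clean + a * noise
}

#' Bundle aligned noisy/clean segments
#'
#' Container for training/evaluation examples: aligned noisy and clean
#' segments with their nominal input-SNR labels and provenance tags.
#'
#' @param noisy,clean `segment_length x n` matrices (segments in columns).
#' @param snr_db Numeric vector of nominal input SNRs, length `n`.
#' @param source_id Character vector of provenance tags (recycled).
#' @return An object of class `"segment_pairs"`.
#' @export
segment_pairs <- function(noisy, clean, snr_db, source_id = "synthetic") {
  stopifnot(is.matrix(noisy), is.matrix(clean),
            all(dim(noisy) == dim(clean)), length(snr_db) == ncol(noisy))
  structure(list(noisy = noisy, clean = clean, snr_db = as.numeric(snr_db),
                 source_id = rep_len(as.character(source_id), ncol(noisy))),
            class = "segment_pairs")
}

#' @export
print.segment_pairs <- function(x, ...) {
  cat(sprintf("segment_pairs: %d pairs of length %d\n", ncol(x$noisy), nrow(x$noisy)))
  tb <- table(x$snr_db)
  cat("  nominal SNR (dB):", paste(sprintf("%s dB x%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.segment_pairs <- function(x) ncol(x$noisy)

#' @export
`[.segment_pairs` <- function(x, i) {
  segment_pairs(x$noisy[, i, drop = FALSE], x$clean[, i, drop = FALSE],
                x$snr_db[i], x$source_id[i])
}

#' Split pairs into training and test sets
#'
#' Random, seed-reproducible 80/20 (by default) split: `ceiling(f*n)`
#' training pairs, the rest test, disjoint and exhaustive.
#'
#' @param pairs A [segment_pairs()] object.
#' @param train_fraction Fraction assigned to the training set.
#' @param seed Integer seed controlling the split.
#' @return A list with elements `train` and `test`, both `segment_pairs`.
#' @export
split_dataset <- function(pairs, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(pairs, "segment_pairs"))
  n <- length(pairs)
  if (n < 5L) stop("need at least 5 pairs to split, got ", n)
  ntr <- ceiling(train_fraction * n)
  idx <- .with_seed(seed, sample.int(n, ntr))
  list(train = pairs[sort(idx)], test = pairs[setdiff(seq_len(n), idx)])
}

#' Write / read segment pairs as CSV
#'
#' Long-format columnar text: one row per sample with columns `segment`,
#' `sample`, `noisy`, `clean`, `nominal_snr_db`, `source_id`. Plain text and
#' diff-friendly; intended for small exports, not bulk storage.
#'
#' @param pairs A [segment_pairs()] object.
#' @param file Path to the CSV file.
#' @return `write_segment_pairs()` returns `file` invisibly;
#'   `read_segment_pairs()` returns a `segment_pairs` object.
#' @export
write_segment_pairs <- function(pairs, file) {
  stopifnot(inherits(pairs, "segment_pairs"))
  N <- nrow(pairs$noisy); n <- length(pairs)
  df <- data.frame(segment = rep(seq_len(n), each = N),
                   sample = rep(seq_len(N), n),
                   noisy = as.numeric(pairs$noisy),
                   clean = as.numeric(pairs$clean),
                   nominal_snr_db = rep(pairs$snr_db, each = N),
                   source_id = rep(pairs$source_id, each = N))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_segment_pairs
#' @export
read_segment_pairs <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  segs <- sort(unique(df$segment))
  N <- sum(df$segment == segs[1L])
  df <- df[order(df$segment, df$sample), ]
  segment_pairs(matrix(df$noisy, N), matrix(df$clean, N),
                df$nominal_snr_db[seq(1L, nrow(df), by = N)],
                df$source_id[seq(1L, nrow(df), by = N)])
}

#' Read a WFDB record (formats 212 and 16)
#'
#' Minimal reader for the PhysioNet waveform-database format: parses the
#' text header (`<record>.hea`) and decodes the binary signal file for the
#' two encodings used by the MIT-BIH databases (12-bit packed format 212 and
#' 16-bit little-endian format 16). Values are converted to physical units
#' via each channel's gain and baseline.
#'
#' @param record Record name (header is `<record>.hea`).
#' @param path Directory containing the record files.
#' @param channel Optional channel name (e.g. `"MLII"`, `"V1"`) to select a
#'   single channel; default returns all.
#' @return A list: `signal` (samples x channels matrix, physical units),
#'   `fs` (sampling rate, Hz), `channel_names`, `record`.
#' @export
read_wfdb <- function(record, path = ".", channel = NULL) {
  hea <- file.path(path, paste0(record, ".hea"))
  if (!file.exists(hea)) stop("header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(head_f[2L])
  fs <- if (length(head_f) >= 3L) as.numeric(sub("/.*", "", head_f[3L])) else 250
  nsamp <- if (length(head_f) >= 4L) as.integer(head_f[4L]) else NA_integer_
  spec <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    gain_f <- sub("\\(.*", "", f[3L])          # strip "(baseline)/units"
    baseline <- if (grepl("\\(", f[3L])) as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", f[3L]))
                else if (length(f) >= 5L) as.integer(f[5L]) else 0L
    gain <- as.numeric(sub("/.*", "", gain_f))
    if (!is.finite(gain) || gain == 0) gain <- 200
    list(file = f[1L], fmt = as.integer(sub("[x:+].*", "", f[2L])),
         gain = gain, baseline = baseline,
         name = if (length(f) >= 9L) f[length(f)] else paste0("ch", i))
  })
  fmts <- unique(vapply(spec, `[[`, 0L, "fmt"))
  datf <- unique(vapply(spec, `[[`, "", "file"))
  if (length(datf) != 1L) stop("multi-file records are not supported")
  if (length(fmts) != 1L || !fmts %in% c(212L, 16L))
    stop("unsupported WFDB signal format: ", paste(fmts, collapse = ", "),
         " (formats 212 and 16 are supported)")
  raw <- readBin(file.path(path, datf), "raw", file.info(file.path(path, datf))$size)
  if (fmts == 212L) {
    np <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(np)])
    b1 <- b[seq(1L, np, 3L)]; b2 <- b[seq(2L, np, 3L)]; b3 <- b[seq(3L, np, 3L)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8L)
    s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4L), 15L), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    adc <- as.numeric(rbind(s1, s2))          # interleaved sample stream
  } else {
    adc <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
  }
  ns <- length(adc) %/% nsig
  if (!is.na(nsamp) && is.finite(nsamp) && nsamp > 0L) ns <- min(ns, nsamp)
  sig <- matrix(adc[seq_len(ns * nsig)], ncol = nsig, byrow = TRUE)
  for (i in seq_len(nsig))
    sig[, i] <- (sig[, i] - spec[[i]]$baseline) / spec[[i]]$gain
  nm <- vapply(spec, `[[`, "", "name")
  colnames(sig) <- nm
  if (!is.null(channel)) {
    if (!channel %in% nm)
      stop("channel '", channel, "' not in record (has: ", paste(nm, collapse = ", "), ")")
    sig <- sig[, channel, drop = FALSE]
  }
  list(signal = sig, fs = fs, channel_names = colnames(sig), record = record)
}
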