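test_that("segmentation cuts non-overlapping windows and drops the remainder", {
  expect_identical(ncol(segment_signal(numeric(2048))), 2L)
  s <- segment_signal(as.numeric(seq_len(2047)))
  expect_identical(dim(s), c(1024L, 1L))
  expect_identical(s[, 1], as.numeric(1:1024))   # remainder discarded from the end
  expect_identical(ncol(segment_signal(numeric(1048576))), 1024L)
  expect_warning(out <- segment_signal(numeric(100)), "shorter than one segment")
  expect_identical(ncol(out), 0L)
  expect_identical(ncol(segment_signal(1:64, segment_length = 16)), 4L)
})

test_that("DC removal and max-abs normalization behave as documented", {
  expect_equal(remove_dc(rep(3.2, 50)), numeric(50))
  z <- rnorm(100); z <- z - mean(z)
  expect_equal(remove_dc(z), z)
  expect_lt(abs(mean(remove_dc(rnorm(1000, mean = 7)))), 1e-12)
  expect_equal(normalize_segment(c(-2, 2)), c(-1, 1))
  expect_equal(normalize_segment(remove_dc(c(0, 4))), c(-1, 1))
  set.seed(7)
  for (i in 1:20) {
    y <- normalize_segment(remove_dc(rnorm(256, sd = runif(1, 0.1, 10))))
    expect_equal(max(abs(y)), 1)
    expect_true(all(abs(y) <= 1))
  }
  expect_error(normalize_segment(numeric(10)), "all-zero")
})

test_that("mix_at_snr realizes the requested SNR exactly", {
  set.seed(8)
  clean <- sin(2 * pi * 3 * (0:1023) / 360)
  noise <- rnorm(1024)
  # 0 dB: scaled-noise energy equals clean energy
  y0 <- mix_at_snr(clean, noise, 0)
  expect_equal(sum((y0 - clean)^2), sum(clean^2), tolerance = 1e-12)
  # -6 dB: noise power 10^0.6 times clean power
  ym6 <- mix_at_snr(clean, noise, -6)
  expect_equal(sum((ym6 - clean)^2) / sum(clean^2), 10^0.6, tolerance = 1e-12)
  for (lv in c(-6, 0, 6, 12, 18, 24)) {
    y <- mix_at_snr(clean, noise, lv)
    expect_lt(abs(10 * log10(snr_in_ratio(clean, y)) - lv), 1e-9)
  }
  expect_error(mix_at_snr(clean, numeric(1024), 0), "silent")
})

test_that("train/test split is disjoint, exhaustive, sized and reproducible", {
  set.seed(9)
  mk <- function(n) segment_pairs(matrix(rnorm(16 * n), 16), matrix(rnorm(16 * n), 16),
                                  rep(0, n))
  sp <- split_dataset(mk(10), 0.8, seed = 1)
  expect_identical(length(sp$train), 8L)
  expect_identical(length(sp$test), 2L)
  # stated dataset size: 6888 segments -> 5511 / 1377 (ceiling/floor of 80:20)
  big <- mk(6888)
  spb <- split_dataset(big, 0.8, seed = 2)
  expect_identical(length(spb$train), as.integer(ceiling(0.8 * 6888)))
  expect_identical(length(spb$test), 6888L - as.integer(ceiling(0.8 * 6888)))
  sp2 <- split_dataset(big, 0.8, seed = 2)
  expect_identical(spb$train$source_id, sp2$train$source_id)
  expect_error(split_dataset(mk(4)), "at least 5")
})

test_that("segment pairs survive a CSV round trip", {
  set.seed(10)
  p <- segment_pairs(matrix(rnorm(32 * 3), 32), matrix(rnorm(32 * 3), 32),
                     c(-6, 0, 6), c("a", "b", "c"))
  f <- tempfile(fileext = ".csv")
  write_segment_pairs(p, f)
  q <- read_segment_pairs(f)
  expect_equal(q$noisy, p$noisy, tolerance = 1e-12)
  expect_equal(q$clean, p$clean, tolerance = 1e-12)
  expect_identical(q$snr_db, p$snr_db)
  expect_identical(q$source_id, p$source_id)
  unlink(f)
})

# encode a two-channel integer stream in WFDB format 212 (the MIT-BIH
# packing: two 12-bit samples in three bytes), independent of the reader
encode_212 <- function(s1, s2) {
  u1 <- ifelse(s1 < 0, s1 + 4096L, s1)
  u2 <- ifelse(s2 < 0, s2 + 4096L, s2)
  b1 <- bitwAnd(u1, 255L)
  b2 <- bitwOr(bitwShiftR(u1, 8L), bitwShiftL(bitwAnd(bitwShiftR(u2, 8L), 15L), 4L))
  b3 <- bitwAnd(u2, 255L)
  as.raw(as.integer(rbind(b1, b2, b3)))
}

test_that("the WFDB reader decodes synthetic format-212 and format-16 records", {
  dir <- tempfile(); dir.create(dir)
  set.seed(11)
  n <- 360
  adc1 <- as.integer(round(600 * sin(2 * pi * (1:n) / 90)))
  adc2 <- as.integer(round(300 * cos(2 * pi * (1:n) / 45)) - 100L)
  writeLines(c("rec212 2 360 360",
               "rec212.dat 212 200 11 1024 0 0 0 MLII",
               "rec212.dat 212 100(-50) 11 1024 0 0 0 V1"),
             file.path(dir, "rec212.hea"))
  writeBin(encode_212(adc1, adc2), file.path(dir, "rec212.dat"))
  r <- read_wfdb("rec212", dir)
  expect_identical(r$fs, 360)
  expect_identical(r$channel_names, c("MLII", "V1"))
  expect_equal(r$signal[, "MLII"], (adc1 - 1024) / 200, tolerance = 1e-12)
  expect_equal(r$signal[, "V1"], (adc2 - (-50)) / 100, tolerance = 1e-12)
  one <- read_wfdb("rec212", dir, channel = "V1")
  expect_identical(colnames(one$signal), "V1")
  expect_error(read_wfdb("rec212", dir, channel = "nope"), "not in record")

  writeLines(c("rec16 1 250 100", "rec16.dat 16 100 16 0 0 0 0 ECG"),
             file.path(dir, "rec16.hea"))
  adc <- as.integer(round(rnorm(100, sd = 500)))
  writeBin(adc, file.path(dir, "rec16.dat"), size = 2L, endian = "little")
  r16 <- read_wfdb("rec16", dir)
  expect_equal(as.numeric(r16$signal), adc / 100, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
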