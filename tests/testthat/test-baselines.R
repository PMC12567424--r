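fs <- 360
tt <- (0:(10 * fs - 1)) / fs
tone <- function(f) sin(2 * pi * f * tt)

test_that("FIR band-pass keeps the pass band and rejects the upper stop band", {
  spec <- filter_spec("fir")
  y_lo <- fir_denoise(tone(0.1), spec)
  y_mid <- fir_denoise(tone(10), spec)
  y_hi <- fir_denoise(tone(120), spec)
  # A 101-tap window-method design at 360 Hz has a transition width of
  # several hertz, so its 0.67 Hz high-pass edge can only nibble at a
  # 0.1 Hz tone (|H| ~ 0.86, confirmed against an external filter-design
  # oracle); it attenuates, but nothing like a resolved stop band.
  expect_lt(rms(y_lo), 0.9 * rms(tone(0.1)))
  expect_lt(abs(rms(y_mid) / rms(tone(10)) - 1), 0.1)
  expect_lt(rms(y_hi), 0.1 * rms(tone(120)))
  expect_identical(length(y_mid), length(tt))
  # group-delay compensation: pass-band output stays aligned with the input
  mid <- 500:3000
  expect_gt(cor(y_mid[mid], tone(10)[mid]), 0.99)
  expect_error(fir_denoise(rnorm(50), spec), "longer than the filter")
})

test_that("zero-phase Butterworth band-pass meets the same band contracts", {
  spec <- filter_spec("iir")
  expect_lt(rms(iir_denoise(tone(0.1), spec)), 0.1 * rms(tone(0.1)))
  y10 <- iir_denoise(tone(10), spec)
  expect_lt(abs(rms(y10) / rms(tone(10)) - 1), 0.1)
  expect_lt(rms(iir_denoise(tone(120), spec)), 0.1 * rms(tone(120)))
  expect_identical(length(y10), length(tt))
})

test_that("the multilevel db6 transform matches an external oracle and inverts", {
  # frozen PyWavelets (db6, symmetric mode) output: 3-level decomposition of
  # a two-tone signal with d1, d2 and the approximation nullified
  x <- c(0.5,0.525983,0.277785,0.275418,0.732538,1.312381,1.471178,1.027064,
         0.353553,-0.007073,0.097545,0.288488,0.079256,-0.585385,-1.247204,
         -1.397901,-1,-0.51598,-0.415735,-0.683402,-0.844623,-0.484522,
         0.292635,0.949867,1.06066,0.736779,0.490393,0.677988,1.115221,
         1.270603,0.833355,0.054586,-0.5,-0.525983,-0.277785,-0.275418,
         -0.732538,-1.312381,-1.471178,-1.027064,-0.353553,0.007073,
         -0.097545,-0.288488,-0.079256,0.585385,1.247204,1.397901,1,0.51598,
         0.415735,0.683402,0.844623,0.484522,-0.292635,-0.949867,-1.06066,
         -0.736779,-0.490393,-0.677988,-1.115221,-1.270603,-0.833355,-0.054586)
  y_ref <- c(-0.069802912413,-0.084519525389,-0.075521589536,-0.084886175708,
             -0.093797080854,-0.083747467794,-0.063163879617,-0.024359771899,
             0.03071194389,0.093271675603,0.155876133715,0.203939181426,
             0.223490401589,0.197626814811,0.134336500626,0.052195337962,
             -0.05371993733,-0.180741158101,-0.301526338875,-0.385584399075,
             -0.399556711188,-0.297237580321,-0.122493028264,0.047362317775,
             0.205765616176,0.316873091199,0.375693128122,0.411090040478,
             0.375301467197,0.222800887143,0.013594553395,-0.179365350372,
             -0.321287096429,-0.339853733281,-0.273208722189,-0.210078650584,
             -0.117945089909,0.007740931406,0.130998412905,0.241041560965,
             0.284529486619,0.187638013718,0.017078890333,-0.126168787793,
             -0.235284787506,-0.260978597695,-0.218692862895,-0.177217675624,
             -0.092468749269,0.067047524717,0.244305049364,0.389092051839,
             0.455465563958,0.364734743411,0.176496494862,-0.00039901723,
             -0.176099048458,-0.321002622863,-0.409298869499,-0.454233817211,
             -0.386272494028,-0.126721391535,0.206365704041,0.449392048755)
  dec <- dwt_multilevel(x, 3)
  dec$details[[1]][] <- 0
  dec$details[[2]][] <- 0
  dec$approx[] <- 0
  expect_equal(idwt_multilevel(dec), y_ref, tolerance = 1e-9)
  # perfect reconstruction without shrinkage
  set.seed(13)
  z <- rnorm(1024)
  expect_equal(idwt_multilevel(dwt_multilevel(z, 9)), z, tolerance = 1e-10)
})

test_that("wavelet shrinkage kills constants and drift but keeps the carrier", {
  spec <- filter_spec("dwt")
  cst <- dwt_denoise(rep(2.5, 1024), spec)
  expect_lt(sum(cst^2), 1e-6 * sum(rep(2.5, 1024)^2))
  t2 <- (0:1023) / fs
  carrier <- sin(2 * pi * 5 * t2)
  y_c <- dwt_denoise(carrier, spec)
  expect_gt(sum(y_c^2), 0.8 * sum(carrier^2))
  drift <- sin(2 * pi * 0.05 * t2)
  y_m <- dwt_denoise(carrier + drift, spec)
  expect_lt(windowed_low_energy(y_m, 0.5, fs),
            0.1 * windowed_low_energy(carrier + drift, 0.5, fs))
  expect_identical(length(y_c), 1024L)
  expect_warning(dwt_denoise(rnorm(256), spec), "supports only")
})

test_that("all three baselines are linear operators", {
  set.seed(14)
  x <- rnorm(2048); y <- rnorm(2048)
  a <- 1.7; b <- -0.4
  for (sp in list(filter_spec("fir"), filter_spec("iir"), filter_spec("dwt"))) {
    f <- switch(sp$method, fir = fir_denoise, iir = iir_denoise, dwt = dwt_denoise)
    expect_equal(f(a * x + b * y, sp), a * f(x, sp) + b * f(y, sp),
                 tolerance = 1e-8)
  }
})

test_that("baselines give positive SNR improvement on out-of-band noise", {
  clean <- normalize_segment(remove_dc(synth_ecg(4, heart_rate = 70, seed = 15)[1:1024]))
  for (nz in list(synth_bw_noise(4, seed = 16)[1:1024],
                  synth_pli_noise(4, seed = 17)[1:1024])) {
    noisy <- mix_at_snr(clean, nz, 6)
    for (sp in list(filter_spec("fir"), filter_spec("iir"), filter_spec("dwt"))) {
      f <- switch(sp$method, fir = fir_denoise, iir = iir_denoise, dwt = dwt_denoise)
      expect_gt(snr_improvement_db(clean, noisy, f(noisy, sp)), 0)
    }
  }
})

test_that("filter specifications validate their band edges", {
  expect_error(filter_spec("fir", highpass_cutoff = 50, lowpass_cutoff = 40), "highpass")
  expect_error(filter_spec("fir", lowpass_cutoff = 200), "Nyquist")
  expect_error(filter_spec("dwt", wavelet = "sym4"), "db6")
})
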