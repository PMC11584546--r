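test_that("parameter constructors enforce their invariants", {
  expect_error(glottal_source_params(f0 = -5), "f0")
  expect_error(glottal_source_params(jitter_pct = 25), "jitter")
  expect_error(glottal_source_params(shimmer_pct = 60), "shimmer")
  expect_error(glottal_source_params(open_quotient = 1.2), "open_quotient")
  expect_error(vocal_tract_params(formant_freqs = c(800, 700)), "increasing")
  expect_error(vocal_tract_params(formant_bandwidths = c(80, 90, 120)),
               "bandwidth")
  expect_error(vowel_spec(duration_s = 0), "duration")
  expect_error(vowel_spec(sample_rate_hz = 4000), "8000")
  expect_error(synthesize_vowel(vowel_spec(duration_s = 100), max_samples = 1e5),
               "max_samples")
})

test_that("zero-perturbation vowel is periodic at the requested f0", {
  fs <- 44100
  f0 <- fs / 420  # period an integer number of samples
  w <- synthesize_vowel(vowel_spec(glottal_source_params(f0 = f0),
                                   duration_s = 0.5, seed = 1))
  expect_equal(wave_duration(w), 0.5)
  expect_equal(max(abs(w$samples)), 1)
  x <- w$samples
  lags <- 380:460
  ac <- vapply(lags, function(L) {
    stats::cor(x[1:(length(x) - L)], x[(L + 1):length(x)])
  }, numeric(1))
  expect_equal(lags[which.max(ac)], 420)
  expect_gt(max(ac), 0.999)
})

test_that("shimmer produces per-cycle peak amplitude dispersion", {
  fs <- 44100
  f0 <- fs / 420
  cycle_peaks <- function(shimmer) {
    w <- synthesize_vowel(vowel_spec(
      glottal_source_params(f0 = f0, shimmer_pct = shimmer),
      duration_s = 0.5, seed = 42))
    x <- abs(w$samples)
    n_cycles <- floor(length(x) / 420)
    vapply(seq_len(n_cycles), function(i) max(x[((i - 1) * 420 + 1):(i * 420)]),
           numeric(1))
  }
  expect_lt(stats::sd(cycle_peaks(0)), 1e-6)
  expect_gt(stats::sd(cycle_peaks(10)), 0.01)
})

test_that("formant drift sweeps the F1 spectral ridge over the stated range", {
  fs <- 44100
  w <- synthesize_vowel(vowel_spec(
    glottal_source_params(f0 = 120),
    vocal_tract_params(drift_amplitude = 100, drift_rate = 2),
    duration_s = 1, seed = 3))
  # independent check: short-time FFT ridge in the F1 search band
  x <- w$samples
  seg <- 2048
  starts <- seq(1, length(x) - seg + 1, by = 1024)
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  freqs <- (0:(seg - 1)) * fs / seg
  band <- which(freqs >= 500 & freqs <= 1100)
  ridge <- vapply(starts, function(s) {
    spec <- Mod(fft(x[s:(s + seg - 1)] * taper))^2
    freqs[band][which.max(spec[band])]
  }, numeric(1))
  expect_lt(min(ridge), 780)
  expect_gt(max(ridge), 830)
  expect_gt(max(ridge) - min(ridge), 100)
})

test_that("synthesis is deterministic under a fixed seed", {
  sp <- vowel_spec(glottal_source_params(jitter_pct = 1, shimmer_pct = 5,
                                         noise_snr_db = 20),
                   duration_s = 0.3, seed = 11)
  expect_identical(synthesize_vowel(sp)$samples, synthesize_vowel(sp)$samples)
})
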