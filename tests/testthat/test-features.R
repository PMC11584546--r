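test_that("A1 matches the 2f/fs oracle on pure tones", {
  fs <- 44100
  for (f in c(80, 200, 500, 1000)) {
    tone <- make_tone(f, fs)
    oracle <- count_sign_changes(tone$samples) / length(tone$samples)
    a1 <- compute_a1(tone)
    expect_lt(abs(a1 - 2 * f / fs) / (2 * f / fs), 0.02)
    expect_equal(a1, oracle, tolerance = 0.01)
  }
})

test_that("A1 degenerate cases", {
  fs <- 8000
  # constant signal: no crossings
  expect_equal(compute_a1(waveform(rep(0.5, 800), fs)), 0)
  # alternating +1/-1: one crossing per sample interval
  expect_gt(compute_a1(waveform(rep(c(1, -1), 400), fs)), 0.98)
  expect_error(compute_a1(waveform(rep(1, 10), fs)), "shorter than one frame")
})

test_that("A2 measures per-frame extremum dispersion", {
  fs <- 1000
  cfg <- frame_config(0.02, 0.02)  # 20-sample frames, no overlap
  frame_with_peak <- function(a) c(0, a, 0, -a, rep(0, 16))
  # constant extrema -> A2 = 0
  const <- waveform(rep(frame_with_peak(1), 10), fs)
  expect_equal(compute_a2(const, cfg), 0)
  # amplitudes alternating 1.0 / 0.8 per frame:
  # D_P = 0.1, mean(P) = 0.9 -> each term 100*0.1/0.9
  alt <- waveform(rep(c(frame_with_peak(1), frame_with_peak(0.8)), 5), fs)
  expect_equal(compute_a2(alt, cfg), 100 * 0.1 / 0.9, tolerance = 1e-9)
  # raw variant skips normalization
  expect_equal(compute_a2(alt, cfg, relative = FALSE), 0.1, tolerance = 1e-9)
})

test_that("A2 handles frames without extrema", {
  fs <- 1000
  cfg <- frame_config(0.02, 0.02)
  x <- c(rep(c(0, 1, 0, -1, rep(0, 16)), 3), rep(0, 20),
         rep(c(0, 1, 0, -1, rep(0, 16)), 3))
  expect_warning(a2 <- compute_a2(waveform(x, fs), cfg), "skipped")
  expect_equal(a2, 0)
  expect_error(suppressWarnings(compute_a2(waveform(seq(0, 1, length.out = 60),
                                                    fs), cfg)),
               "insufficient|extrema|usable")
})

test_that("A3 is at the noise floor without drift and tracks drift magnitude", {
  w0 <- synthesize_vowel(vowel_spec(duration_s = 1, seed = 21))
  expect_lt(compute_a3(w0), 5)
  # sinusoidal drift of amplitude d -> mean absolute deviation 2d/pi
  wd <- synthesize_vowel(vowel_spec(
    tract = vocal_tract_params(drift_amplitude = 100, drift_rate = 3),
    duration_s = 1, seed = 22))
  expect_equal(compute_a3(wd), 2 * 100 / pi, tolerance = 0.12)
  # approximate linearity in drift amplitude
  wh <- synthesize_vowel(vowel_spec(
    tract = vocal_tract_params(drift_amplitude = 50, drift_rate = 3),
    duration_s = 1, seed = 22))
  expect_equal(compute_a3(wd) / compute_a3(wh), 2, tolerance = 0.2)
})

test_that("A4 band-energy ratio matches analytic expectations", {
  fs <- 44100
  expect_gt(compute_a4(make_tone(200, fs)), 0.99)
  expect_lt(compute_a4(make_tone(5000, fs)), 0.01)
  set.seed(31)
  noise <- waveform(rnorm(fs), fs)
  expect_equal(compute_a4(noise), 800 / 22050, tolerance = 0.15)
  # monotone in the band edge; equals 1 at Nyquist
  w <- synthesize_vowel(vowel_spec(duration_s = 0.5, seed = 5))
  edges <- c(400, 800, 1600, 3200, 22050)
  vals <- vapply(edges, function(e) compute_a4(w, e), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[length(vals)], 1)
  expect_error(compute_a4(waveform(rep(0, 1000) + 0, fs)), "zero total")
})

test_that("all four features are scale invariant and deterministic", {
  w <- synthesize_vowel(vowel_spec(
    glottal_source_params(jitter_pct = 0.5, shimmer_pct = 3,
                          noise_snr_db = 25),
    vocal_tract_params(drift_amplitude = 20), duration_s = 0.8, seed = 13))
  scaled <- waveform(w$samples * 3.7, w$sample_rate_hz)
  f1 <- compute_features(w)
  f2 <- compute_features(scaled)
  expect_equal(f1, f2, tolerance = 1e-8)
  expect_identical(compute_features(w), f1)
  expect_true(f1$A1 >= 0 && f1$A1 <= 1)
  expect_true(f1$A2 >= 0)
  expect_true(f1$A3 >= 0)
  expect_true(f1$A4 >= 0 && f1$A4 <= 1)
})
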