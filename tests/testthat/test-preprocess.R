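test_that("endpoint detection recovers constructed speech boundaries", {
  fs <- 44100
  vow <- synthesize_vowel(vowel_spec(duration_s = 1.0, seed = 7))
  sig <- waveform(c(numeric(round(0.2 * fs)), 0.7 * vow$samples,
                    numeric(round(0.2 * fs))), fs)
  trimmed <- detect_endpoints(sig)
  expect_lt(abs(wave_duration(trimmed) - 1.0), 2 * 0.010 + 1e-9)

  # with a realistic (nonzero) noise floor
  set.seed(5)
  noisy <- waveform(c(rnorm(round(0.2 * fs), 0, 0.004),
                      0.7 * vow$samples + rnorm(length(vow$samples), 0, 0.004),
                      rnorm(round(0.2 * fs), 0, 0.004)), fs)
  expect_lt(abs(wave_duration(detect_endpoints(noisy)) - 1.0), 2 * 0.010 + 1e-9)
})

test_that("endpoint detection handles degenerate inputs", {
  fs <- 44100
  expect_error(detect_endpoints(waveform(numeric(8820) + 0, fs)),
               "no speech detected")
  vow <- synthesize_vowel(vowel_spec(duration_s = 0.8, seed = 2))
  # fully voiced input passes through unchanged; trimming is idempotent
  expect_identical(detect_endpoints(vow)$samples, vow$samples)
  once <- detect_endpoints(waveform(c(numeric(4410), vow$samples,
                                      numeric(4410)), fs))
  twice <- detect_endpoints(once)
  expect_lt(abs(length(twice$samples) - length(once$samples)), 441 + 1)
})

test_that("duration gate bounds are inclusive at 0.8 and 1.2 seconds", {
  fs <- 44100
  mk <- function(d) waveform(sin(2 * pi * 120 * seq_len(round(d * fs)) / fs), fs)
  expect_false(validate_duration(mk(0.79)))
  expect_true(validate_duration(mk(0.80)))
  expect_true(validate_duration(mk(1.00)))
  expect_true(validate_duration(mk(1.20)))
  expect_false(validate_duration(mk(1.21)))
})

test_that("repeat-variability QC applies the CV rule per parameter", {
  m <- rbind(c(10, 10, 10), c(10, 10, 16), c(10, 11, 10.5))
  reps <- data.frame(A1 = c(10, 10, 10), A2 = c(10, 10, 16),
                     A3 = c(10, 11, 10.5), A4 = c(0.5, 0.5, 0.5))
  qc <- select_repeats(reps)
  # population-SD CV: (10,10,16) -> 100*sqrt(8)/12; (10,11,10.5) -> ~3.89%
  expect_equal(unname(qc$per_parameter_cv_pct["A1"]), 0)
  expect_equal(unname(qc$per_parameter_cv_pct["A2"]), 100 * sqrt(8) / 12)
  expect_equal(unname(qc$per_parameter_cv_pct["A3"]),
               100 * sqrt(mean((c(10, 11, 10.5) - 10.5)^2)) / 10.5)
  expect_equal(unname(qc$variability_pass), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(unname(qc$accepted_values), c(10, NA, 10.5, 0.5))
})

test_that("repeat QC is permutation invariant and rejects bad input", {
  reps <- data.frame(A1 = c(9, 10, 11), A2 = c(3, 4, 5))
  qc1 <- select_repeats(reps)
  qc2 <- select_repeats(reps[c(3, 1, 2), ])
  expect_equal(qc1$per_parameter_cv_pct, qc2$per_parameter_cv_pct)
  expect_equal(qc1$accepted_values, qc2$accepted_values)

  expect_error(select_repeats(reps[1:2, ]), "exactly 3")
  expect_error(select_repeats(data.frame(A1 = c(1, NA, 2))), "finite")
  expect_warning(qc0 <- select_repeats(data.frame(A1 = c(-1, 0, 1))),
                 "zero repeat mean")
  expect_true(is.na(qc0$accepted_values["A1"]))
})
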