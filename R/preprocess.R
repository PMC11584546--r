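#' Endpoint-detection configuration
#'
#' Settings for the energy + zero-crossing double-threshold endpoint
#' detector that trims leading and trailing non-speech.
#'
#' @param frame_length_s analysis frame length in seconds.
#' @param hop_length_s hop between frames in seconds.
#' @param noise_floor_s initial stretch used to estimate the noise floor.
#' @param upper_k,lower_k noise-floor multipliers (mean + k*SD) for the
#'   upper and lower energy thresholds.
#' @param upper_cap,lower_cap caps on the thresholds as fractions of the
#'   maximum frame energy, so fully voiced inputs pass through unchanged.
#' @param zcr_extend_s maximum boundary extension by the zero-crossing
#'   criterion, seconds.
#' @return an object of class `endpoint_config`.
#' @export
endpoint_config <- function(frame_length_s = 0.020, hop_length_s = 0.010,
                            noise_floor_s = 0.100, upper_k = 5, lower_k = 2,
                            upper_cap = 0.10, lower_cap = 0.03,
                            zcr_extend_s = 0.25) {
  if (hop_length_s <= 0 || hop_length_s > frame_length_s)
    stop("endpoint_config: need 0 < hop_length_s <= frame_length_s")
  structure(list(frame_length_s = frame_length_s, hop_length_s = hop_length_s,
                 noise_floor_s = noise_floor_s, upper_k = upper_k,
                 lower_k = lower_k, upper_cap = upper_cap,
                 lower_cap = lower_cap, zcr_extend_s = zcr_extend_s),
            class = "endpoint_config")
}

#' Trim leading and trailing non-speech from a recording
#'
#' Rabiner-style double-threshold endpoint detection. Short-time energy is
#' computed on 20 ms frames (10 ms hop); a noise floor (mean and SD of the
#' frame energies) is estimated from the first 100 ms. The voiced region is
#' located where energy exceeds the upper threshold, then grown outward
#' while energy stays above the lower threshold, and finally extended by up
#' to 250 ms where the frame zero-crossing rate exceeds the noise ZCR
#' threshold (catching low-energy voiced onsets/offsets). Both thresholds
#' are capped relative to the maximum frame energy so an input that is
#' already fully voiced is returned unchanged. The signal is mean-removed
#' before analysis.
#'
#' @param w a [waveform()].
#' @param cfg an [endpoint_config()].
#' @return the contiguous voiced sub-span as a [waveform()] (identifiers
#'   preserved).
#' @export
detect_endpoints <- function(w, cfg = endpoint_config()) {
  check_wave_input(w, "detect_endpoints")
  x <- w$samples - mean(w$samples)
  fs <- w$sample_rate_hz
  flen <- round(cfg$frame_length_s * fs)
  hop <- max(1L, round(cfg$hop_length_s * fs))
  starts <- frame_starts(length(x), flen, hop)
  if (length(starts) == 0L) stop("detect_endpoints: no speech detected")
  crossing <- zero_crossing_intervals(x)
  energy <- vapply(starts, function(s) mean(x[s:(s + flen - 1L)]^2), numeric(1))
  zcr <- vapply(starts, function(s) sum(crossing[s:(s + flen - 2L)]) / flen,
                numeric(1))
  e_max <- max(energy)
  if (e_max <= 0) stop("detect_endpoints: no speech detected")

  sd0 <- function(v) if (length(v) >= 2L) stats::sd(v) else 0
  noise_frames <- which((starts - 1L) / fs < cfg$noise_floor_s)
  e_noise <- energy[noise_frames]
  z_noise <- zcr[noise_frames]
  itu <- min(mean(e_noise) + cfg$upper_k * sd0(e_noise), cfg$upper_cap * e_max)
  itl <- min(mean(e_noise) + cfg$lower_k * sd0(e_noise), cfg$lower_cap * e_max)
  izct <- max(mean(z_noise) + 2 * sd0(z_noise), 0.02)

  above <- which(energy > itu)
  if (length(above) == 0L) stop("detect_endpoints: no speech detected")
  i1 <- min(above); i2 <- max(above)
  while (i1 > 1L && energy[i1 - 1L] > itl) i1 <- i1 - 1L
  while (i2 < length(energy) && energy[i2 + 1L] > itl) i2 <- i2 + 1L
  max_ext <- round(cfg$zcr_extend_s / cfg$hop_length_s)
  ext <- 0L
  while (i1 > 1L && ext < max_ext && zcr[i1 - 1L] > izct) {
    i1 <- i1 - 1L; ext <- ext + 1L
  }
  ext <- 0L
  while (i2 < length(energy) && ext < max_ext && zcr[i2 + 1L] > izct) {
    i2 <- i2 + 1L; ext <- ext + 1L
  }
  waveform(w$samples[starts[i1]:(starts[i2] + flen - 1L)], fs,
           subject_id = w$subject_id, repeat_index = w$repeat_index)
}

#' Duration gate for a trimmed recording
#'
#' A recording passes if its trimmed duration lies within the protocol
#' bounds, 0.8 to 1.2 seconds inclusive (the protocol withdraws recordings
#' strictly shorter than 0.8 s or strictly longer than 1.2 s).
#'
#' @param w a trimmed [waveform()].
#' @param min_s,max_s inclusive duration bounds in seconds.
#' @return `TRUE` if the duration is within bounds.
#' @export
validate_duration <- function(w, min_s = 0.8, max_s = 1.2) {
  check_wave_input(w, "validate_duration")
  if (min_s <= 0 || min_s >= max_s)
    stop("validate_duration: need 0 < min_s < max_s")
  d <- wave_duration(w)
  d >= min_s && d <= max_s
}

#' Repeat-variability quality control
#'
#' The protocol records each subject three times and accepts a parameter
#' only if its variability across the repeats is below 15%. Variability is
#' measured per parameter as the coefficient of variation,
#' `CV% = 100 * SD / mean` (population SD, i.e. divisor n); the accepted
#' value of a passing parameter is the mean of the three repeats. A
#' parameter whose repeat mean is zero has an undefined CV and is marked
#' missing with a warning.
#'
#' @param features_by_repeat a `data.frame` or matrix with exactly 3 rows
#'   (repeats) and one column per parameter (e.g. `A1`..`A4`), all finite.
#' @param threshold_pct acceptance threshold on the CV, percent (strict
#'   `<`); default 15.
#' @return an object of class `qc_report`: a list with
#'   `per_parameter_cv_pct`, `variability_pass`, and `accepted_values`
#'   (named vectors; rejected parameters are `NA` in `accepted_values`).
#' @export
select_repeats <- function(features_by_repeat, threshold_pct = 15) {
  m <- as.matrix(features_by_repeat)
  if (nrow(m) != 3L)
    stop("select_repeats: exactly 3 repeats are required (got ", nrow(m), ")")
  if (!all(is.finite(m)))
    stop("select_repeats: all repeat values must be finite")
  if (threshold_pct <= 0) stop("select_repeats: threshold_pct must be > 0")
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  cv <- 100 * sd_pop / mu
  cv[mu == 0] <- NA_real_
  if (any(mu == 0))
    warning("select_repeats: parameter(s) with zero repeat mean have ",
            "undefined CV and are marked missing: ",
            paste(colnames(m)[mu == 0], collapse = ", "))
  pass <- !is.na(cv) & cv < threshold_pct
  accepted <- ifelse(pass, mu, NA_real_)
  names(cv) <- names(pass) <- names(accepted) <- colnames(m)
  structure(list(per_parameter_cv_pct = cv, variability_pass = pass,
                 accepted_values = accepted, threshold_pct = threshold_pct),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> CV threshold %g%%\n", x$threshold_pct))
  print(data.frame(cv_pct = round(x$per_parameter_cv_pct, 2),
                   pass = x$variability_pass,
                   accepted = x$accepted_values))
  invisible(x)
}
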