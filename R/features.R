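#' Short-time analysis frame configuration
#'
#' @param frame_length_s frame length in seconds (> 0).
#' @param hop_length_s hop between frame starts in seconds; `0 < hop <= frame`.
#' @param window taper used for spectral operations: "hamming", "hann" or
#'   "rectangular".
#' @return an object of class `frame_config`.
#' @export
frame_config <- function(frame_length_s = 0.020, hop_length_s = 0.010,
                         window = c("hamming", "hann", "rectangular")) {
  window <- match.arg(window)
  if (!is.numeric(frame_length_s) || frame_length_s <= 0)
    stop("frame_config: frame_length_s must be > 0")
  if (!is.numeric(hop_length_s) || hop_length_s <= 0 ||
      hop_length_s > frame_length_s)
    stop("frame_config: need 0 < hop_length_s <= frame_length_s")
  structure(list(frame_length_s = frame_length_s, hop_length_s = hop_length_s,
                 window = window), class = "frame_config")
}

# start indices of full frames covering a signal of n samples
frame_starts <- function(n, flen, hop) {
  if (n < flen) return(integer(0))
  seq.int(1L, n - flen + 1L, by = hop)
}

window_taper <- function(name, n) {
  switch(name,
         hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         rectangular = rep(1, n))
}

# mean absolute deviation from the mean ("average deviation")
mean_abs_dev <- function(x) mean(abs(x - mean(x)))

# logical vector over the n-1 sample intervals: TRUE where the signal crosses
# zero (sign change between the nearest nonzero samples, so samples exactly
# at zero do not hide a positive-to-negative transit)
zero_crossing_intervals <- function(x) {
  n <- length(x)
  crossing <- logical(n - 1L)
  nz <- which(x != 0)
  if (length(nz) < 2L) return(crossing)
  s <- sign(x[nz])
  changed <- s[-1L] != s[-length(s)]
  crossing[nz[-1L][changed] - 1L] <- TRUE
  crossing
}

check_wave_input <- function(w, fn) {
  if (!inherits(w, "waveform")) stop(fn, ": input must be a waveform")
  w
}

#' A1: average zero-crossing rate
#'
#' Counts strict sign changes between consecutive samples within each frame,
#' divides by the frame length in samples, and averages over frames. The
#' signal is mean-removed first so a DC offset cannot suppress crossings.
#' For a pure tone of frequency f the expected value is 2f/fs.
#'
#' @param w a trimmed [waveform()].
#' @param cfg a [frame_config()]; 20 ms frames with 10 ms hop by default.
#' @return A1, crossings per sample, in `[0, 1]`.
#' @export
compute_a1 <- function(w, cfg = frame_config()) {
  check_wave_input(w, "compute_a1")
  x <- w$samples - mean(w$samples)
  flen <- round(cfg$frame_length_s * w$sample_rate_hz)
  hop <- max(1L, round(cfg$hop_length_s * w$sample_rate_hz))
  starts <- frame_starts(length(x), flen, hop)
  if (length(starts) == 0L)
    stop("compute_a1: signal shorter than one frame")
  crossing <- zero_crossing_intervals(x)
  nint <- length(crossing)
  # each frame counts the flen intervals beginning at its samples (the last
  # interval reaches one sample past the frame; the final frame simply has
  # one interval fewer), so a tone with an integer number of cycles per
  # frame is counted exactly
  rate <- vapply(starts, function(s) {
    sum(crossing[s:min(s + flen - 1L, nint)]) / flen
  }, numeric(1))
  mean(rate)
}

#' A2: variation of local peaks and valleys
#'
#' Per frame, takes the largest local-maximum amplitude P and the smallest
#' local-minimum amplitude V (interior extrema only). Across frames it
#' computes the average absolute deviation of each series from its mean and
#' reports, in percent,
#' `A2 = 100 * (mad(P)/|mean(P)| + mad(V)/|mean(V)|) / 2`
#' (shimmer-like amplitude instability). `relative = FALSE` skips the
#' normalization by the mean extremum amplitude and returns
#' `(mad(P) + mad(V)) / 2` in raw amplitude units.
#'
#' @inheritParams compute_a1
#' @param relative normalize the deviations by the mean extremum amplitude
#'   and express the result in percent (default), or report raw amplitude
#'   deviations.
#' @return A2 (>= 0); percent when `relative = TRUE`.
#' @export
compute_a2 <- function(w, cfg = frame_config(), relative = TRUE) {
  check_wave_input(w, "compute_a2")
  x <- w$samples - mean(w$samples)
  flen <- round(cfg$frame_length_s * w$sample_rate_hz)
  hop <- max(1L, round(cfg$hop_length_s * w$sample_rate_hz))
  starts <- frame_starts(length(x), flen, hop)
  if (length(starts) < 2L)
    stop("compute_a2: need at least two full frames")
  n <- length(x)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n], FALSE)
  is_min <- c(FALSE, x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n], FALSE)
  peaks <- valleys <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + flen - 1L)
    pk <- x[idx][is_max[idx]]
    vl <- x[idx][is_min[idx]]
    if (length(pk) && length(vl)) {
      peaks[i] <- max(pk)
      valleys[i] <- min(vl)
    }
  }
  keep <- !is.na(peaks)
  if (sum(keep) < length(starts))
    warning("compute_a2: ", length(starts) - sum(keep),
            " frame(s) without interior extrema skipped")
  if (sum(keep) < 2L)
    stop("compute_a2: fewer than two frames with usable extrema")
  p <- peaks[keep]; v <- valleys[keep]
  if (relative) {
    if (mean(p) == 0 || mean(v) == 0)
      stop("compute_a2: mean extremum amplitude is zero; relative A2 undefined")
    100 * (mean_abs_dev(p) / abs(mean(p)) + mean_abs_dev(v) / abs(mean(v))) / 2
  } else {
    (mean_abs_dev(p) + mean_abs_dev(v)) / 2
  }
}

# Linear-prediction formant candidates for one frame. Returns a numeric
# vector of candidate frequencies (Hz), ascending, after bandwidth and
# minimum-frequency screening.
lp_formant_candidates <- function(frame, fs, order, min_freq, max_bandwidth) {
  n <- length(frame)
  r <- vapply(0:order, function(k) sum(frame[1:(n - k)] * frame[(k + 1):n]),
              numeric(1))
  if (r[1] <= 0) return(numeric(0))
  a <- tryCatch(solve(stats::toeplitz(r[1:order]), r[2:(order + 1)]),
                error = function(e) NULL)
  if (is.null(a)) return(numeric(0))
  rt <- polyroot(c(-rev(a), 1))       # roots of z^p - a1 z^(p-1) - ... - ap
  ang <- Arg(rt)
  keep <- ang > 0 & ang < pi
  freq <- ang[keep] * fs / (2 * pi)
  bw <- -log(pmin(Mod(rt[keep]), 1 - 1e-12)) * fs / pi
  ok <- freq > min_freq & freq < fs / 2 - min_freq & bw < max_bandwidth
  sort(freq[ok])
}

#' A3: variation of the first and second formant frequencies
#'
#' Per frame, F1 and F2 are estimated by autocorrelation linear prediction:
#' the signal is downsampled to about 11 kHz (anti-aliased), pre-emphasized
#' (two first-order passes, compensating the roughly -12 dB/oct tilt of the
#' voiced source), windowed (Hamming, 25 ms frames / 10 ms hop by default),
#' and the LP
#' polynomial roots are converted to candidate resonances, screened by
#' bandwidth (< 400 Hz) and minimum frequency (> 250 Hz, the lower edge of
#' plausible F1 values, which rejects spurious low poles left by the glottal
#' source spectrum); the lowest two
#' surviving candidates are taken as F1 < F2. A3 is the mean of the average
#' absolute deviations of the frame-wise F1 and F2 series from their means:
#' `A3 = (mad(F1) + mad(F2)) / 2`, in Hz.
#'
#' @param w a trimmed, voiced [waveform()].
#' @param cfg a [frame_config()] for the LP analysis.
#' @param lp_order linear-prediction order at the downsampled rate.
#' @param target_fs_hz analysis rate the signal is decimated to.
#' @param preemphasis first-order pre-emphasis coefficient.
#' @param min_freq_hz candidates at or below this frequency are discarded.
#' @param max_bandwidth_hz candidates broader than this are discarded.
#' @param outlier_window_hz frames whose F1 or F2 estimate lies further than
#'   this from the track median are treated as tracking failures and
#'   skipped.
#' @return A3 in Hz (>= 0).
#' @export
compute_a3 <- function(w, cfg = frame_config(0.025, 0.010, "hamming"),
                       lp_order = 12, target_fs_hz = 11025,
                       preemphasis = 0.97, min_freq_hz = 250,
                       max_bandwidth_hz = 400, outlier_window_hz = 400) {
  check_wave_input(w, "compute_a3")
  x <- w$samples - mean(w$samples)
  fs <- w$sample_rate_hz
  q <- max(1L, floor(fs / target_fs_hz))
  if (q > 1L) {
    x <- signal::decimate(x, q)
    fs <- fs / q
  }
  # two pre-emphasis passes (~ +12 dB/oct) flatten the full voiced-source
  # tilt; a single pass leaves enough residual tilt to bias the LP poles
  # toward the strongest harmonic near each formant
  for (pass in 1:2)
    x <- c(x[1] * (1 - preemphasis), x[-1L] - preemphasis * x[-length(x)])
  flen <- round(cfg$frame_length_s * fs)
  hop <- max(1L, round(cfg$hop_length_s * fs))
  starts <- frame_starts(length(x), flen, hop)
  taper <- window_taper(cfg$window, flen)
  f1 <- f2 <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    frame <- x[starts[i]:(starts[i] + flen - 1L)] * taper
    cand <- lp_formant_candidates(frame, fs, lp_order, min_freq_hz,
                                  max_bandwidth_hz)
    if (length(cand) >= 2L) {
      f1[i] <- cand[1L]
      f2[i] <- cand[2L]
    }
  }
  ok <- !is.na(f1)
  # plausibility screen: a frame whose estimate sits hundreds of Hz from the
  # track median is a tracking failure (e.g. a boundary frame locking onto
  # F3), not vocal variation; genuine formant drift stays well inside 400 Hz
  if (sum(ok) >= 2L) {
    ok <- ok & abs(f1 - stats::median(f1[ok])) <= outlier_window_hz &
      abs(f2 - stats::median(f2[ok])) <= outlier_window_hz
    ok[is.na(ok)] <- FALSE
  }
  if (sum(ok) < length(starts))
    warning("compute_a3: ", length(starts) - sum(ok),
            " frame(s) skipped (too few candidates or implausible estimate)")
  if (sum(ok) < 2L)
    stop("compute_a3: fewer than two frames with valid formant estimates")
  (mean_abs_dev(f1[ok]) + mean_abs_dev(f2[ok])) / 2
}

#' A4: low-frequency spectral energy ratio
#'
#' Ratio of the spectral power at or below `end_frequency_hz` to the total
#' spectral power up to Nyquist, computed from an averaged (Welch)
#' periodogram of the whole trimmed utterance: Hann-windowed segments of
#' `segment_length` samples with 50% overlap. Signals shorter than one
#' segment use a single full-length periodogram.
#'
#' @param w a trimmed [waveform()].
#' @param end_frequency_hz band edge in Hz; the bin at exactly this frequency
#'   counts toward the numerator. Default 800 Hz.
#' @param segment_length Welch segment length in samples.
#' @return A4, dimensionless, in `[0, 1]`.
#' @export
compute_a4 <- function(w, end_frequency_hz = 800, segment_length = 4096) {
  check_wave_input(w, "compute_a4")
  if (end_frequency_hz <= 0 || end_frequency_hz > w$sample_rate_hz / 2)
    stop("compute_a4: end_frequency_hz must be in (0, Nyquist]")
  x <- w$samples - mean(w$samples)
  n <- length(x)
  seg <- min(segment_length, n)
  hop <- max(1L, seg %/% 2L)
  starts <- frame_starts(n, seg, hop)
  taper <- window_taper("hann", seg)
  nyq_bin <- seg %/% 2L + 1L
  pxx <- numeric(nyq_bin)
  for (s in starts) {
    spec <- Mod(fft(x[s:(s + seg - 1L)] * taper))^2
    pxx <- pxx + spec[1:nyq_bin]
  }
  total <- sum(pxx)
  if (total <= 0) stop("compute_a4: zero total spectral energy; ratio undefined")
  freqs <- (0:(nyq_bin - 1L)) * w$sample_rate_hz / seg
  sum(pxx[freqs <= end_frequency_hz]) / total
}

#' Extract the full A1-A4 feature vector from one recording
#'
#' @param w a trimmed [waveform()].
#' @param cfg_time [frame_config()] for A1/A2 (time-domain framing).
#' @param cfg_lp [frame_config()] for the A3 linear-prediction analysis.
#' @param end_frequency_hz band edge for A4 in Hz.
#' @param a2_relative passed to [compute_a2()].
#' @return one-row `data.frame` with columns `A1`, `A2`, `A3`, `A4`.
#' @export
compute_features <- function(w, cfg_time = frame_config(),
                             cfg_lp = frame_config(0.025, 0.010, "hamming"),
                             end_frequency_hz = 800, a2_relative = TRUE) {
  data.frame(
    A1 = compute_a1(w, cfg_time),
    A2 = compute_a2(w, cfg_time, relative = a2_relative),
    A3 = compute_a3(w, cfg_lp),
    A4 = compute_a4(w, end_frequency_hz)
  )
}
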