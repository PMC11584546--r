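#' Glottal source parameters
#'
#' Parameters of a Rosenberg-type glottal pulse train: fundamental frequency,
#' cycle-to-cycle period (jitter) and amplitude (shimmer) perturbation,
#' open quotient (the fraction of each cycle the glottis is open, which
#' controls the spectral tilt of the source), and an additive broadband
#' aspiration-noise level.
#'
#' @param f0 fundamental frequency in Hz (> 0).
#' @param jitter_pct SD of the cycle-to-cycle period perturbation, as a
#'   percentage of the nominal period; in `[0, 20)`.
#' @param shimmer_pct SD of the cycle-to-cycle amplitude perturbation, as a
#'   percentage of the nominal amplitude; in `[0, 50)`.
#' @param open_quotient fraction of each cycle the glottal pulse is open,
#'   strictly in (0, 1). Larger values tilt the source spectrum toward the
#'   first harmonic (breathier, more low-frequency-dominant phonation).
#' @param noise_snr_db aspiration-noise level as a signal-to-noise ratio in
#'   dB. `Inf` means no added noise.
#' @return an object of class `glottal_source_params`.
#' @export
glottal_source_params <- function(f0 = 120, jitter_pct = 0, shimmer_pct = 0,
                                  open_quotient = 0.6, noise_snr_db = Inf) {
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("glottal_source_params: f0 must be a positive number")
  if (!is.numeric(jitter_pct) || jitter_pct < 0 || jitter_pct >= 20)
    stop("glottal_source_params: jitter_pct must be in [0, 20)")
  if (!is.numeric(shimmer_pct) || shimmer_pct < 0 || shimmer_pct >= 50)
    stop("glottal_source_params: shimmer_pct must be in [0, 50)")
  if (!is.numeric(open_quotient) || open_quotient <= 0 || open_quotient >= 1)
    stop("glottal_source_params: open_quotient must be in (0, 1)")
  if (!is.numeric(noise_snr_db) || length(noise_snr_db) != 1L || is.na(noise_snr_db))
    stop("glottal_source_params: noise_snr_db must be a number (Inf = no noise)")
  structure(list(f0 = f0, jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
                 open_quotient = open_quotient, noise_snr_db = noise_snr_db),
            class = "glottal_source_params")
}

#' Vocal tract (formant filter) parameters
#'
#' The vocal tract is modelled as a cascade of second-order resonators at the
#' formant frequencies. F1 and F2 may drift sinusoidally (same phase) to
#' emulate unsteady articulation; F3/F4 are static.
#'
#' @param formant_freqs strictly increasing resonance centre frequencies
#'   F1..F4 in Hz. Defaults are textbook values for the vowel /a/.
#' @param formant_bandwidths per-formant -3 dB bandwidths in Hz (all > 0).
#' @param drift_amplitude peak sinusoidal modulation of F1 and F2, Hz (>= 0).
#' @param drift_rate modulation frequency in Hz.
#' @return an object of class `vocal_tract_params`.
#' @export
vocal_tract_params <- function(formant_freqs = c(800, 1200, 2500, 3500),
                               formant_bandwidths = c(80, 90, 120, 130),
                               drift_amplitude = 0, drift_rate = 3) {
  if (length(formant_freqs) < 1L || any(diff(formant_freqs) <= 0))
    stop("vocal_tract_params: formant_freqs must be strictly increasing")
  if (length(formant_bandwidths) != length(formant_freqs) ||
      any(formant_bandwidths <= 0))
    stop("vocal_tract_params: one positive bandwidth per formant required")
  if (drift_amplitude < 0) stop("vocal_tract_params: drift_amplitude must be >= 0")
  if (drift_rate <= 0) stop("vocal_tract_params: drift_rate must be > 0")
  structure(list(formant_freqs = formant_freqs,
                 formant_bandwidths = formant_bandwidths,
                 drift_amplitude = drift_amplitude, drift_rate = drift_rate),
            class = "vocal_tract_params")
}

#' Specification of one synthetic sustained vowel
#'
#' @param source a [glottal_source_params()].
#' @param tract a [vocal_tract_params()].
#' @param duration_s duration in seconds (> 0); the study protocol targets
#'   approximately 1 second.
#' @param sample_rate_hz sampling rate in Hz (>= 8000); the study protocol
#'   records at 44100 Hz.
#' @param seed optional integer seed for the perturbation and noise draws.
#' @return an object of class `vowel_spec`.
#' @export
vowel_spec <- function(source = glottal_source_params(),
                       tract = vocal_tract_params(),
                       duration_s = 1, sample_rate_hz = 44100, seed = NULL) {
  stopifnot(inherits(source, "glottal_source_params"),
            inherits(tract, "vocal_tract_params"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("vowel_spec: duration_s must be > 0")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz < 8000)
    stop("vowel_spec: sample_rate_hz must be >= 8000")
  if (max(tract$formant_freqs) + tract$drift_amplitude >= sample_rate_hz / 2)
    stop("vowel_spec: formants (plus drift) must lie below Nyquist")
  structure(list(source = source, tract = tract, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, seed = seed),
            class = "vowel_spec")
}

# One Rosenberg glottal flow pulse of `period` samples: raised-cosine opening
# (2/3 of the open phase), cosine-quarter closing (1/3), closed remainder.
rosenberg_pulse <- function(period, open_quotient) {
  n_open <- max(3L, round(open_quotient * period))
  n_open <- min(n_open, period)
  n_up <- max(2L, round(2 / 3 * n_open))
  n_down <- max(1L, n_open - n_up)
  up <- 0.5 * (1 - cos(pi * seq_len(n_up) / n_up))
  down <- cos(pi * seq_len(n_down) / (2 * n_down))
  c(up, down, numeric(max(0L, period - n_up - n_down)))[seq_len(period)]
}

# i.i.d. standard normal draws truncated at +/- 3 SD (redrawn, not clipped,
# would bias the variance; clipping keeps the perturbation model simple and
# prevents period collapse)
rnorm_trunc3 <- function(n) pmax(-3, pmin(3, rnorm(n)))

# Second-order resonator with per-sample centre frequency (time-varying
# difference equation); used only when formant drift is requested.
resonator_timevarying <- function(x, freq_hz, bandwidth_hz, fs) {
  r <- exp(-pi * bandwidth_hz / fs)
  a1 <- 2 * r * cos(2 * pi * freq_hz / fs)
  a2 <- -r * r
  y <- numeric(length(x))
  y1 <- 0; y2 <- 0
  for (n in seq_along(x)) {
    yn <- x[n] + a1[n] * y1 + a2 * y2
    y2 <- y1; y1 <- yn
    y[n] <- yn
  }
  y
}

resonator_static <- function(x, freq_hz, bandwidth_hz, fs) {
  r <- exp(-pi * bandwidth_hz / fs)
  as.numeric(stats::filter(x, c(2 * r * cos(2 * pi * freq_hz / fs), -r * r),
                           method = "recursive"))
}

#' Synthesize a sustained vowel
#'
#' Source-filter synthesis: a Rosenberg glottal pulse train with optional
#' jitter/shimmer perturbations is passed through a cascade of second-order
#' resonators at the formant frequencies (F1/F2 optionally drifting
#' sinusoidally), and broadband aspiration noise is added at the requested
#' SNR. A 50 ms warm-up is synthesized and discarded so the output is in
#' steady state (no resonator onset transient). The output is mean-removed
#' and peak-normalized to |1|.
#'
#' @param spec a [vowel_spec()].
#' @param max_samples guard against runaway allocations; an error is raised
#'   if `duration_s * sample_rate_hz` exceeds it.
#' @return a [waveform()] of the requested duration and rate.
#' @export
#' @examples
#' w <- synthesize_vowel(vowel_spec(duration_s = 0.3, seed = 1))
#' wave_duration(w)
synthesize_vowel <- function(spec, max_samples = 1e7) {
  if (!inherits(spec, "vowel_spec")) stop("synthesize_vowel: 'spec' must be a vowel_spec")
  fs <- spec$sample_rate_hz
  n_out <- round(spec$duration_s * fs)
  if (n_out > max_samples)
    stop("synthesize_vowel: requested ", n_out, " samples exceeds max_samples")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  src <- spec$source
  warmup <- round(0.05 * fs)
  n_total <- n_out + warmup

  # glottal pulse train, cycle by cycle
  t0 <- fs / src$f0
  n_cycles <- ceiling(n_total / (t0 * (1 - 3 * src$jitter_pct / 100))) + 2L
  periods <- pmax(8L, as.integer(round(
    t0 * (1 + src$jitter_pct / 100 * rnorm_trunc3(n_cycles)))))
  amps <- pmax(0.05, 1 + src$shimmer_pct / 100 * rnorm_trunc3(n_cycles))
  pulses <- vector("list", n_cycles)
  for (i in seq_len(n_cycles)) {
    pulses[[i]] <- amps[i] * rosenberg_pulse(periods[i], src$open_quotient)
  }
  flow <- unlist(pulses, use.names = FALSE)[seq_len(n_total)]
  # excite the tract with the glottal flow derivative (lip-radiation model),
  # then apply a Klatt-style one-pole spectral-tilt low-pass whose cutoff
  # falls as the open quotient rises; the pulse shape alone does tilt the
  # source but its sinc-like ripple in the F1/F2 region makes band-energy
  # ratios non-monotone in open_quotient, while the explicit tilt filter is
  # pointwise monotone in its cutoff
  source_sig <- c(0, diff(flow))
  tilt_fc <- 200 + 5000 * (1 - src$open_quotient)^2
  b <- exp(-2 * pi * tilt_fc / fs)
  source_sig <- as.numeric(stats::filter((1 - b) * source_sig, b,
                                         method = "recursive"))
  source_sig <- source_sig - mean(source_sig)

  # formant filter cascade
  tract <- spec$tract
  y <- source_sig
  for (k in seq_along(tract$formant_freqs)) {
    fk <- tract$formant_freqs[k]
    if (k <= 2L && tract$drift_amplitude > 0) {
      inst <- fk + tract$drift_amplitude *
        sin(2 * pi * tract$drift_rate * (seq_len(n_total) - 1) / fs)
      y <- resonator_timevarying(y, inst, tract$formant_bandwidths[k], fs)
    } else {
      y <- resonator_static(y, fk, tract$formant_bandwidths[k], fs)
    }
  }
  y <- y[(warmup + 1L):n_total]

  if (is.finite(src$noise_snr_db)) {
    noise_sd <- sqrt(mean(y^2) / 10^(src$noise_snr_db / 10))
    y <- y + rnorm(n_out, sd = noise_sd)
  }
  y <- y - mean(y)
  waveform(y / max(abs(y)), fs)
}
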