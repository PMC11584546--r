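---
title: "Acoustic vowel biomarkers of frailty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic vowel biomarkers of frailty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxfrail)
```

## The scientific problem

Frailty in older adults is conventionally screened with questionnaires and
physical performance tests. Phonation is a candidate digital alternative: a
sustained vowel carries information about respiratory drive, laryngeal
muscle tone and articulatory steadiness, all of which decline with frailty.
`voxfrail` implements a complete analysis pipeline from raw sustained-/a/
recordings and a clinical assessment table to effect estimates linking four
acoustic parameters to four rule-based frailty phenotypes, together with a
synthetic-data module so that every stage can be exercised and validated
against known truth without any clinical data.

## The four acoustic parameters

All four are computed from a trimmed, DC-removed recording
(44.1 kHz mono in the reference protocol).

* **A1 — zero-crossing rate.** Strict sign changes between consecutive
  samples, counted per 20 ms frame (10 ms hop), divided by the frame length
  in samples, averaged over frames. For a pure tone of frequency $f$,
  $\mathrm{A1} = 2f/f_s$; broadband (aspiration) noise raises it. Samples
  exactly at zero are skipped when locating sign changes, and each frame
  counts the crossings in the intervals that begin at its samples, so a
  tone with an integer number of cycles per frame is counted exactly.
* **A2 — peak/valley amplitude variation.** Per frame, the largest
  local-maximum amplitude $P_i$ and smallest local-minimum amplitude $V_i$;
  then
  $\mathrm{A2} = 100\,( \overline{|P_i-\bar P|}/|\bar P| +
  \overline{|V_i-\bar V|}/|\bar V| )/2$,
  a shimmer-like relative amplitude-instability measure in percent. A raw
  (non-normalized) variant is available via `relative = FALSE`; the
  relative form is the default because it makes A2 invariant to recording
  gain.
* **A3 — formant frequency variation.** Frame-wise F1/F2 estimates by
  autocorrelation linear prediction (order 12 at 11.025 kHz after
  anti-aliased decimation, 25 ms Hamming frames, 10 ms hop), followed by
  $\mathrm{A3} = (\overline{|F1_i - \bar{F1}|} +
  \overline{|F2_i - \bar{F2}|})/2$ in Hz. "Average deviation" is read as
  the mean absolute deviation from the mean throughout (A2 and A3).
* **A4 — low-frequency spectral energy ratio.** The fraction of Welch
  periodogram power (Hann, 4096-sample segments, 50% overlap) at or below
  800 Hz. It rises when the glottal source spectrum tilts toward the first
  harmonic (breathy, hypofunctional phonation).

### Numerical choices in the formant tracker

The LP-based A3 estimator required three robustness decisions, each fixed
after systematic comparison on synthetic vowels with known formant motion:

1. **Double pre-emphasis.** The voiced source falls at roughly
   −12 dB/octave; a single first-order pre-emphasis pass (+6 dB/oct) left
   enough residual tilt to bias LP poles toward the strongest harmonic near
   each formant, producing zero-drift noise floors up to ~6 Hz at some
   fundamental frequencies. Two passes of the 0.97 pre-emphasis filter give
   floors of ≤ 3.3 Hz across f0 100–180 Hz while leaving drifting-formant
   estimates unbiased. (Burg LP, autocorrelation lag-windowing, longer
   windows, and median track smoothing were all tried; double pre-emphasis
   dominated.)
2. **Candidate screening.** LP roots are kept as formant candidates only if
   their frequency exceeds 250 Hz (the lower edge of plausible F1, which
   rejects spurious low poles left by the glottal source) and their
   bandwidth is below 400 Hz; the lowest two survivors are F1 < F2.
3. **Track plausibility screen.** Frames whose F1 or F2 lies more than
   400 Hz from the track median are treated as tracking failures (typically
   a boundary frame locking onto F3) and skipped. Genuine formant drift in
   sustained phonation is an order of magnitude smaller, so the screen does
   not touch the quantity A3 measures.

## Recording quality control

Three gates reproduce the reference measurement protocol; all thresholds
are configuration defaults, not hard-coded:

* **Endpoint detection** (`detect_endpoints()`): Rabiner-style
  energy + zero-crossing double threshold on 20 ms frames, noise floor from
  the first 100 ms, thresholds capped relative to the maximum frame energy
  so fully voiced inputs pass through unchanged. Trimming never lengthens a
  signal and is idempotent to within one frame hop.
* **Duration gate** (`validate_duration()`): the trimmed utterance must
  last 0.8–1.2 s. The bounds are inclusive, because the protocol withdraws
  recordings *strictly* shorter than 0.8 s or longer than 1.2 s.
* **Repeat variability** (`select_repeats()`): each subject is recorded
  three times; a parameter is accepted only if its coefficient of variation
  across the repeats (population SD / mean × 100) is strictly below 15%,
  and the accepted value is the mean of the three repeats. The protocol
  states only "variability less than 15%"; the CV is the standard
  dimensionless repeatability measure, and the mean is the minimum-variance
  summary. Acceptance is per parameter, not per recording, so one unstable
  parameter does not discard the subject's other three.

## Frailty phenotype scoring

Two indices are scored from the assessment table, then combined:

| index | criteria | frail | prefrail |
|---|---|---|---|
| EBF (energy-based) | weight loss ≥ 4.5 kg or > 5% in the past year; exhaustion | 2 | 1 |
| SBF (sarcopenia-based) | chair-rise inability; grip < 28 kg (men) / < 18 kg (women); gait < 1.0 m/s or non-ambulatory; ADL deterioration | ≥ 3 | 1–2 |

HBF-E is EBF-frail while at least SBF-prefrail; HBF-S is SBF-frail while at
least EBF-prefrail; the four-category outcome is
nonfrail / EBF-only / SBF-only / both by which indices score frail.

Boundary conventions follow the wording of the definitions: "at least
4.5 kg" is inclusive, "> 5%" strict, the grip cutoffs strict (28/18 are
cutoffs for *low* grip), "< 1.0 m/s" strict. A non-ambulatory subject
counts as low mobility even with no gait measurement. Any other missing
required item makes the affected status indeterminate (`NA`); subjects with
indeterminate outcomes are excluded from the corresponding models with a
logged count (complete-case analysis). Whether a subject frail on both
indices "belongs" to HBF-E or HBF-S is left open by the definitions; both
flags are reported and the four-category variable disambiguates.

## Association models

Each acoustic parameter is evaluated in its own model (univariable by
default; covariate adjustment is available but off, since the reference
analysis does not state any adjustment):

* `fit_binomial()`: maximum-likelihood logistic regression (IRLS via
  `stats::glm`, convergence tolerance 1e-10, max 100 iterations) of a
  binary frailty outcome on one exposure; reports OR = $e^{\hat\beta}$ with
  Wald 95% CI $e^{\hat\beta \pm 1.96\,\mathrm{SE}}$.
* `fit_multinomial()`: multinomial logit (`nnet::multinom`, relative
  tolerance 1e-14) of the four-category outcome with **nonfrail** as
  baseline; reports one RRR per non-baseline category with Wald CIs. With
  two categories the RRR coincides with the binomial OR (verified to
  1e-6 in the tests).
* `odds_to_probability()`: odds/(1 + odds).

Perfect or quasi-separation — fitted probabilities pinned at 0/1, or a
slope exceeding 7 on the per-SD log-odds scale — raises an error rather
than reporting a meaningless estimate; the pipeline records such models
with a note. Wald (not profile) intervals are used to match conventional
symmetric-on-the-log-scale OR reporting. No multiple-testing correction is
applied; the run manifest records how many models were fitted. Because the
original feature units behind published effect sizes are not recoverable,
`standardize_exposure = TRUE` optionally reports per-SD effects; effects
are otherwise per natural unit of A1–A4 as defined above.

## The synthetic-data generator

### Vowel synthesis (`synthesize_vowel()`)

Source-filter synthesis:

* **Source**: Rosenberg glottal pulse (raised-cosine opening over 2/3 of
  the open phase, cosine-quarter closing over 1/3), cycle periods and
  amplitudes perturbed by i.i.d. Gaussian jitter/shimmer truncated at
  ±3 SD (truncation prevents period collapse). The vocal tract is excited
  by the flow derivative (lip-radiation convention).
* **Spectral tilt**: a one-pole low-pass on the source with cutoff
  $f_c = 200 + 5000\,(1-\mathrm{OQ})^2$ Hz, falling as the open quotient
  rises. The pulse shape alone does tilt the source monotonically, but its
  sinc-like spectral ripple sweeps through the F1/F2 region as OQ changes,
  making post-filter band-energy ratios non-monotone; the explicit tilt
  filter (the same device as the tilt control in cascade formant
  synthesizers) is pointwise monotone in its cutoff, so A4 responds
  monotonically to OQ as intended.
* **Filter**: cascade of second-order resonators at F1–F4 (defaults 800,
  1200, 2500, 3500 Hz with bandwidths 80/90/120/130 Hz, textbook /a/
  values). F1 and F2 may drift sinusoidally (same phase; F3/F4 static,
  since A3 measures only F1/F2). For a drift of amplitude $d$, the mean
  absolute deviation of a sinusoid gives the closed-form expectation
  $\mathrm{A3} \approx 2d/\pi$.
* **Noise**: white aspiration noise added after the filter at a stated SNR
  (dB) versus the voiced signal; `Inf` disables it. Adding it post-filter
  keeps it broadband, which is what drives the zero-crossing rate up as
  SNR falls.
* A 50 ms warm-up is synthesized and discarded so outputs are steady-state
  (no resonator onset transient contaminating A2/A3); output is
  mean-removed and peak-normalized.

What the generator does **not** emulate: onset/offset dynamics, intonation,
vocal fry, nonlinear source-filter interaction, room acoustics, or
microphone coloration. Tests passing on these vowels therefore validate the
*estimators and pipeline logic*, not field robustness on clinical
recordings.

### Cohort synthesis (`generate_cohort()`)

Mode 1 draws assessment items from configurable distributions, scores true
phenotypes with the package's own rules, and draws A1–A4 conditional on
phenotype (linear shifts plus Gaussian noise, directions matching the
reported associations: lower A1 and higher A4 with EBF, higher A2/A3 with
SBF). Mode 2 draws features marginally and then binary outcomes from
$\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j A_j))$
with user-set coefficients — the parameter-recovery harness: fitting
`fit_binomial()` to mode-2 cohorts must recover the generating $\beta$.

Default assessment distributions target a frailty prevalence of roughly
12–15% per index, inside the 12–24% range reported for community-dwelling
older adults, e.g. P(weight-loss criterion) ≈ 0.4 × 0.7 = 0.28 and
P(exhaustion) = 0.5 give EBF-frail ≈ 14%. They are deliberately **not**
calibrated to any particular study sample, whose item distributions are not
public. Weight loss is capped at 25% of body weight (physiologic bound).

## Problem sizes used in validation

The packaged tests and the acceptance script use: 50 replicates per level
for the monotone synthesis-response checks (1 s vowels, f0 drawn uniformly
from 100–180 Hz per replicate as between-subject variation); 200 replicates
of n = 5000 mode-2 cohorts for coefficient recovery and CI coverage; 500
null multinomial fits of n = 400 for the type-I error rate; and a
60-subject, 3-repeat synthetic study (180 recordings) for the end-to-end
run. These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands (e.g. coverage SE ≈ 1.5 percentage points at 200
replicates).

## Known limitations

* The acoustic feature definitions leave frame length, windowing and
  normalization open; the values here are standard short-time speech
  analysis conventions, not reconstructions of the original
  implementation, so absolute feature values (and hence per-unit ORs) are
  not comparable across implementations.
* The A2 reading ("largest/smallest extremum per frame, averaged
  deviation across frames") is one of several defensible interpretations;
  the raw-amplitude variant is provided behind a switch.
* LP formant tracking assumes an adult /a/-like spectrum; vowels with F1
  below 250 Hz would need the candidate floor lowered.
* Separation handling refuses to report estimates rather than applying
  penalized (Firth-type) corrections; small studies with rare phenotypes
  will therefore show models flagged with notes instead of estimates.
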