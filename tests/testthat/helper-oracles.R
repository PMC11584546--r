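# shared fixtures and independent oracles, built in code

make_tone <- function(freq_hz, fs = 44100, duration_s = 1, amp = 1) {
  waveform(amp * sin(2 * pi * freq_hz * (0:(round(duration_s * fs) - 1)) / fs),
           fs)
}

# brute-force count of strict sign changes over a whole signal
count_sign_changes <- function(x) {
  s <- sign(x[x != 0])
  sum(s[-1] != s[-length(s)])
}

# one assessment record realizing a given criterion combination, using
# values safely away from (or exactly at) the scoring cutoffs
record_for_combo <- function(w, e, c_, g, wk, a) {
  data.frame(
    subject_id = "X", sex = "male",
    weight_loss_kg = if (w) 5 else 0, weight_loss_pct = if (w) 6 else 0,
    exhaustion = as.logical(e), chair_rise_unable = as.logical(c_),
    grip_kg = if (g) 27 else 30, gait_speed_mps = if (wk) 0.9 else 1.2,
    non_ambulatory = FALSE, adl_deterioration = as.logical(a))
}

# independent brute-force phenotype enumerator (mirrors the clinical rules
# directly from criterion counts, no shared code with the package)
brute_force_phenotype <- function(w, e, c_, g, wk, a) {
  ebf_met <- w + e
  sbf_met <- c_ + g + wk + a
  ebf <- if (ebf_met == 2) "frail" else if (ebf_met == 1) "prefrail" else "robust"
  sbf <- if (sbf_met >= 3) "frail" else if (sbf_met >= 1) "prefrail" else "robust"
  hbf_e <- ebf == "frail" && sbf %in% c("prefrail", "frail")
  hbf_s <- sbf == "frail" && ebf %in% c("prefrail", "frail")
  four <- if (ebf == "frail" && sbf == "frail") "both"
    else if (ebf == "frail") "EBF-only"
    else if (sbf == "frail") "SBF-only"
    else "nonfrail"
  list(ebf_met = ebf_met, ebf = ebf, sbf_met = sbf_met, sbf = sbf,
       hbf_e = hbf_e, hbf_s = hbf_s, four = four)
}

# 2x2 data with the given cell counts (exposed cases a, exposed controls b,
# unexposed cases c, unexposed controls d)
table2x2_data <- function(a, b, c_, d) {
  data.frame(exposed = rep(c(1, 1, 0, 0), c(a, b, c_, d)),
             case = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d)))
}
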