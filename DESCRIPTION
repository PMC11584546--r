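Package: voxfrail
Title: Sustained-Vowel Acoustic Biomarkers of Frailty Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline linking four sustained-vowel acoustic
    parameters (zero-crossing rate, peak/valley amplitude variation, formant
    frequency variation, and low-frequency spectral energy ratio) to rule-based
    frailty phenotypes in older adults. Provides source-filter vowel synthesis
    and cohort simulation with known truth, recording quality control (endpoint
    trimming, duration gating, repeat-variability screening), acoustic feature
    extraction, Fried-derived frailty phenotype scoring (energy-based,
    sarcopenia-based, and hybrid indices), and per-feature binomial and
    multinomial logistic association models reporting odds ratios and relative
    risk ratios with Wald confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
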