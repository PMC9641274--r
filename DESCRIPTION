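Package: thzburn
Title: Burn Severity and Wound-Healing Prediction from Terahertz
    Time-Domain Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing thermal burn injuries from terahertz
    time-domain spectroscopy (THz-TDS) reflection images. Implements the
    full analysis chain: a synthetic THz-TDS image simulator for the
    two-reflection imaging-window geometry, signal conditioning (zero-phase
    band-pass filtering, first-reflection alignment, Blackman time gating,
    biopsy-pixel rejection, region-of-interest averaging), a maximal-overlap
    discrete wavelet packet transform (MODWPT) with sequency-ordered
    sub-bands, energy-to-Shannon-entropy-ratio (ESER) features deconvolved
    by an air reference, and cross-validation-tuned support vector machine
    classifiers for wound-healing prediction and burn-depth grading, with
    repeated-split evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
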