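Package: pwvflow
Title: Pulse Wave Velocity Estimation from Phase-Contrast Flow Curves
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating aortic pulse wave velocity (PWV) from
    single-cardiac-cycle phase-contrast MRI flow and velocity curves.
    Implements the time-to-foot, maximum-upslope and time-to-peak
    transit-time estimators with automatic and manual baseline correction,
    circular Gaussian curve smoothing, centerline traveling-distance
    computation, a temporal-resolution computer phantom that determines the
    minimum number of timeframes per cardiac cycle required for accurate
    PWV, a parametric synthetic waveform generator with known ground-truth
    PWV for validation, and Bland-Altman agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
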