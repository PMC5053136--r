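Package: iecsaxs
Title: Background Correction and Analysis for Ion-Exchange Chromatography
    Coupled SAXS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction for time-resolved small-angle X-ray scattering
    (SAXS) acquired during ion-exchange chromatography (IEC) runs with linear
    or stepwise salt gradients. Provides frame-series containers and curve
    arithmetic, shift-scan background correction for linear gradients with
    low-q/mid-q ratio flatness diagnostics, exponential buffer-transition
    modelling and per-frame interpolated background subtraction for salt
    steps, averaged-curve buffer matching against a salt series, Guinier and
    Porod analysis, correlated-volume mass estimation, longest-run (CORMAP)
    frame similarity testing, stable-region selection, and a synthetic run
    generator with full ground truth so every stage of the pipeline can be
    validated without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
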