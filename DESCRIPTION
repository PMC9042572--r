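Package: hpadyn
Title: Dynamic Phenotypes of the HPA Axis During and After Cardiac Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired ACTH-cortisol time series sampled at
    high frequency around major surgery. Implements an open-loop,
    two-compartment cortisol model driven by delayed ACTH input through a
    Hill-type adrenal response; ensemble random-search calibration of the
    model with fixed-sensitivity and fixed-Hill-coefficient scenarios; a
    non-stationary synchrony battery (time-lagged cross-correlation, rolling
    window TLCC, instantaneous phase synchrony, ultradian period and pulse
    statistics); a rule-based classifier of post-surgical dynamic phenotypes
    (single-pulse, two-pulse, multiple-pulse); and a residual-error versus
    inflammatory-mediator correlation analysis with cytokine PCA. Includes a
    seeded synthetic-data generator emulating healthy ultradian/circadian
    profiles, post-surgical disruption regimes and cytokine responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
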