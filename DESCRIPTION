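Package: ojipr
Title: Analysis of Fast Chlorophyll Fluorescence (OJIP) Transients and the JIP-Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing polyphasic chlorophyll-a fluorescence rise
    (OJIP) transients from continuous-excitation fluorometers and related
    photosystem II inhibition assays. Extracts the O, L, K, J, I and P
    landmark values, computes the JIP-test energy-flux and quantum-yield
    parameter suite (performance indexes PI_ABS and PI_total included),
    double-normalised kinetics with L-band and K-band difference curves and
    the I-P half-rise time, the Q_B-site inhibitor occupancy statistic R_J,
    characteristic features of modulated 820 nm reflection kinetics,
    saturation-pulse quenching parameters, log-logistic dose-response I50
    estimation, and a lesion-diameter pathogenicity classifier. A compact
    mechanistic generator of inhibitor-treated transients makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
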