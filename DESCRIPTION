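Package: h2axdosim
Title: Gamma-H2AX Biodosimetry for Protracted Cesium-137 Internal Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiation biodosimetry after protracted internal
    exposure to Cesium-137. Implements biexponential whole-body retention
    biokinetics with committed-dose and dose-rate calculation, a
    stretched-exponential kinetic model of gamma-H2AX fluorescence as a
    function of injected activity and time, weighted Gaussian
    maximum-likelihood fitting with profile-likelihood confidence
    intervals, Monte-Carlo inversion of fluorescence measurements into
    injected-activity estimates with correlation and ROC evaluation,
    per-cell fluorescence screening rules, and a seeded synthetic-study
    generator emulating the mouse internal-emitter study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
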