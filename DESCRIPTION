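Package: cvreserve
Title: Beat-by-Beat Classification of Progressive Central Hypovolemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying machine-learning detection of progressive
    central hypovolemia from non-invasive hemodynamic waveforms. Simulates
    lower-body-negative-pressure (LBNP) style recordings ending in
    pre-syncope, parametrizes arterial pressure and cerebral blood flow
    velocity pulses into landmark features, derives per-beat hemodynamics,
    windowed trend/variance features and transfer-function cerebral
    autoregulation gain and phase, assembles nine feature sets, trains
    radial-basis-function support vector classifiers under a
    leave-one-subject-out protocol with an 8 x 8 hyperparameter grid, and
    quantifies performance with one-vs-all sensitivity/specificity,
    moving-average model error, and log-odds-ratio cutoff analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
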