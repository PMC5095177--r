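Package: benthicN
Title: Co-Occurring Benthic Nitrogen Cycling Rates from 15N Flow-Through
    Core Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers co-occurring sediment nitrogen cycling rates
    (denitrification, anammox, dissimilatory nitrate reduction to ammonium,
    nitrogen fixation and sediment oxygen demand) from flow-through core
    incubations amended with 15N tracers, using the isotope pairing
    technique. Provides benthic flux computation with steady-state and
    above-control screening, the community bioturbation potential index
    (BPc), Pearson correlation and regression between rates and station
    variables, ordinary-kriging interpolation of predicted rates, and three
    regional annualization (upscaling) techniques with Monte Carlo
    uncertainty. Includes a forward simulator of three-treatment incubation
    series and log-normal infauna communities for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
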