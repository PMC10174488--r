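Package: cyclecombo
Title: Cell-Cycle State-Transition Markov Modelling of Drug Combination Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov modelling of cell-cycle state transitions
    (G0/G1, late G1/S, G2/M with division on re-entry) for predicting cancer
    cell population responses to targeted single agents and, without
    refitting, to pairwise drug combinations. Provides growth calibration
    from population doubling time and steady-state cell-cycle fractions,
    Hill-type mapping of drug dose to transition inhibition and drug-induced
    death, least-squares dose-response fitting with AIC model comparison,
    8x8 combination-surface prediction, robust excess-over-Bliss synergy
    scoring via row/column four-parameter logistic fits, and a stochastic
    synthetic 96-well plate generator so the whole pipeline runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml
Config/testthat/edition: 3
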