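Package: fupbpk
Title: Physiologically Based Pharmacokinetics and Toxicity Thresholds for
    5-Fluorouracil
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An eight-organ perfusion-limited physiologically based
    pharmacokinetic (PBPK) model of intravenous 5-fluorouracil with
    saturable (Michaelis-Menten) hepatic elimination, solved for arbitrary
    bolus/infusion schedules via compiled 'deSolve' code.  Derives the
    exposure metrics used in therapeutic drug monitoring (Cmax, AUC,
    steady-state and early "dynamic" concentrations), relates exposure to
    toxicity through concentration binning and a depth-1 classification
    tree (decision stump), and generates seeded synthetic patient cohorts
    with the dosing and toxicity structure of published 5-FU case series
    so the whole exposure-toxicity pipeline is reproducible end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
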