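Package: nitrokin
Title: Ping-Pong Enzyme Kinetics, Mixed Inhibition and Flavin Redox
    Titration Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Global nonlinear least-squares analysis of two-substrate
    ping-pong (substituted-enzyme) steady-state kinetics, dual-half-reaction
    mixed inhibition with nested-model comparison, and one- versus
    two-electron Nernst fitting of spectroelectrochemical redox titrations,
    as used to characterise flavin-dependent nitroreductases such as
    Escherichia coli NfsA.  Includes the spectrophotometric arithmetic that
    turns raw absorbance traces into molar rates, error propagation for
    catalytic efficiencies (kcat/Km), a synthetic-data generator reproducing
    the statistical structure of initial-rate surfaces and potentiometric
    titrations, delimited-text readers and writers for all inputs, and a
    small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
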