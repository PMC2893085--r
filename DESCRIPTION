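Package: araLogic
Title: Input Integration at Arabinose Regulon Promoters from Repression
    Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers in-vivo transcription-factor activities (AraC-arabinose
    and CRP-cAMP) from synthetic repression reporters, fits an additive
    input-integration model of promoter expression to steady-state
    arabinose x cAMP gradient data with significance-based model reduction
    (nonlinear least squares, RSE and AIC comparison), and predicts dynamic
    promoter expression during diauxic shift by integrating a production-
    dilution ODE driven by measured activity profiles. Includes a seeded
    synthetic-data generator for gradient plates and diauxic time courses
    with known ground truth, and in-silico tools for degenerate consensus
    operator design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
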