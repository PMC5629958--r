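Package: ewmtrial
Title: Entropy-Weight Evaluation of Replicated Water-Fertilizer Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the decision analysis of factorial irrigation by
    fertilization field trials: derivation of per-scheme agronomic indicators
    (marketable yield, blossom-end rot incidence, fruit sugar/acid ratio,
    irrigation water use efficiency, topsoil salinity and available nutrients)
    from plot-level replicate records; two-way fixed-effects ANOVA with
    Duncan's multiple range letter groups; and an entropy weight coefficient
    model that fuses Shannon-entropy objective weights with decision-maker
    subjective weights to score and rank treatment schemes. A synthetic-trial
    generator with known response surfaces supports end-to-end testing without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
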