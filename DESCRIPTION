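Package: qsrrop
Title: Biomimetic-Chromatography QSRR Modelling of Organophosphate Pesticides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-retention relationship (QSRR)
    analysis of organophosphate pesticides characterised by biomimetic
    chromatography (C18 lipophilicity, immobilized-artificial-membrane
    phospholipid affinity, and human-serum-albumin binding). Provides
    chromatographic index transforms and gradient calibration, descriptor
    matrix pruning and auto-scaling, genetic-algorithm feature selection
    coupled to multiple linear regression, OECD-style internal and external
    validation metrics (R2, Q2_LOO, RMSE, Lin's concordance), applicability
    domain assessment via leverages and Williams plots, exploratory
    clustering and correlation analysis of endpoint tables, and a synthetic
    data generator with planted linear signals for end-to-end testing.
    Ships a published 18-compound organophosphate endpoint table and
    reference model equations as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
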