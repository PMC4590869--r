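Package: ioxgfr
Title: Iohexol Plasma-Clearance GFR with Limited Sampling Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Noncompartmental estimation of glomerular filtration rate (GFR)
    from iohexol plasma-clearance curves in cats: dose/AUC clearance from a
    seven-point sampling schedule, four limited-sampling simplifications
    (Models A-D), and the agreement and accuracy battery used to validate
    them (Pearson correlation, linear regression, Bland-Altman limits of
    agreement, P15/P30/P50 accuracy, chi-square comparison of accuracy
    proportions, and group t-tests). Includes a two-compartment IV-bolus
    simulator that generates synthetic feline cohorts with known true
    clearance, proportional assay noise and limit-of-quantification
    censoring, so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
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
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
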