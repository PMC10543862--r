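Package: cochloc
Title: Method Agreement and Mid-Modiolar Axis Collocation for Cochlear
    Implant Electrode Localization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing cochlear-implant electrode localization
    methods that report electrode-to-modiolar-axis distance (EMD) and
    angular depth of insertion (aDOI). Implements the polar/Cartesian
    coordinate model with multi-turn angle unwrapping, a translation-only
    post-hoc collocation of the mid-modiolar axis that minimizes a
    Pearson-correlation cost, a method-comparison statistics battery
    (Bland-Altman limits of agreement, percentage error, Pearson
    correlation with Fisher-z confidence interval, two-way mixed-effects
    intraclass correlation, Lilliefors normality test, confounder
    subgroup tests), and a synthetic spiral-cohort simulator calibrated
    to interrater precision so the whole pipeline is testable without
    patient data.
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
    nortest,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
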