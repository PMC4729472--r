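Package: cvimmune
Title: Longitudinal Analysis of Cervicovaginal Soluble Immune Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying background variability of soluble immune
    proteins measured longitudinally in cervicovaginal lavage samples.
    Provides a calibrated synthetic-cohort generator, healthy-visit
    filtering, quantification-limit (LLOQ/ULOQ) handling, menstrual
    cycle-phase classification from the urinary pregnanediol-glucuronide to
    creatinine ratio, variance-components and intraclass-correlation
    estimation by restricted maximum likelihood, and per-analyte exposure
    signature scans using random-intercept linear and logistic models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    lme4,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    generics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
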