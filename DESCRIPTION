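Package: cmmcdyn
Title: Longitudinal Dynamics of Circulating Multiple Myeloma Cell Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial enumerations of circulating multiple
    myeloma cells (CMMCs, absolute count per 4 mL of peripheral blood) in
    smouldering and newly diagnosed multiple myeloma: baseline median
    stratification, the coMMstant on-treatment trajectory index,
    biomarker-count association and random-intercept longitudinal modelling,
    concordance between CMMC detectability and bone-marrow minimal residual
    disease, Kaplan-Meier/Cox survival contrasts between trajectory classes,
    and arm-level single-cell copy-number clonality analysis against a bulk
    diagnostic profile. Includes a seeded synthetic-cohort generator with
    zero-inflated negative-binomial counts, proportional-hazards survival and
    multi-subclone single-cell experiments carrying ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
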