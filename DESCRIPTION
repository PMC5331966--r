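Package: hivrebound
Title: Time-Updated Medication Exposure and Virologic Rebound Analysis for HIV Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacoepidemiologic analysis of virologic rebound on
    suppressive antiretroviral therapy. Reconstructs day-resolution drug
    exposure calendars from pharmacy dispensing records and inpatient orders,
    evaluates three time-updated exposure modes (current use, proportion of
    days covered, ever use), classifies antiretroviral regimens, applies
    virologic-failure and censoring rules to viral-load series, assembles
    counting-process datasets over inter-measurement intervals, and fits
    stratified Cox models with multivariate adjustment and stabilized,
    truncated inverse-probability weights. Includes a synthetic-cohort
    generator with known ground truth so the full pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival (>= 3.4),
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
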