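Package: cgmvar
Title: Glycemic Variability Analytics for Continuous Glucose Monitoring Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of continuous glucose monitoring (CGM)
    cohorts from open-source automated insulin delivery systems: reading
    Nightscout-style glucose entries, cleaning rules for out-of-range
    artifacts, per-participant glycemic variability metrics (time in range,
    LBGI/HBGI, GMI, J-index, SD of rate of change, coefficient of
    variation), gender-stratified distribution summaries with z,
    Kolmogorov-Smirnov and Mann-Whitney tests, calendar-binned glucose time
    series, agglomerative clustering of glucose profiles, fingerprint-based
    deduplication of participants across data sets, and cross-cohort
    comparison. Includes a synthetic CGM cohort generator with circadian
    structure, AR(1) noise, sensor gaps, artifacts and planted duplicates
    so the whole pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    cluster,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust
Config/testthat/edition: 3
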