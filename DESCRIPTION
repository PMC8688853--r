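Package: amirei
Title: Digital Biomarkers for the Clinical Course of Alcohol Use Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes digital biomarkers of sobriety and test compliance from
    scheduled breathalyzer test logs. Daily outcomes (performed tests below or
    above a blood-alcohol threshold, and streaks of omitted tests with a
    decaying imputed score) are aggregated into a 0-100 raw score and smoothed
    into the Addiction Monitoring Index (AMI) family of exponentially weighted
    moving averages. The Recovery and Exacerbation Index (REI), the ratio of a
    short-memory to a long-memory AMI, tracks the current trend independent of
    level; runs of days with REI below a threshold are segmented into
    exacerbation events (EEs) with per-patient summaries. Includes an
    ANOVA-based threshold-selection scan over drinks-per-drinking-day data,
    cohort periodicity analysis (weekday, ISO week, treatment-time bins) with
    cluster-robust logistic tests, a synthetic-cohort simulator with known
    ground truth, and a command-line pipeline with multi-panel clinical-course
    plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    patchwork,
    sandwich,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
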