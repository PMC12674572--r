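Package: accelharmony
Title: Harmonization of Accelerometry Metrics Across Sensor Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes four movement-intensity metrics (movement acceleration
    intensity, Euclidean norm minus one, mean amplitude deviation, and
    ActiGraph-style activity counts rescaled to counts per minute) from raw
    triaxial acceleration recorded at six body positions, and reproduces a
    laboratory comparability analysis across metrics and wearing sites:
    per-condition trimming and truncation, activity-category descriptives,
    between-person variance, a 24 x 24 Pearson correlation matrix over
    metric-by-location series, pairwise linear conversion models, and
    ROC-based intensity cut-point calibration. Ships published reference
    tables of category means and correlations as queryable data resources and
    a seeded synthetic cohort generator so the full pipeline runs without any
    raw-data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    signal,
    yaml,
    jsonlite,
    pROC,
    withr,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
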