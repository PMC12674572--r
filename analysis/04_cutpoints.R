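#!/usr/bin/env Rscript
# Step 4: metric- and location-specific intensity cut-points.
#
# Calibrates thresholds between adjacent intensity zones (sedentary |
# light | moderate | vigorous) for every (metric, location) series by
# maximizing Youden's J over the pooled second-level values. Cut-points are
# expected to differ strongly between metrics and between wearing
# positions — the reason a single published cut-point does not transfer
# across devices or placements.

suppressPackageStartupMessages({
  library(accelharmony)
  library(dplyr)
})

cohort <- read_cohort_csv("results/cohort.csv")
cuts <- calibrate_cutpoints(cohort)
readr::write_csv(cuts, "results/cutpoints.csv")

message("MAD cut-points (mg) per location:")
cuts |>
  filter(metric == "MAD") |>
  mutate(across(c(threshold, sensitivity, specificity, j), \(x) round(x, 3))) |>
  as.data.frame() |>
  print(row.names = FALSE)

spread <- cuts |>
  group_by(metric, boundary) |>
  summarise(min_threshold = min(threshold), max_threshold = max(threshold),
            .groups = "drop")
message("Cut-point range across wearing positions (same metric, same boundary):")
print(as.data.frame(spread), row.names = FALSE)
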