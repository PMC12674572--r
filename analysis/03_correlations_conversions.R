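#!/usr/bin/env Rscript
# Step 3: the 24 x 24 second-level correlation matrix and all pairwise
# linear conversion models.
#
# Pearson correlations are computed over pooled one-second values aligned
# by (participant, condition, second); conversion models are OLS fits for
# each of the 276 series pairs. The count metric's quantized, dead-banded
# pipeline makes its relationship to the amplitude metrics less linear, so
# its between-location correlations come out lower — the directional
# finding that motivates caution when converting CPM.

suppressPackageStartupMessages({
  library(accelharmony)
  library(dplyr)
})

cohort <- read_cohort_csv("results/cohort.csv")

cm <- correlation_matrix(cohort)
conv <- conversion_table(cohort)
readr::write_csv(conv, "results/conversions.csv")
cm_df <- tibble::as_tibble(as.data.frame(unclass(cm)))
readr::write_csv(dplyr::bind_cols(tibble::tibble(series = rownames(cm)),
                                  cm_df), "results/correlations.csv")

within_mean <- function(metric) {
  idx <- grep(paste0("^", metric, "\\."), rownames(cm))
  sub <- cm[idx, idx]
  mean(sub[lower.tri(sub)])
}
message("Mean within-metric between-location r on the synthetic cohort:")
for (m in accel_metrics()) {
  message(sprintf("  %-4s %.3f", m, within_mean(m)))
}

best <- conv |> arrange(desc(r2)) |> slice_head(n = 3)
worst <- conv |> arrange(r2) |> slice_head(n = 3)
message("Most linear conversions (by r2):")
print(as.data.frame(best), row.names = FALSE)
message("Least linear conversions (by r2):")
print(as.data.frame(worst), row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  wide <- cohort |>
    mutate(series = paste(metric, location, sep = ".")) |>
    select(participant, condition, category, second, series, value) |>
    tidyr::pivot_wider(names_from = series, values_from = value)
  p <- ggplot(wide, aes(MAD.hip, MAD.chest, colour = category)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "black", linewidth = 0.4) +
    labs(title = "A nearby-position pair stays linear across categories") +
    theme_bw(base_size = 9)
  ggsave("results/figures/scatter_mad_hip_chest.png", p,
         width = 6, height = 4.5, dpi = 120)
  message("Wrote results/figures/scatter_mad_hip_chest.png")
}
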