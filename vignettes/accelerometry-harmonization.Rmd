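---
title: "Harmonizing accelerometry metrics across sensor positions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing accelerometry metrics across sensor positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelharmony)
```

## The problem

Physical activity is routinely measured with body-worn triaxial
accelerometers, but two sources of heterogeneity make study results hard to
compare. First, raw acceleration is summarised by different intensity
metrics — movement acceleration intensity (MAI), Euclidean norm minus one
(ENMO), mean amplitude deviation (MAD), and ActiGraph-lineage activity
counts rescaled to counts per minute (CPM) — that treat gravity and
frequency content differently. Second, devices are worn at different sites
(thigh, hip, chest, ankle, wrist, upper arm), and placement strongly shapes
the measured signal: a wrist sensor barely sees cycling, while an ankle
sensor sees it amplified.

`accelharmony` implements the four metrics from raw 64 Hz signals,
reproduces the comparability analysis that quantifies how values translate
across metrics and wearing positions (descriptives, between-person
variance, a 24 x 24 second-level Pearson matrix, pairwise linear
conversion models, intensity cut-points), ships the published reference
tables of category means and correlations as queryable resources, and
provides a seeded synthetic cohort generator so every stage runs without
any raw-data download.

## The four metrics

All metrics operate on the per-sample vector magnitude
$r_i = \lVert(x_i, y_i, z_i)\rVert$ (in g) or on the filtered axes, and
aggregate over half-open one-second epochs $[k, k+1)$; trailing partial
epochs are dropped. Values are held in g-derived units internally and
scaled to mg exactly once, at epoch aggregation.

* **MAI** — each axis is band-pass filtered (Butterworth, 0.25–11 Hz),
  then the per-sample Euclidean norm of the filtered axes is averaged per
  epoch. The band-pass removes both gravity (DC) and content too fast to
  be human movement.
* **ENMO** — $\max(r_i - 1, 0)$ averaged per epoch. Subtracting 1 g
  removes gravity on average; clipping prevents negative epochs when the
  magnitude dips below 1 g.
* **MAD** — per epoch, $\frac{1}{n}\sum_i \lvert r_i - \bar r \rvert$.
  The epoch mean $\bar r$ estimates the static (gravity) component, so MAD
  needs no filter and is insensitive to orientation.
* **Counts / CPM** — each axis is resampled to 30 Hz (polyphase), band-pass
  filtered over 0.29–1.63 Hz, clipped to $\pm 2.13$ g, rectified,
  dead-banded at 0.068 g, quantized by a signed 12-bit converter over
  $[-2.13, 2.13]$ g, and every quantization level beyond 128 becomes one
  count; per-sample counts are summed per second. Vector-magnitude counts
  are the Euclidean norm of the three per-axis epoch counts. Per-second
  CPM multiplies by 60 (a constant rescaling that leaves Pearson
  correlations untouched); condition-level CPM averages the condition's
  seconds first.

ENMO and MAD depend only on $\lVert a \rVert$ and are therefore exactly
invariant under 3D rotations of the axes; MAI and counts are not, because
they filter per axis. For a magnitude $1 + A\sin(\omega t)$ over whole
periods, ENMO tends to $1000\,A/\pi$ mg and MAD to $1000\,2A/\pi$ mg —
the closed forms the test suite asserts to 0.5 % at 64 Hz.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| MAI band | 0.25–11 Hz | removes gravity and non-movement content while keeping gait harmonics |
| MAI `order` | 4 | Butterworth prototype order; the band-pass has `2 * order` poles |
| MAI `phase` | causal | stream processing applies filters causally; `zero_phase` (forward–backward) is available and tested |
| count band | 0.29–1.63 Hz | the narrow human-movement band of the count lineage |
| `resample_hz` | 30 | count algorithms operate at a reduced rate; only downsampling is supported |
| `peak_g`, `deadband_g` | 2.13 g, 0.068 g | clip and rectified dead-band of the count pipeline |
| `adc_bits`, `deadband_levels` | 12, 128 | quantization depth and the level threshold beyond which levels become counts |
| `trim_s` | 5 s | first/last seconds of each condition hold start/stop artefacts |
| epoch | 1 s, half-open | fine enough to resolve 2–5 min conditions |

Two genuinely open choices deserve note. "4th order" for the MAI filter is
read as the analogue prototype order (8 poles after the band-pass
transformation); both the order and the phase mode are exposed because
either convention exists in the wild. For the count algorithm, the
published description underdetermines how the rectified dead-band and the
"each level beyond 128" rule interact; this implementation applies the
dead-band before quantization and converts levels in excess of
`deadband_levels` to counts one-for-one. With a 12-bit converter the
dead-band (0.068 g ≈ 65 levels) is then subsumed by the level threshold
(128 levels ≈ 0.133 g); both stages are kept and separately configurable
so other conventions can be dialled in. Absolute count magnitudes under
this reading are larger than commercial devices print; every comparative
analysis in the package (correlations, conversions, cut-points) is
invariant to that overall scale.

A practical numerical consequence of the causal default: a 1 g DC step
takes roughly 12 s to decay below 1 mg through the 8-pole band-pass, so
"steady-state" assertions about static signals skip the first ~13 epochs.
In the pipeline this is immaterial because the first and last 5 s of every
condition are discarded and conditions last minutes.

## The statistical pipeline

The workflow mirrors the study design it reproduces: trim 5 s from each
end of every condition; truncate all participants of a condition to the
common minimum length (keeping the earliest epochs); map the conditions to
eight superordinate categories (lying, sitting, standing, adl, climbing
stairs, walking, jogging, cycling); then

1. **Descriptives** — mean and SD per (location, category, metric).
   Pooling all seconds is the default, matching the second-level
   resolution of the correlation analysis; a participant-means mode is
   available because summary tables in this literature sometimes average
   within person first. Sample SD (n − 1) throughout.
2. **Between-person variance** — participant means first, then the SD
   across participants per cell, plus the per-location average of those
   SDs used to rank wearing sites by between-person spread.
3. **Correlations** — Pearson r over pooled seconds for all 276 pairs of
   the 24 (metric, location) series, aligned by (participant, condition,
   second). Misalignment is a hard error, never silent dropping.
   Zero-variance series yield missing entries (with a warning), not zeros.
4. **Conversion models** — OLS `target = slope * source + intercept` per
   pair, with r² tied to the matrix entry to 1e-12 by construction.
5. **Cut-points** — for each (metric, location), thresholds between
   adjacent intensity zones (default: sedentary = lying + sitting, light =
   standing + adl, moderate = climbing stairs + walking + cycling,
   vigorous = jogging) maximize Youden's J over pooled seconds. This
   ROC-based calibration is the field-standard approach and is labelled an
   approximation of the original supplementary procedure, which is not
   redistributed. Boundaries with J below 0.1 are flagged unreliable;
   non-increasing thresholds across boundaries trigger a warning rather
   than silent reordering.

Determinism is a contract: identical cohort input gives bit-identical
tables, `run_end_to_end()` writes byte-identical CSVs for identical
(config, seed), and the run report records every resolved parameter.

## The packaged reference tables

The published category means/SDs (6 locations x 8 categories x 4 metrics)
and the lower triangle of the published 24 x 24 correlation matrix ship as
plain CSV resources, mirrored to a symmetric matrix with unit diagonal on
load. Query helpers recompute the headline comparability numbers:

```{r reference}
ref <- reference_tables()
within_metric_between_location_mean_r(ref, "CPM", digits = 2)
within_metric_between_location_mean_r(ref, c("MAI", "ENMO", "MAD"), digits = 1)
extreme_pair(ref, "within_metric_between_location", "min")
activity_ratio(ref, "thigh", "CPM", "jogging", "cycling", digits = 1)
```

Presentation rounding is half-up at the printed precision (plain `round()`
is half-even and disagrees with typeset tables); stored values are the
printed two-decimal numbers themselves. Ties at that precision are real:
five between-metric pairs share the maximum of 0.98, and `extreme_pair()`
returns all of them. One internal inconsistency of the printed record is
preserved deliberately: the stored matrix contains a chest ENMO–CPM entry
of 0.81, smaller than the chest MAD–CPM value of 0.83 that the
accompanying text singles out as the between-metric minimum; the arg-min
search reports 0.81 and `lookup_r()` still returns the 0.83 entry.

## The synthetic cohort generator

The generator emulates the *statistical structure* the analysis assumes,
not biomechanics. Each condition contributes, per location,

$$a(t) = g \cdot 1\,\mathrm{g} + m \cdot A \sum_k w_k \sin(2\pi k f t + \varphi_k)\,u + \varepsilon(t),$$

with `g` a posture-dependent unit gravity orientation, `u` a fixed
movement axis mixing a gravity-aligned (0.6) and an orthogonal (0.8)
component so that amplitude changes move both MAD and ENMO, harmonics
`w = {1: 1.0, 2: 0.4}`, uniform phases shared across locations within a
(participant, condition) — one underlying movement seen at several
attachment sites — and white Gaussian noise (8 mg per axis, putting the
lying-still MAD floor near 6 mg). Between-person variability is one
lognormal amplitude multiplier per (participant, category) with unit mean
and a per-category sigma (largest, 0.25, for jogging/adl/standing where
individual style differs most; 0.05 for lying).

The default profile set — 12 conditions spanning all eight categories,
durations 120–300 s, amplitudes per location — was written once so the
qualitative placement findings hold by construction: vigour orders MAD at
the lower-body sites, wrist exceeds thigh for household activity,
ankle/thigh exceed wrist for cycling, wrist standing rivals slow walking,
and wrist jogging shows the largest between-person spread. Fundamental
frequencies (0.3–2.8 Hz) place jogging partly outside the narrow count
band, which is what makes CPM correlate less and less linearly with the
amplitude metrics in pipeline output — the directional analogue of the
published CPM finding.

What the generator does **not** emulate: realistic gait waveforms, impact
transients, sensor drift or temperature effects, autocalibration error,
non-wear, or the actual magnitudes of the published category means. Tests
passing on synthetic data therefore demonstrate correctness of the
computations and reproduction of directional structure, not quantitative
agreement with any real cohort.

All randomness flows through reproducible substreams keyed by (seed,
participant, condition, location), so output is independent of iteration
order, and restricting the location or condition set leaves the shared
cells bit-identical.

## Problem sizes

The test suite exercises signals of 5–60 s and cohorts of 2–8
participants over 2–4 conditions at 30–40 s per condition (about 400
assertions in a few seconds). The analysis scripts under `analysis/` use
10 participants x 12 conditions x 6 locations at 60 s per condition
(~36,000 aligned seconds); `scripts/acceptance.R` uses 6 participants x 8
conditions x 6 locations at 40 s. These sizes are the package's working
defaults for a fast, fully reproducible demonstration; a cohort of the
published study's scale is one argument change
(`cohort_config(n_participants = 20, duration_s = NULL)`).

## Known limitations

* The count stage list follows a one-sentence published description plus
  field conventions; it is not a bit-exact emulation of any firmware, and
  absolute counts are larger than device output (comparative results are
  scale-invariant).
* Cut-point calibration approximates an unavailable supplementary
  procedure with ROC/Youden maximization.
* The linear conversion layer is deliberately restricted to OLS; no
  mixed-effects, Bland–Altman, or nonlinear/ML conversion is included.
* `read_raw_csv()` ingests delimited text only; proprietary device
  formats are out of scope.
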