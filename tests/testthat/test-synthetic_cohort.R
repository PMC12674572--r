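profiles <- activity_profiles()

test_that("profiles cover the eight categories with valid geometry", {
  cats <- vapply(profiles, `[[`, character(1), "category")
  expect_setequal(unique(cats), accel_categories())
  for (p in profiles) {
    for (g in p$gravity) expect_equal(sqrt(sum(g^2)), 1, tolerance = 1e-6)
    expect_true(p$duration_s > 10 + 1) # every condition survives trimming
  }
})

test_that("a motionless profile yields only the noise floor", {
  sig <- withr::with_seed(1, simulate_condition(profiles$lying_horizontal,
                                                "thigh", duration_s = 30))
  mad <- compute_mad(sig)
  expect_lt(mean(mad$values), 10)
  expect_gt(mean(mad$values), 0)
})

test_that("activity vigour orders the metric output by construction", {
  mad_mean <- function(cond, loc) {
    sig <- withr::with_seed(2, simulate_condition(profiles[[cond]], loc,
                                                  duration_s = 30))
    mean(compute_mad(sig)$values[6:25])
  }
  # full vigour chain at the lower-body sites; at the wrist, standing
  # fidgeting rivals slow walking (as in real wrist recordings), so only
  # the unambiguous comparisons are asserted there
  for (loc in c("thigh", "hip")) {
    expect_gt(mad_mean("jogging_8kmh", loc), mad_mean("walking_3.2kmh", loc))
    expect_gt(mad_mean("walking_3.2kmh", loc), mad_mean("standing", loc))
    expect_gt(mad_mean("standing", loc), mad_mean("lying_horizontal", loc))
  }
  expect_gt(mad_mean("jogging_8kmh", "wrist"), mad_mean("walking_3.2kmh", "wrist"))
  expect_gt(mad_mean("standing", "wrist"), mad_mean("sitting_upright", "wrist"))
  expect_gt(mad_mean("sitting_upright", "wrist"),
            mad_mean("lying_horizontal", "wrist"))
  # placement effects: wrist dominates for household activity, lower limbs
  # dominate for cycling
  expect_gt(mad_mean("tidying_up", "wrist"), mad_mean("tidying_up", "thigh"))
  expect_gt(mad_mean("cycling", "ankle"), mad_mean("cycling", "wrist"))
  expect_gt(mad_mean("cycling", "thigh"), mad_mean("cycling", "wrist"))
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- withr::with_seed(9, simulate_condition(profiles$walking_3.2kmh,
                                               "hip", duration_s = 20))
  s2 <- withr::with_seed(9, simulate_condition(profiles$walking_3.2kmh,
                                               "hip", duration_s = 20))
  expect_identical(s1$x, s2$x)
  expect_identical(s1$z, s2$z)
})

test_that("a non-unit gravity orientation is rejected", {
  bad <- profiles$standing
  bad$gravity$hip <- c(0, 0, 2)
  expect_error(withr::with_seed(1, simulate_condition(bad, "hip", 10)),
               "unit vector")
})

test_that("the cohort bundle has one signal per cell and a full manifest", {
  cfg <- cohort_config(n_participants = 2,
                       conditions = c("lying_horizontal", "standing",
                                      "walking_3.2kmh"),
                       locations = c("hip", "wrist"), duration_s = 30,
                       seed = 4)
  bundle <- simulate_cohort(cfg, profiles)
  expect_equal(nrow(bundle$manifest), 2 * 3 * 2)
  expect_equal(sum(lengths(unlist(bundle$signals, recursive = FALSE))), 12)
  expect_s3_class(bundle$signals$P01$standing$hip, "raw_signal")
  expect_true(all(c("multiplier", "amplitude_mg") %in%
                    names(bundle$manifest)))
  cfg_bad <- cohort_config(conditions = "handstand", seed = 1)
  expect_error(simulate_cohort(cfg_bad, profiles), "handstand")
})

test_that("zero between-person variability collapses participants", {
  cfg <- cohort_config(n_participants = 2, conditions = "walking_3.2kmh",
                       locations = "hip", between_person_sd = 0,
                       duration_s = 30, seed = 11)
  bundle <- simulate_cohort(cfg, profiles)
  expect_equal(unique(bundle$manifest$multiplier), 1)
})

test_that("cohort generation is reproducible and order-invariant", {
  cfg <- cohort_config(n_participants = 2,
                       conditions = c("lying_horizontal", "walking_3.2kmh"),
                       locations = c("hip", "thigh"), duration_s = 30,
                       seed = 5)
  c1 <- build_cohort(cfg, profiles)
  c2 <- build_cohort(cfg, profiles)
  expect_identical(c1, c2)
  # restricting the location set leaves the shared cells untouched
  cfg_hip <- cohort_config(n_participants = 2,
                           conditions = c("lying_horizontal", "walking_3.2kmh"),
                           locations = "hip", duration_s = 30, seed = 5)
  c3 <- build_cohort(cfg_hip, profiles)
  expect_equal(dplyr::filter(c1, location == "hip"), c3)
})

test_that("linear pairs carry their ground truth", {
  p0 <- linear_pair_cohort(2, 0, 0, 100, seed = 3)
  fit0 <- fit_conversion(p0$source, p0$target)
  expect_equal(fit0$slope, 2, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0, tolerance = 1e-9)
  pf <- linear_pair_cohort(0, 50, 5, 2000, seed = 8)
  fitf <- fit_conversion(pf$source, pf$target)
  expect_lt(abs(fitf$slope), 0.01)
  expect_lt(abs(fitf$r), 0.1)
  expect_error(linear_pair_cohort(1, 0, 1, 5, seed = 1), ">= 10")
})
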