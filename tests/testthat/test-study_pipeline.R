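test_that("condition trimming drops exactly trim_s epochs from each end", {
  s <- epoch_series(seq_len(120), "MAD", condition = "walking_3.2kmh")
  tr <- trim_condition(s)
  expect_length(tr$values, 110)
  expect_equal(tr$values[1], 6)
  expect_equal(tr$second_index[1], 5L)
  expect_length(trim_condition(epoch_series(1:11, "MAD"))$values, 1)
  short <- epoch_series(1:10, "MAD", condition = "standing")
  expect_error(trim_condition(short), "standing")
})

test_that("truncation to common length keeps earliest epochs and is idempotent", {
  grp <- lapply(c(110, 113, 111), function(n) epoch_series(seq_len(n), "MAI"))
  out <- truncate_to_common_length(grp)
  expect_equal(vapply(out, length, integer(1)), rep(110L, 3))
  expect_equal(out[[2]]$values, as.numeric(seq_len(110)))
  one <- truncate_to_common_length(grp[1])
  expect_equal(one[[1]]$values, grp[[1]]$values)
  again <- truncate_to_common_length(out)
  expect_identical(lapply(again, `[[`, "values"), lapply(out, `[[`, "values"))
  expect_error(truncate_to_common_length(list()), "empty")
})

test_that("conditions map onto the eight superordinate categories", {
  expect_equal(assign_categories("walking_3.2kmh"), "walking")
  expect_equal(assign_categories("cycling"), "cycling")
  expect_equal(assign_categories("tidying_up"), "adl")
  expect_equal(assign_categories(c("lying_horizontal", "jogging_8kmh")),
               c("lying", "jogging"))
  expect_error(assign_categories("moonwalking"), "moonwalking")
  expect_length(default_category_mapping(), 32)
  expect_true(all(default_category_mapping() %in% accel_categories()))
})

test_that("descriptives use the sample-sd convention and both pooling modes", {
  co <- toy_cohort()
  co$value <- 100
  d <- descriptive_table(co)
  expect_equal(unique(d$mean), 100)
  expect_equal(unique(d$sd), 0)
  two <- tibble::tibble(participant = "P01", location = "hip",
                        condition = "standing", category = "standing",
                        metric = "MAD", second = 0:1, value = c(90, 110))
  d2 <- descriptive_table(two)
  expect_equal(d2$mean, 100)
  expect_equal(d2$sd, sqrt(((90 - 100)^2 + (110 - 100)^2) / 1))
  # participant-mean mode collapses seconds first
  pm <- descriptive_table(toy_cohort(), mode = "participant_means")
  expect_true(all(pm$n == 2)) # two participants per cell
})

test_that("between-person variance is the sd of participant means", {
  co <- toy_cohort()
  co$value <- ifelse(co$participant == "P01", 10, 20)
  bp <- between_person_variance(co)
  expect_equal(unique(bp$cell_sd$between_person_sd),
               sqrt(((10 - 15)^2 + (20 - 15)^2) / 1))
  co$value <- 7
  bp0 <- between_person_variance(co)
  expect_equal(unique(bp0$cell_sd$between_person_sd), 0)
  one <- dplyr::filter(toy_cohort(), participant == "P01")
  expect_warning(between_person_variance(one), "single participant")
})

test_that("the pooled-seconds correlation matrix matches the covariance oracle", {
  co <- toy_cohort(n_sec = 100)
  cm <- correlation_matrix(co)
  expect_true(isSymmetric(unclass(cm)))
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
  expect_true(all(cm >= -1 & cm <= 1))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(co, series = paste(metric, location, sep = ".")),
    id_cols = c("participant", "condition", "second"),
    names_from = "series", values_from = "value")
  expect_equal(cm["MAD.hip", "ENMO.thigh"],
               naive_pearson(wide$MAD.hip, wide$ENMO.thigh), tolerance = 1e-12)
  # an exactly anti-correlated pair gives r = -1
  x <- as.numeric(1:30)
  co2 <- dplyr::bind_rows(
    tibble::tibble(participant = "P01", location = "hip",
                   condition = "standing", category = "standing",
                   metric = "MAD", second = 0:29, value = x),
    tibble::tibble(participant = "P01", location = "hip",
                   condition = "standing", category = "standing",
                   metric = "ENMO", second = 0:29, value = 100 - x))
  cm2 <- correlation_matrix(co2)
  expect_equal(cm2["MAD.hip", "ENMO.hip"], -1, tolerance = 1e-12)
})

test_that("zero-variance series are reported as missing, not zero", {
  co <- toy_cohort()
  co$value[co$metric == "ENMO" & co$location == "hip"] <- 3
  expect_warning(cm <- correlation_matrix(co), "zero-variance")
  expect_true(all(is.na(cm["ENMO.hip", ])))
  expect_false(anyNA(cm["MAD.hip", setdiff(colnames(cm), "ENMO.hip")]))
})

test_that("conversion models agree with the normal equations and Pearson r", {
  exact <- fit_conversion(1:10, 2 * (1:10))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-10)
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  off <- fit_conversion(1:10, (1:10) + 5)
  expect_equal(off$slope, 1, tolerance = 1e-12)
  expect_equal(off$intercept, 5, tolerance = 1e-10)
  withr::with_seed(7, {
    x <- runif(50, 0, 10)
    y <- 3 * x + 1 + rnorm(50, 0, 0.5)
  })
  fit <- fit_conversion(x, y)
  ne <- naive_ols(x, y)
  expect_equal(fit$slope, unname(ne["slope"]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(ne["intercept"]), tolerance = 1e-9)
  expect_equal(fit$r2, fit$r^2, tolerance = 1e-12)
  expect_error(fit_conversion(rep(1, 10), 1:10), "zero-variance")
  expect_error(fit_conversion(1:2, 1:2), "at least 3")
})

test_that("conversion r equals the correlation-matrix entry on the same data", {
  co <- toy_cohort(n_sec = 60)
  cm <- correlation_matrix(co)
  conv <- conversion_table(co)
  for (i in seq_len(nrow(conv))) {
    expect_equal(conv$r[i], cm[conv$source[i], conv$target[i]],
                 tolerance = 1e-12)
  }
  expect_equal(nrow(conv), choose(4, 2)) # 4 series -> 6 unordered pairs
})

test_that("positive rescaling of one series leaves its correlations unchanged", {
  co <- toy_cohort(n_sec = 80)
  cm1 <- correlation_matrix(co)
  co$value[co$metric == "MAD" & co$location == "thigh"] <-
    co$value[co$metric == "MAD" & co$location == "thigh"] * 37.5
  cm2 <- correlation_matrix(co)
  expect_equal(unclass(cm1), unclass(cm2), tolerance = 1e-12)
})

test_that("pipeline outputs are invariant to participant order", {
  co <- toy_cohort(n_sec = 40)
  shuffled <- co[order(rev(seq_len(nrow(co)))), ]
  expect_equal(descriptive_table(co), descriptive_table(shuffled))
  expect_equal(unclass(correlation_matrix(co)),
               unclass(correlation_matrix(shuffled)))
})

test_that("cut-points separate classes at the Youden optimum", {
  withr::with_seed(5, {
    lo <- runif(200, 0, 50)
    hi <- runif(200, 150, 300)
  })
  co <- tibble::tibble(
    participant = "P01", location = "thigh", metric = "MAD",
    condition = rep(c("sitting_upright", "walking_3.2kmh"), each = 200),
    category = rep(c("sitting", "walking"), each = 200),
    second = c(seq_along(lo), seq_along(hi)) - 1L,
    value = c(lo, hi))
  cuts <- calibrate_cutpoints(
    co, intensity_labels = c(sitting = "sedentary", walking = "active"))
  expect_equal(nrow(cuts), 1)
  expect_gt(cuts$threshold, 50)
  expect_lt(cuts$threshold, 150)
  expect_equal(cuts$sensitivity, 1)
  expect_equal(cuts$specificity, 1)
  expect_true(cuts$reliable)
})

test_that("unseparated classes are flagged unreliable", {
  withr::with_seed(6, v <- runif(400, 0, 100))
  co <- tibble::tibble(
    participant = "P01", location = "hip", metric = "ENMO",
    condition = rep(c("sitting_upright", "walking_3.2kmh"), each = 200),
    category = rep(c("sitting", "walking"), each = 200),
    second = rep(0:199, 2), value = v)
  cuts <- calibrate_cutpoints(
    co, intensity_labels = c(sitting = "sedentary", walking = "active"))
  expect_lt(cuts$j, 0.15)
  expect_false(cuts$reliable)
})
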