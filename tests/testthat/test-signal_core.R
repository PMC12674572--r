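fs <- 64

sine_signal <- function(amp, freq, dur = 10, fs = 64, dc = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  raw_signal(rep(0, length(t)), rep(0, length(t)), dc + amp * sin(2 * pi * freq * t),
             fs = fs)
}

test_that("vector magnitude matches geometry and the per-sample loop oracle", {
  n <- 64
  g <- raw_signal(rep(0, n), rep(0, n), rep(1, n))
  expect_equal(vector_magnitude(g), rep(1, n))
  tri <- raw_signal(rep(3e-3, n), rep(4e-3, n), rep(0, n))
  expect_equal(vector_magnitude(tri), rep(5e-3, n))
  withr::with_seed(11, {
    sig <- random_signal(64)
    expect_equal(vector_magnitude(sig), naive_vm(sig), tolerance = 1e-12)
  })
  expect_error(raw_signal(1:3, 1:3, 1:2), "identical length")
  expect_error(raw_signal(0, 0, 17), "16 g")
  expect_error(raw_signal(0, 0, NaN), "finite")
})

test_that("ENMO clips below gravity and matches the half-sine closed form", {
  expect_equal(compute_enmo(sine_signal(0, 0.5))$values, rep(0, 10))
  expect_equal(compute_enmo(sine_signal(0, 0.5, dc = 0.5))$values, rep(0, 10))
  # magnitude 1 + A sin(2 pi t): epoch mean of the positive part is A / pi
  e <- compute_enmo(sine_signal(0.3, 1))
  expect_equal(e$values, rep(1000 * 0.3 / pi, 10), tolerance = 0.005)
  expect_s3_class(e, "epoch_series")
  expect_length(e$values, 10)
})

test_that("MAD removes the static component and matches closed forms", {
  expect_equal(compute_mad(sine_signal(0, 1, dc = 0.8))$values, rep(0, 10))
  alt <- raw_signal(rep(0, 128), rep(0, 128), rep(c(0.9, 1.1), 64))
  expect_equal(compute_mad(alt)$values, rep(100, 2))
  m <- compute_mad(sine_signal(0.3, 1))
  expect_equal(m$values, rep(1000 * 2 * 0.3 / pi, 10), tolerance = 0.005)
})

test_that("MAI suppresses DC, passes in-band movement, attenuates out-of-band", {
  # the causal 8-pole band-pass needs ~12 s to bleed off a 1 g DC step
  dc <- compute_mai(sine_signal(0, 1, dur = 30))
  expect_true(all(dc$values[14:29] <= 1))
  expect_lt(dc$values[30], dc$values[2])
  in_band <- compute_mai(sine_signal(0.2, 2))
  out_band <- compute_mai(sine_signal(0.2, 20))
  expect_gt(mean(in_band$values[4:8]), 100)
  expect_lt(mean(out_band$values[4:8]), mean(in_band$values[4:8]))
  # numeric oracle: same stage list evaluated per sample via the raw
  # difference equation
  withr::with_seed(3, {
    sig <- random_signal(5 * fs)
    expect_equal(compute_mai(sig)$values, naive_mai(sig), tolerance = 1e-9)
  })
  # zero-phase variant stays non-negative and finite
  zp <- compute_mai(sine_signal(0.2, 2), filter_spec(phase = "zero_phase"))
  expect_true(all(zp$values >= 0))
  expect_error(compute_mai(sine_signal(0.2, 2), filter_spec(high_hz = 40)),
               "Nyquist")
  expect_error(compute_mai(sine_signal(0.2, 2), epoch_len = -1), "positive")
})

test_that("counts match the independently coded staged reference exactly", {
  n <- 60 * fs
  zero <- raw_signal(rep(0, n), rep(0, n), rep(0, n))
  expect_equal(compute_counts(zero)$values, rep(0, 60))
  grav <- raw_signal(rep(0, n), rep(0, n), rep(1, n))
  expect_equal(compute_counts(grav)$values[6:60], rep(0, 55))
  t <- (seq_len(n) - 1) / fs
  dyn <- raw_signal(0.5 * sin(2 * pi * 2 * t), rep(0, n), 1 + 0.3 * sin(2 * pi * 1 * t))
  got <- compute_counts(dyn)
  expect_identical(got$values, naive_counts_vm(dyn))
  ax <- attr(got, "axis_counts")
  expect_true(all(ax == floor(ax)))
  expect_true(all(got$values >= 0))
  expect_error(compute_counts(dyn, count_config(resample_hz = 128)),
               "upsampling")
})

test_that("counts-to-CPM rescaling follows both modes", {
  s <- epoch_series(c(10, 20, 30), "counts")
  expect_equal(counts_to_cpm(s, "per_condition"), 1200)
  expect_equal(counts_to_cpm(s, "per_second")$values, c(600, 1200, 1800))
  z <- epoch_series(c(0, 0), "counts")
  expect_equal(counts_to_cpm(z, "per_condition"), 0)
  expect_error(counts_to_cpm(epoch_series(numeric(0), "counts")), "empty")
})

test_that("ENMO and MAD are invariant under 3D rotations of the axes", {
  withr::with_seed(21, {
    for (i in 1:5) {
      sig <- random_signal(5 * fs)
      rot <- random_rotation()
      m <- rot %*% rbind(sig$x, sig$y, sig$z)
      rsig <- raw_signal(m[1, ], m[2, ], m[3, ])
      expect_equal(compute_enmo(rsig)$values, compute_enmo(sig)$values,
                   tolerance = 1e-12)
      expect_equal(compute_mad(rsig)$values, compute_mad(sig)$values,
                   tolerance = 1e-12)
    }
  })
})

test_that("dynamic-amplitude scaling follows the closed-form covariances", {
  base <- compute_mad(sine_signal(0.1, 1))$values
  scaled <- compute_mad(sine_signal(0.3, 1))$values
  expect_equal(scaled, 3 * base, tolerance = 1e-9)
  # MAI is linear in amplitude for an in-band sinusoid (no DC term, so no
  # step transient confounds the scaling)
  a1 <- compute_mai(sine_signal(0.1, 2, dc = 0))$values[4:8]
  a3 <- compute_mai(sine_signal(0.3, 2, dc = 0))$values[4:8]
  expect_equal(a3, 3 * a1, tolerance = 1e-6)
})

test_that("every vectorized metric equals its naive loop on random signals", {
  withr::with_seed(99, {
    for (i in 1:3) {
      sig <- random_signal(5 * fs, scale = 0.4)
      expect_equal(compute_enmo(sig)$values, naive_enmo(sig), tolerance = 1e-9)
      expect_equal(compute_mad(sig)$values, naive_mad(sig), tolerance = 1e-9)
      expect_equal(compute_mai(sig)$values, naive_mai(sig), tolerance = 1e-9)
      expect_identical(compute_counts(sig)$values, naive_counts_vm(sig))
    }
  })
})
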