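# Independent brute-force oracles: per-sample scalar loops kept deliberately
# naive so they share no code path with the vectorized implementations.

naive_vm <- function(sig) {
  out <- numeric(sig$n)
  for (i in seq_len(sig$n)) {
    out[i] <- sqrt(sig$x[i]^2 + sig$y[i]^2 + sig$z[i]^2)
  }
  out
}

naive_epoch_means <- function(v, spe) {
  n_ep <- length(v) %/% spe
  out <- numeric(n_ep)
  for (k in seq_len(n_ep)) {
    acc <- 0
    for (j in seq_len(spe)) acc <- acc + v[(k - 1) * spe + j]
    out[k] <- acc / spe
  }
  out
}

naive_enmo <- function(sig, epoch_len = 1) {
  r <- naive_vm(sig)
  for (i in seq_along(r)) r[i] <- max(r[i] - 1, 0)
  naive_epoch_means(r, sig$fs * epoch_len) * 1000
}

naive_mad <- function(sig, epoch_len = 1) {
  r <- naive_vm(sig)
  spe <- sig$fs * epoch_len
  n_ep <- length(r) %/% spe
  out <- numeric(n_ep)
  for (k in seq_len(n_ep)) {
    w <- r[((k - 1) * spe + 1):(k * spe)]
    mu <- sum(w) / spe
    out[k] <- sum(abs(w - mu)) / spe
  }
  out * 1000
}

# direct-form-II-transposed difference equation, one sample at a time
naive_iir <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    acc <- 0
    for (j in seq_len(nb)) {
      if (i - j + 1 >= 1) acc <- acc + b[j] * x[i - j + 1]
    }
    if (na > 1) {
      for (j in 2:na) {
        if (i - j + 1 >= 1) acc <- acc - a[j] * y[i - j + 1]
      }
    }
    y[i] <- acc
  }
  y
}

naive_mai <- function(sig, filt = filter_spec(), epoch_len = 1) {
  bf <- signal::butter(filt$order, c(filt$low_hz, filt$high_hz) / (sig$fs / 2),
                       type = "pass")
  fx <- naive_iir(bf$b, bf$a, sig$x)
  fy <- naive_iir(bf$b, bf$a, sig$y)
  fz <- naive_iir(bf$b, bf$a, sig$z)
  r <- sqrt(fx^2 + fy^2 + fz^2)
  naive_epoch_means(r, sig$fs * epoch_len) * 1000
}

# staged count reference: same published stage list, coded sample-by-sample
naive_counts_vm <- function(sig, cfg = count_config(), epoch_len = 1) {
  lsb <- cfg$peak_g / 2^(cfg$adc_bits - 1)
  axis_counts <- function(v) {
    if (cfg$resample_hz < sig$fs) {
      p <- cfg$resample_hz * 1000; q <- sig$fs * 1000
      g <- function(a, b) if (b == 0) a else g(b, a %% b)
      d <- g(p, q)
      n_out <- floor(length(v) * (p / d) / (q / d))
      v <- as.numeric(signal::resample(v, p / d, q / d))[seq_len(n_out)]
    }
    bf <- signal::butter(cfg$band_order,
                         c(cfg$band_low_hz, cfg$band_high_hz) /
                           (cfg$resample_hz / 2), type = "pass")
    v <- naive_iir(bf$b, bf$a, v)
    spe <- cfg$resample_hz * epoch_len
    n_ep <- length(v) %/% spe
    out <- integer(n_ep)
    for (k in seq_len(n_ep)) {
      acc <- 0L
      for (j in seq_len(spe)) {
        s <- v[(k - 1) * spe + j]
        if (s > cfg$peak_g) s <- cfg$peak_g
        if (s < -cfg$peak_g) s <- -cfg$peak_g
        s <- abs(s)
        if (s < cfg$deadband_g) s <- 0
        lev <- floor(s / lsb)
        acc <- acc + max(lev - cfg$deadband_levels, 0)
      }
      out[k] <- acc
    }
    out
  }
  cx <- axis_counts(sig$x); cy <- axis_counts(sig$y); cz <- axis_counts(sig$z)
  sqrt(cx^2 + cy^2 + cz^2)
}

# textbook two-pass Pearson correlation
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# closed-form normal equations for simple OLS
naive_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

random_signal <- function(n = 320, fs = 64, scale = 0.5) {
  raw_signal(stats::rnorm(n, 0, scale), stats::rnorm(n, 0, scale),
             1 + stats::rnorm(n, 0, scale), fs = fs)
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  qr.Q(qr(m))
}

# tiny hand-built cohort table for pipeline tests
toy_cohort <- function(n_sec = 50, seed = 42) {
  withr::with_seed(seed, {
    grid <- expand.grid(participant = c("P01", "P02"),
                        condition = c("walking_3.2kmh", "lying_horizontal"),
                        location = c("hip", "thigh"),
                        metric = c("MAD", "ENMO"),
                        second = 0:(n_sec - 1), stringsAsFactors = FALSE)
    base <- ifelse(grid$condition == "walking_3.2kmh", 250, 5)
    grid$value <- pmax(base * ifelse(grid$metric == "ENMO", 0.8, 1) +
                         stats::rnorm(nrow(grid), 0, 10), 0)
    grid$category <- ifelse(grid$condition == "walking_3.2kmh",
                            "walking", "lying")
    tibble::as_tibble(grid[c("participant", "location", "condition",
                             "category", "metric", "second", "value")])
  })
}
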