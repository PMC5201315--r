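test_that("epoching arithmetic, truncation and boundaries", {
  fs <- 256
  ep <- epoch_signal(rnorm(300 * fs), fs)
  expect_length(ep, 5)
  expect_true(all(lengths(ep) == 15360))
  expect_length(epoch_signal(rnorm(119 * fs), fs), 1)
  expect_length(epoch_signal(rnorm(60 * fs), fs), 1)
  expect_error(epoch_signal(rnorm(59 * fs), fs), "shorter")
})

test_that("band power of a pure tone lands in its band with Parseval scale", {
  fs <- 256
  t <- seq_len(60 * fs) / fs
  for (A in c(1, 2.5)) {
    x <- A * sin(2 * pi * 10 * t)
    expect_equal(band_power(x, fs, eeg_band("alpha")), A^2 / 2,
                 tolerance = 0.05)
    expect_lt(band_power(x, fs, eeg_band("beta")), 1e-10)
  }
  expect_equal(band_power(rep(0, 60 * fs), fs, eeg_band("delta")), 0)
  expect_error(band_power(rnorm(60 * fs), fs, band_def("x", 100, 140)),
               "Nyquist")
})

test_that("white-noise band power is proportional to bandwidth", {
  set.seed(42)
  fs <- 128
  x <- rnorm(600 * fs)
  psd <- welch_psd(x, fs)
  p <- vapply(c("delta", "theta", "alpha", "beta"), function(b) {
    bd <- eeg_band(b)
    band_power(x, fs, bd, psd = psd) / (bd$hi_hz - bd$lo_hz)
  }, numeric(1))
  expect_true(all(abs(p / mean(p) - 1) < 0.10))
})

test_that("band power is sign-invariant and quadratic in amplitude", {
  set.seed(1)
  fs <- 128
  x <- rnorm(60 * fs)
  b <- eeg_band("alpha")
  expect_equal(band_power(-x, fs, b), band_power(x, fs, b))
  expect_equal(band_power(3 * x, fs, b), 9 * band_power(x, fs, b),
               tolerance = 1e-10)
})

test_that("band powers of the named bands nearly partition the broadband range", {
  s <- short_session()
  fs <- s$fs
  epochs <- epoch_signal(s$eeg, fs)[c(1, 40, 100)]
  for (ep in epochs) {
    psd <- welch_psd(ep, fs)
    tot <- sum(vapply(c("alpha", "beta", "delta", "theta"), function(b)
      band_power(ep, fs, eeg_band(b), psd = psd), numeric(1)))
    eeg <- band_power(ep, fs, eeg_band("eeg"), psd = psd)
    expect_lte(tot, eeg * 1.05)
  }
})

test_that("ratio features are exact arithmetic", {
  expect_equal(unname(ratio_features(2, 1, 1)), c(2, 3))
  expect_equal(unname(ratio_features(0, 5, 0)), c(0, 0))
  expect_equal(unname(ratio_features(4, 4, 1))[1], 1)
  expect_error(ratio_features(1, 0, 1), "positive")
})

test_that("rrsd is the population SD and matches a two-pass oracle", {
  expect_equal(rrsd(c(0.8, 0.8, 0.8)), 0)
  expect_equal(rrsd(c(0.7, 0.9)), 0.1)
  set.seed(3)
  for (i in 1:20) {
    rr <- runif(50, 0.6, 1.1)
    mu <- sum(rr) / length(rr)
    oracle <- sqrt(sum((rr - mu)^2) / length(rr))
    expect_equal(rrsd(rr), oracle, tolerance = 1e-12)
    expect_equal(rrsd(rr + 0.3), rrsd(rr), tolerance = 1e-12)
  }
  expect_error(rrsd(0.8), "at least 2")
})

test_that("heart rate is 60 over the mean RR interval", {
  expect_equal(heart_rate(rep(1, 10)), 60)
  expect_equal(heart_rate(rep(0.5, 4)), 120)
  expect_equal(heart_rate(c(0.8, 1.0)), 60 / 0.9)
  expect_error(heart_rate(numeric(0)), "empty")
})

test_that("Haar denoising: identity cases and noise reduction", {
  expect_equal(haar_denoise(rep(2.5, 64), level = 3), rep(2.5, 64))
  set.seed(8)
  x <- rnorm(256)
  expect_equal(haar_denoise(x, level = 4, threshold = 0), x,
               tolerance = 1e-12)
  step <- rep(c(0, 4), each = 128)
  noisy <- step + rnorm(256, 0, 0.3)
  den <- haar_denoise(noisy, level = 5)
  expect_lt(sum((den - step)^2), sum((noisy - step)^2))
  expect_length(den, 256)
  expect_error(haar_denoise(rnorm(8), level = 5), "too short")
})

test_that("feature table has one row per reaction-time sample and is order-invariant", {
  s <- short_session()
  tab <- build_feature_table(s)
  expect_equal(nrow(tab), nrow(s$rt))
  expect_true(all(tab$level %in% 1:3))
  psd_cols <- c("alpha_psd", "beta_psd", "delta_psd", "eeg_psd",
                "alpha_over_beta_psd", "alpha_theta_over_beta",
                "alpha_over_beta")
  expect_true(all(as.matrix(tab[psd_cols]) >= 0))
  expect_true(all(tab$heart_rate_bpm > 0))
  shuffled <- s
  set.seed(2)
  shuffled$rt <- s$rt[sample(nrow(s$rt)), ]
  expect_equal(build_feature_table(shuffled), tab)
})

test_that("noise-free generator round-trips its alpha/beta targets", {
  cfg <- sim_config(duration_min = 120, period_bounds = c(30, 80),
                    band_jitter_sd = 0, ratio_jitter_sd = 0,
                    level2_flip_prob = 0, rng_seed = 6L)
  s <- simulate_session(cfg)
  tab <- build_feature_table(s)
  m <- tapply(tab$alpha_over_beta, tab$level, mean)
  expect_equal(as.vector(m), cfg$alpha_beta_by_level, tolerance = 0.10)
})

test_that("early or unalignable samples are dropped with a warning", {
  s <- short_session()
  early <- s
  early$rt <- rbind(data.frame(time_min = 0.5, rt_s = 1.2, level = 1),
                    s$rt)
  expect_warning(tab <- build_feature_table(early), "dropped")
  expect_equal(nrow(tab), nrow(s$rt))
})

test_that("feature table CSV round-trips", {
  s <- short_session()
  tab <- build_feature_table(s, session_id = 3L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, p)
  tab2 <- read_feature_table(p)
  expect_equal(as.data.frame(tab2), as.data.frame(tab), tolerance = 1e-12)
})
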