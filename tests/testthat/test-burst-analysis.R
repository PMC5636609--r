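test_that("conditioning band-passes, rectifies, and integrates", {
  fs <- 4000
  zero <- trace(numeric(2 * fs), fs, "neurogram_cnx")
  out <- condition_neurogram(zero)
  expect_true(all(abs(out$samples) < 1e-9))
  expect_true(all(out$samples >= -1e-12))
  # band selectivity: 50 Hz (below band) attenuated >= 20 dB vs 300 Hz
  t <- seq(0, 2, length.out = 2 * fs)
  lo <- trace(sin(2 * pi * 50 * t), fs, "neurogram_cnx")
  hi <- trace(sin(2 * pi * 300 * t), fs, "neurogram_cnx")
  m_lo <- mean(condition_neurogram(lo)$samples[fs:(2 * fs)])
  m_hi <- mean(condition_neurogram(hi)$samples[fs:(2 * fs)])
  expect_lt(m_lo / m_hi, 10^(-20 / 20))
  # parameter errors
  expect_error(condition_neurogram(trace(rnorm(1000), 1000, "neurogram_cnx")),
               class = "synscale_usage_error")
  expect_error(condition_neurogram(zero, conditioning_config(band = c(100, 2500))),
               class = "synscale_parameter_error")
})

test_that("leaky integrator reaches 63% of plateau after one time constant", {
  fs <- 2000
  # average the stochastic step response of rectified white noise over
  # many realizations against the closed-form first-order response
  set.seed(12)
  at_tau <- replicate(200, {
    x <- c(numeric(fs / 2), abs(rnorm(fs)))
    y <- leaky_integrate(x, fs, 60)
    plateau <- mean(y[(fs / 2 + round(0.4 * fs)):(fs / 2 + fs - 1)])
    y[fs / 2 + round(0.060 * fs)] / plateau
  })
  expect_equal(mean(at_tau), 1 - exp(-1), tolerance = 0.05)
})

test_that("burst metrics measure a half-sine exactly", {
  fs <- 1000
  d <- 1; h <- 3; b <- 1
  x <- rep(b, 10 * fs)
  i0 <- 5 * fs
  tt <- seq(0, d, length.out = d * fs)
  x[i0 + seq_along(tt) - 1] <- b + h * sin(pi * tt / d)
  tr <- trace(x, fs, "neurogram_cnx")
  m <- burst_metrics(c(5, 6), tr)
  expect_equal(m$amplitude, 3, tolerance = 0.02)       # peak-smoothing ~0.4%
  expect_equal(m$area, 2 * h / pi * d, tolerance = 0.02)
  expect_equal(m$baseline, 1, tolerance = 1e-6)
  # zero-height window
  m0 <- burst_metrics(c(1, 2), tr)
  expect_equal(m0$amplitude, 0, tolerance = 1e-9)
  expect_equal(m0$area, 0, tolerance = 1e-9)
  # window at trace start: baseline from available prefix, flagged
  m_start <- burst_metrics(c(0.2, 1.2), tr)
  expect_true(m_start$baseline_clipped)
})

test_that("burst metrics are invariant to a constant trace offset", {
  ng <- generate_neurogram(epochs = default_epochs(120), seed = 17)
  b1 <- detect_bursts(ng$cnx, ng$snii)
  up <- ng$cnx; up$samples <- up$samples + 5
  up2 <- ng$snii; up2$samples <- up2$samples + 5
  b2 <- detect_bursts(up, up2)
  expect_equal(nrow(b2), nrow(b1))
  expect_equal(b2$amplitude, b1$amplitude, tolerance = 1e-9)
  expect_equal(b2$area, b1$area, tolerance = 1e-9)
})

test_that("noiseless coincident bursts are all found at the right times", {
  ng <- generate_neurogram(burst_rate_per_min = 6,
                           epochs = default_epochs(100, c(1, 1, 1), c(1, 1, 1)),
                           channel_lag = 0, noise_sd = 0, seed = 2)
  b <- detect_bursts(ng$cnx, ng$snii)
  cnx <- b[b$channel == "neurogram_cnx", ]
  expect_equal(nrow(cnx), nrow(ng$truth$bursts))
  expect_true(all(cnx$coincident))
  # onsets near truth (exit-threshold crossing is within the rise)
  expect_true(all(vapply(cnx$onset_s, function(o)
    min(abs(ng$truth$bursts$onset_s - o)) < 0.2, logical(1))))
})

test_that("single-channel bursts are never counted as respiratory", {
  ng <- generate_neurogram(epochs = default_epochs(200), n_extra_cnx = 2,
                           seed = 23)
  b <- detect_bursts(ng$cnx, ng$snii)
  cnx <- b[b$channel == "neurogram_cnx", ]
  extras <- ng$truth$bursts[!ng$truth$bursts$coincident, ]
  for (t0 in extras$onset_s) {
    hit <- which(abs(cnx$onset_s - t0) < 0.3)
    expect_true(length(hit) >= 1)
    expect_false(any(cnx$coincident[hit]))
  }
})

test_that("coincidence is symmetric in the channel-lag sign", {
  n_resp <- function(lag) {
    ng <- generate_neurogram(epochs = default_epochs(150),
                             channel_lag = lag, seed = 41)
    b <- detect_bursts(ng$cnx, ng$snii)
    sum(b$coincident[b$channel == "neurogram_cnx"])
  }
  expect_equal(n_resp(0.15), n_resp(-0.15))
})

test_that("overlong envelopes are rejected by the duration window", {
  fs <- 100
  x <- rep(1, 300 * fs) + rnorm(300 * fs, 0, 0.02)
  tt <- seq(0, 5, length.out = 5 * fs)
  x[100 * fs + seq_along(tt)] <- x[100 * fs + seq_along(tt)] + 3 * sin(pi * tt / 5)
  cnx <- trace(x, fs, "neurogram_cnx")
  b <- synscale:::detect_bursts_channel(cnx, burst_config())
  expect_equal(nrow(b), 0L)
})

test_that("epoch comparison reports percent of baseline", {
  ng <- generate_neurogram(seed = 19)
  ec <- epoch_compare(detect_bursts(ng$cnx, ng$snii), ng$truth$epochs)
  expect_equal(ec$pct_frequency[ec$epoch == "baseline"], 100)
  expect_equal(ec$pct_amplitude[ec$epoch == "baseline"], 100)
  expect_equal(ec$pct_amplitude[ec$epoch == "drug"], 60, tolerance = 0.1)
  expect_equal(ec$pct_frequency[ec$epoch == "drug"], 20, tolerance = 0.35)
  expect_error(epoch_compare(detect_bursts(ng$cnx, ng$snii),
                             data.frame(epoch = "drug", start_s = 0,
                                        end_s = 600)),
               class = "synscale_usage_error")
})

test_that("non-overlapping time bases are refused", {
  a <- trace(rnorm(1000), 100, "neurogram_cnx", t0 = 0)
  b <- trace(rnorm(1000), 100, "neurogram_snii", t0 = 100)
  expect_error(detect_bursts(a, b), class = "synscale_usage_error")
})
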