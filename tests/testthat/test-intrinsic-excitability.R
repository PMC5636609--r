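test_that("input resistance recovers the generating value", {
  fam <- generate_fi_sweeps(lif_params(R_in = 100, tau_m = 10))
  expect_equal(input_resistance(fam), 100, tolerance = 0.005)
  fam250 <- generate_fi_sweeps(lif_params(R_in = 250, tau_m = 20))
  expect_equal(input_resistance(fam250), 250, tolerance = 0.02)
  # by-hand slope: deflections {-15,-10,-5,0} mV at {-150,-100,-50,0} pA
  expect_equal(unname(coef(lm(c(-15, -10, -5, 0) ~ c(-150, -100, -50, 0)))[2]) * 1000,
               100)
  # missing negative steps -> usage error
  fam_pos <- fam
  fam_pos$sweeps <- fam$sweeps[fam$sweeps$current_pA > 0, ]
  expect_error(input_resistance(fam_pos), class = "synscale_usage_error")
})

test_that("input resistance is invariant to a constant voltage offset", {
  fam <- generate_fi_sweeps(lif_params(R_in = 150, tau_m = 10))
  shifted <- fam
  shifted$sweeps$trace <- lapply(shifted$sweeps$trace, function(tr) {
    tr$samples <- tr$samples + 23.7
    tr
  })
  expect_equal(input_resistance(shifted), input_resistance(fam),
               tolerance = 1e-10)
})

test_that("spike detection counts and flags correctly", {
  fam <- generate_fi_sweeps(lif_params(R_in = 100, tau_m = 10),
                            steps = c(-50, 100, 500))
  expect_equal(nrow(detect_spikes(fam$sweeps$trace[[1]])), 0L)
  expect_equal(nrow(detect_spikes(fam$sweeps$trace[[2]])), 0L)  # below rheobase
  sp <- detect_spikes(fam$sweeps$trace[[3]])
  expect_gt(nrow(sp), 0L)
  expect_false(any(sp$below_qc))
  # 40 mV spikes: detected but flagged below the QC criterion
  fs <- 10000
  v <- rep(-60, 2 * fs)
  for (i in seq(0.5, 1.5, by = 0.1)) v[round(i * fs)] <- -20  # peak -20, base -60
  small <- trace(v, fs, "cclamp_voltage")
  sp40 <- detect_spikes(small, threshold = -30)
  expect_equal(nrow(sp40), 11L)
  expect_true(all(sp40$below_qc))
})

test_that("F-I gain matches the analytic LIF oracle within 5%", {
  for (prm in list(c(100, 10), c(250, 20))) {
    nrn <- lif_params(R_in = prm[1], tau_m = prm[2])
    fam <- generate_fi_sweeps(nrn)
    fr <- fi_gain(fam)
    oracle <- lif_gain_oracle(prm[1], prm[2], nrn$V_rest, nrn$V_thresh,
                              nrn$t_ref, seq(0, 1000, by = 50))
    expect_lt(abs(fr$gain - oracle) / oracle, 0.05)
    expect_equal(fr$rheobase,
                 min(fam$sweeps$current_pA[lif_rate(fam$sweeps$current_pA, nrn) > 0 &
                                             fam$sweeps$current_pA >= 0]))
  }
})

test_that("exactly linear rates give the exact gain; silence gives zero", {
  mk <- function(rates, currents) {
    # build sweeps with the requested spike counts as stereotyped spikes
    fs <- 5000
    sweeps <- tibble::tibble(
      current_pA = currents,
      trace = lapply(rates, function(r) {
        v <- rep(-60, fs)          # 1 s sweep, step window 0.2-0.7 s
        n <- round(r * 0.5)
        if (n > 0) {
          at <- round(seq(0.21, 0.69, length.out = n) * fs)
          v[at] <- 10
        }
        trace(v, fs, "cclamp_voltage")
      }))
    structure(list(sweeps = sweeps, step_window = c(0.2, 0.7)),
              class = "step_family")
  }
  currents <- seq(0, 1000, by = 100)
  fam <- mk(0.1 * currents, currents)
  fr <- fi_gain(fam)
  expect_equal(fr$gain, 0.1, tolerance = 1e-10)
  silent <- fi_gain(mk(rep(0, 11), currents))
  expect_equal(silent$gain, 0)
  expect_true(silent$zero_activity)
})

test_that("gain depends on spike times, not spike waveform", {
  fs <- 10000
  mkfam <- function(peak) {
    sweeps <- tibble::tibble(
      current_pA = c(0, 500, 1000),
      trace = lapply(c(0, 10, 20), function(n) {
        v <- rep(-60, fs)
        if (n > 0) {
          at <- round(seq(0.22, 0.68, length.out = n) * fs)
          for (k in 0:2) v[at + k] <- peak - k * 10  # waveform differs
        }
        trace(v, fs, "cclamp_voltage")
      }))
    structure(list(sweeps = sweeps, step_window = c(0.2, 0.7)),
              class = "step_family")
  }
  expect_equal(fi_gain(mkfam(10))$gain, fi_gain(mkfam(40))$gain,
               tolerance = 1e-12)
})

test_that("slope comparison detects forced gain differences and not
           identical groups", {
  mk_rates <- function(gain, noise, seed) {
    set.seed(seed)
    x <- seq(0, 1000, by = 50)
    structure(list(rates = tibble::tibble(current_pA = x,
                                          rate_hz = pmax(0, gain * x +
                                                           rnorm(length(x), 0, noise))),
                   gain = gain, rheobase = 100, zero_activity = FALSE),
              class = "fi_result")
  }
  a <- lapply(1:6, function(i) mk_rates(0.10, 2, i))
  b2 <- lapply(1:6, function(i) mk_rates(0.20, 2, 100 + i))
  cmp <- compare_fi_slopes(a, b2)
  expect_lt(cmp$ancova$p, 1e-6)
  # identical data in both groups: interaction F ~ 0
  cmp0 <- compare_fi_slopes(a, a, labels = c("g1", "g2"))
  expect_lt(cmp0$ancova$statistic, 1e-10)
  expect_error(compare_fi_slopes(a[1], b2), class = "synscale_usage_error")
})

test_that("resting potential applies the junction correction exactly once", {
  fs <- 10000
  tr <- trace(rep(-45.13, fs), fs, "cclamp_voltage")
  v <- resting_potential(tr)
  expect_equal(as.numeric(v), -57.13)
  expect_equal(attr(v, "ljp_applied"), -12)
  expect_equal(as.numeric(resting_potential(tr, ljp = 0)), -45.13)
  flat <- trace(rep(-50, fs), fs, "cclamp_voltage")
  expect_equal(as.numeric(resting_potential(flat)), -62)
  corrected <- trace(rep(-57, fs), fs, "cclamp_voltage",
                     metadata = list(ljp_corrected = TRUE))
  expect_error(resting_potential(corrected), class = "synscale_usage_error")
  expect_error(resting_potential(trace(rep(-50, 100), 10000, "cclamp_voltage")),
               class = "synscale_usage_error")
})
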