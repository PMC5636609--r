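test_that("a single clean event is measured accurately", {
  g <- noiseless_events_trace(onsets = 2, amps = 20)
  ev <- detect_events(g$trace)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude_pA, 20, tolerance = 0.01)   # 20 +/- 0.2 pA
  # rise time ~ kernel time to peak: t* = ln(tau_d/tau_r)*tau_r*tau_d/(tau_d-tau_r)
  t_peak <- log(8 / 1) * 8 / 7
  expect_equal(ev$rise_ms, t_peak, tolerance = 0.35)
  expect_equal(ev$onset_s, 2, tolerance = 2e-3)
  expect_gt(ev$charge_pAms, 0)
})

test_that("events below the rejection threshold are discarded", {
  g <- noiseless_events_trace(onsets = c(1, 2, 3), amps = c(5, 5, 5))
  expect_equal(nrow(detect_events(g$trace)), 0L)
  # and just above it, kept
  g2 <- noiseless_events_trace(onsets = c(1, 2), amps = c(8, 30))
  ev2 <- detect_events(g2$trace)
  expect_equal(nrow(ev2), 2L)
  expect_true(all(ev2$amplitude_pA >= 7.5))
})

test_that("wrong channel role and too-short traces are usage errors", {
  tr <- trace(rnorm(5000), 1000, "cclamp_voltage")
  expect_error(detect_events(tr), class = "synscale_usage_error")
  short <- trace(rnorm(400), 1000, "vclamp_current")
  expect_error(detect_events(short), class = "synscale_usage_error")
})

test_that("doubling all deviations doubles amplitudes and charges", {
  g <- noiseless_events_trace(onsets = c(1, 2.5, 4), amps = c(10, 18, 30))
  ev1 <- detect_events(g$trace)
  doubled <- g$trace
  doubled$samples <- doubled$samples * 2
  ev2 <- detect_events(doubled)
  expect_equal(nrow(ev2), nrow(ev1))
  expect_equal(ev2$amplitude_pA, 2 * ev1$amplitude_pA, tolerance = 1e-10)
  expect_equal(ev2$charge_pAms, 2 * ev1$charge_pAms, tolerance = 1e-10)
})

test_that("pure-noise traces produce under one false event per minute", {
  fp <- vapply(1:25, function(s) {
    p <- mepsc_params(duration = 60, sampling_rate = 5000, event_rate = 0,
                      noise_sd = 2, seed = 1000 + s)
    nrow(detect_events(generate_mepsc_trace(p)$trace))
  }, numeric(1))
  expect_lt(mean(fp), 1)
})

test_that("detection recovers ground truth on noisy synthetic traces", {
  res <- vapply(1:25, function(s) {
    set.seed(s)
    onsets <- sort(runif(30, 0.5, 19.5))
    amps <- runif(30, 12, 40)
    p <- mepsc_params(duration = 20, sampling_rate = 10000, noise_sd = 2,
                      seed = NULL)
    g <- generate_mepsc_trace(p, forced_onsets = onsets,
                              forced_amplitudes = amps)
    ev <- detect_events(g$trace)
    matched <- vapply(onsets, function(o)
      any(abs(ev$onset_s - o) <= 0.002), logical(1))
    fp <- vapply(ev$onset_s, function(o)
      all(abs(onsets - o) > 0.002), logical(1))
    c(mean(matched), sum(fp) / length(onsets))
  }, numeric(2))
  expect_gt(mean(res[1, ]), 0.93)
  expect_lt(mean(res[2, ]), 0.05)
})

test_that("per-neuron summaries average the analysis window", {
  ev <- tibble::tibble(onset_s = c(10, 20), peak_s = c(10.003, 20.003),
                       amplitude_pA = c(10, 20), charge_pAms = c(80, 160),
                       rise_ms = c(2, 3), overlapped = c(FALSE, FALSE))
  rec <- summarize_neuron(ev, window = 60, neuron_id = "n1", group = "ctl")
  expect_equal(rec$mean_amplitude_pA, 15)
  expect_equal(rec$frequency_per_min, 2)
  expect_false(rec$no_events)
  # 48 events in 60 s -> 48 per minute
  ev48 <- tibble::tibble(onset_s = seq(0.5, 59.5, length.out = 48),
                         peak_s = seq(0.5, 59.5, length.out = 48) + 0.003,
                         amplitude_pA = rep(12, 48), charge_pAms = rep(90, 48),
                         rise_ms = rep(2.5, 48), overlapped = FALSE)
  expect_equal(summarize_neuron(ev48)$frequency_per_min, 48)
  # zero events: frequency 0, means NA, flagged - not an error
  none <- summarize_neuron(ev48[0, ])
  expect_equal(none$frequency_per_min, 0)
  expect_true(is.na(none$mean_amplitude_pA))
  expect_true(none$no_events)
})

test_that("recovered frequency and amplitude match the generator law", {
  # oracle: detectable rate = rate * P(amplitude >= threshold); mean
  # detected amplitude = E[A | A >= threshold] under the lognormal law
  p_above <- 1 - plnorm(7.5, log(18), 0.45)
  rate_th <- 0.8 * 60 * p_above
  mu <- log(18); s <- 0.45
  mean_above <- 18 * exp(s^2 / 2) *
    pnorm((mu + s^2 - log(7.5)) / s) / p_above
  res <- vapply(1:40, function(sd_) {
    p <- mepsc_params(duration = 60, sampling_rate = 5000, event_rate = 0.8,
                      noise_sd = 2, seed = 500 + sd_)
    g <- generate_mepsc_trace(p)
    ev <- detect_events(g$trace)
    rec <- summarize_neuron(ev)
    c(rec$frequency_per_min, rec$mean_amplitude_pA)
  }, numeric(2))
  se_f <- sd(res[1, ]) / sqrt(ncol(res))
  se_a <- sd(res[2, ]) / sqrt(ncol(res))
  expect_lt(abs(mean(res[1, ]) - rate_th), 3 * se_f + 1.5)
  expect_lt(abs(mean(res[2, ]) - mean_above), 3 * se_a + 0.3)
})

test_that("first_n_amplitudes takes the earliest events and flags shortfall", {
  ev <- tibble::tibble(onset_s = rev(seq_len(60)),
                       amplitude_pA = rev(seq_len(60)) + 100)
  out <- first_n_amplitudes(ev, 50)
  expect_length(out, 50)
  expect_equal(as.numeric(out), 101:150)  # earliest 50 after time sorting
  expect_false(attr(out, "shortfall"))
  out50 <- first_n_amplitudes(ev[1:50, ], 50)
  expect_false(attr(out50, "shortfall"))
  out30 <- first_n_amplitudes(ev[1:30, ], 50)
  expect_length(out30, 30)
  expect_true(attr(out30, "shortfall"))
})

test_that("QC filter enforces the recording-quality criteria", {
  rec <- tibble::tibble(
    V_rest_mV = c(-57, -57, -57, -40, -57),
    ap_amplitude_mV = c(70, 70, 70, 70, 40),
    Rs_start_MOhm = c(12, 12, 26, 12, 12),
    Rs_end_MOhm = c(13, 15, 26, 13, 13))
  out <- qc_filter(rec)
  expect_true(out$qc_pass[1])                       # -57 mV, 70 mV AP, 12->13
  expect_false(out$qc_pass[2])                      # 25% Rs rise
  expect_match(out$qc_reasons[2], "rs_drift")
  expect_false(out$qc_pass[3])                      # Rs 26 > 25
  expect_match(out$qc_reasons[3], "rs_high")
  expect_match(out$qc_reasons[4], "depolarized")
  expect_match(out$qc_reasons[5], "ap_small")
  # missing fields: explicit incomplete status, not a guess
  out_na <- qc_filter(tibble::tibble(V_rest_mV = NA_real_,
                                     ap_amplitude_mV = 70,
                                     Rs_start_MOhm = 12, Rs_end_MOhm = 13))
  expect_true(is.na(out_na$qc_pass))
  expect_equal(out_na$qc_reasons, "incomplete_qc")
  expect_error(qc_filter(tibble::tibble(V_rest_mV = -57)),
               class = "synscale_usage_error")
})
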