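# Shared small fixtures (built in code at test time).

# A clean noiseless trace with exactly controlled events.
noiseless_events_trace <- function(onsets, amps, duration = 5,
                                   sampling_rate = 10000) {
  p <- mepsc_params(duration = duration, sampling_rate = sampling_rate,
                    event_rate = 0, noise_sd = 0, seed = 1)
  generate_mepsc_trace(p, forced_onsets = onsets, forced_amplitudes = amps)
}

# Study-scale cohort simulation used by the acceptance blocks: 16 neurons
# per group, >= 50 events each, detection at 7.5 pA, first-50 rank-order
# fit. Problem size (40 s at 5 kHz, 2.25 events/s) is the package's
# declared simulation scale for this design (see the methods vignette).
scaling_sim_seed <- function(seed, factor = 1.51) {
  p <- mepsc_params(duration = 40, sampling_rate = 5000, event_rate = 2.25,
                    seed = NULL)
  coh <- generate_scaled_cohorts(p, factor, n_neurons = 16, seed = seed)
  amps <- function(lst) lapply(lst, function(x) detect_events(x$trace)$amplitude_pA)
  res <- scaling_pipeline(amps(coh$control), amps(coh$treated))
  list(slope = res$scaling_factor, r2 = res$linear$r2,
       n_points = res$n_points, result = res)
}
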