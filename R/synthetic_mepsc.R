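#' Parameters for synthetic mEPSC voltage-clamp traces
#'
#' Describes the generative model used for ground-truth miniature EPSC
#' recordings: Poisson-timed events with lognormal peak amplitudes, each
#' event a difference-of-exponentials (biexponential) current transient,
#' summed over a flat baseline with additive Gaussian noise. Events are
#' inward (downward deflections), matching AMPA-mediated miniature currents
#' at a -80 mV holding potential; amplitudes are stored as positive
#' magnitudes in pA.
#'
#' Defaults: the amplitude law is lognormal with median 18 pA and log-scale
#' sigma 0.45, which places under 2% of its mass below the 7.5 pA detection
#' threshold so that threshold truncation is negligible in recovery studies.
#' The kernel time constants are 1 ms rise and 8 ms decay. The default event
#' rate of 1.5 events/s makes 50+ events in a one-minute record essentially
#' certain, which the first-50 sampling design requires.
#'
#' @param duration Trace duration in s.
#' @param sampling_rate Sampling rate in Hz.
#' @param event_rate Mean event rate in events/s (Poisson).
#' @param amp_median Median of the lognormal amplitude law, pA.
#' @param amp_sigma Log-scale standard deviation of the amplitude law.
#' @param rise_tau Kernel rise time constant, ms.
#' @param decay_tau Kernel decay time constant, ms (must exceed `rise_tau`).
#' @param noise_sd Additive Gaussian noise SD, pA.
#' @param baseline Holding-current baseline, pA.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `mepsc_params`.
#' @export
mepsc_params <- function(duration = 60, sampling_rate = 1e5, event_rate = 1.5,
                         amp_median = 18, amp_sigma = 0.45,
                         rise_tau = 1, decay_tau = 8,
                         noise_sd = 2, baseline = 0, seed = 1L) {
  stopifnot(duration > 0, sampling_rate > 0, event_rate >= 0,
            amp_median > 0, amp_sigma > 0, noise_sd >= 0,
            rise_tau > 0, decay_tau > 0)
  if (decay_tau <= rise_tau) {
    abort("`decay_tau` must exceed `rise_tau`.", class = "synscale_error")
  }
  structure(as.list(environment()), class = "mepsc_params")
}

#' Biexponential unit-peak mEPSC kernel
#'
#' `k(t) = exp(-t/tau_decay) - exp(-t/tau_rise)`, sampled on the trace grid
#' and normalized so its discrete maximum is exactly 1; an injected event of
#' amplitude A therefore deflects the trace by exactly A pA at its sampled
#' peak. Kernel support is truncated at 10 decay time constants.
#'
#' @param rise_tau,decay_tau Time constants in ms.
#' @param sampling_rate Hz.
#' @return Numeric vector (unit peak), with attribute `peak_index`.
#' @export
mepsc_kernel <- function(rise_tau, decay_tau, sampling_rate) {
  t_ms <- seq(0, 10 * decay_tau, by = 1000 / sampling_rate)
  k <- exp(-t_ms / decay_tau) - exp(-t_ms / rise_tau)
  pk <- which.max(k)
  k <- k / k[pk]
  attr(k, "peak_index") <- pk
  k
}

# Draw Poisson event times and lognormal amplitudes (RNG state as-is).
draw_mepsc_events <- function(params) {
  n_ev <- stats::rpois(1, params$event_rate * params$duration)
  onsets <- sort(stats::runif(n_ev, 0, params$duration))
  amps <- stats::rlnorm(n_ev, meanlog = log(params$amp_median),
                        sdlog = params$amp_sigma)
  tibble(onset_s = onsets, amplitude_pA = amps)
}

# Synthesize baseline + noise + summed kernels from an explicit event table.
build_mepsc_trace <- function(params, events, group = NULL) {
  n_samp <- round(params$duration * params$sampling_rate)
  samples <- params$baseline +
    (if (params$noise_sd > 0) stats::rnorm(n_samp, 0, params$noise_sd) else
      numeric(n_samp))
  if (nrow(events)) {
    kern <- mepsc_kernel(params$rise_tau, params$decay_tau,
                         params$sampling_rate)
    lk <- length(kern)
    for (i in seq_len(nrow(events))) {
      i0 <- floor(events$onset_s[i] * params$sampling_rate) + 1L
      if (i0 > n_samp) next
      i1 <- min(i0 + lk - 1L, n_samp)
      idx <- i0:i1
      samples[idx] <- samples[idx] - events$amplitude_pA[i] * kern[seq_along(idx)]
    }
  }
  md <- list(kind = "synthetic_mepsc")
  if (!is.null(group)) md$group <- group
  list(trace = trace(samples, params$sampling_rate, "vclamp_current",
                     metadata = md),
       truth = events)
}

#' Generate a synthetic mEPSC trace with ground truth
#'
#' Draws a Poisson number of events over the trace duration, assigns each a
#' lognormal amplitude, and sums unit-peak biexponential kernels scaled by
#' (minus) those amplitudes onto baseline plus Gaussian noise. Overlapping
#' events simply summate. `forced_onsets`/`forced_amplitudes` override the
#' random draws (used to build exactly controlled fixtures).
#'
#' @param params An [mepsc_params()] object.
#' @param forced_onsets,forced_amplitudes Optional numeric vectors giving the
#'   exact event onsets (s) and positive amplitudes (pA) instead of random
#'   draws.
#' @return List with `trace` (a [trace()], role `vclamp_current`) and
#'   `truth` (tibble: `onset_s`, `amplitude_pA`, sorted by onset).
#' @export
generate_mepsc_trace <- function(params, forced_onsets = NULL,
                                 forced_amplitudes = NULL) {
  stopifnot(inherits(params, "mepsc_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(forced_onsets)) {
    events <- draw_mepsc_events(params)
  } else {
    stopifnot(length(forced_onsets) == length(forced_amplitudes),
              all(forced_amplitudes > 0))
    o <- order(forced_onsets)
    events <- tibble(onset_s = as.numeric(forced_onsets)[o],
                     amplitude_pA = as.numeric(forced_amplitudes)[o])
  }
  build_mepsc_trace(params, events)
}

#' Generate control and multiplicatively scaled treated cohorts
#'
#' The treated cohort uses the identical generative process as the control
#' cohort except that every drawn amplitude is multiplied by `factor` before
#' trace synthesis; event times are independent between cohorts and neurons.
#' Per-neuron seeds are derived deterministically from `seed` (fixed prime
#' offsets, reduced modulo 2^31), so one master seed reproduces both cohorts
#' bit-for-bit.
#'
#' @param control An [mepsc_params()] object describing the control law.
#' @param factor Multiplicative scaling factor applied to treated amplitudes
#'   (> 0).
#' @param n_neurons Neurons per cohort.
#' @param seed Master seed.
#' @return List with elements `control` and `treated`, each a list of
#'   `n_neurons` results from [generate_mepsc_trace()].
#' @export
generate_scaled_cohorts <- function(control, factor, n_neurons = 16L,
                                    seed = 1L) {
  stopifnot(inherits(control, "mepsc_params"), n_neurons >= 1)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    abort("`factor` must be a positive scalar.", class = "synscale_error")
  }
  gen_one <- function(i, treated) {
    grp <- if (treated) "treated" else "control"
    set.seed((seed + 7919L * i + if (treated) 104729L else 0L) %% 2147483587L)
    events <- draw_mepsc_events(control)
    if (treated) events$amplitude_pA <- events$amplitude_pA * factor
    out <- build_mepsc_trace(control, events, group = grp)
    out$trace$metadata$neuron_id <- paste0(grp, "_", i)
    out
  }
  list(control = lapply(seq_len(n_neurons), gen_one, treated = FALSE),
       treated = lapply(seq_len(n_neurons), gen_one, treated = TRUE))
}
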