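#' Leaky integrate-and-fire neuron parameters
#'
#' Minimal spiking model used by the step-protocol generator: a passive RC
#' membrane (input resistance `R_in`, time constant `tau_m`) that emits a
#' stereotyped spike whenever the voltage reaches `V_thresh`, then resets to
#' `V_rest` and stays there for an absolute refractory period `t_ref`. The
#' model has a closed-form firing-rate-vs-current relation (see
#' [lif_rate()]), which serves as the analytic oracle for the excitability
#' analyses.
#'
#' @param R_in Input resistance, megaohms.
#' @param tau_m Membrane time constant, ms.
#' @param V_rest Resting potential, mV.
#' @param V_thresh Spike threshold, mV.
#' @param t_ref Absolute refractory period, ms.
#' @param spike_peak Stereotyped spike peak, mV (default +15 mV gives a
#'   60 mV spike from a -45 mV threshold, above the 50 mV QC criterion).
#' @return A list of class `lif_params`.
#' @export
lif_params <- function(R_in = 100, tau_m = 10, V_rest = -60, V_thresh = -45,
                       t_ref = 5, spike_peak = 15) {
  stopifnot(R_in > 0, tau_m > 0, t_ref >= 0, V_thresh > V_rest,
            spike_peak > V_thresh)
  structure(as.list(environment()), class = "lif_params")
}

#' Analytic leaky integrate-and-fire firing rate
#'
#' For a current step I the steady-state depolarization from rest is
#' `dV_inf = I * R_in / 1000` mV (pA times megaohms gives microvolts). With
#' threshold depolarization `dV_th = V_thresh - V_rest`, the firing rate is
#' 0 when `dV_inf <= dV_th` (subthreshold) and otherwise
#' `f = 1 / (t_ref + tau_m * ln(dV_inf / (dV_inf - dV_th)))` with the time
#' constants in seconds.
#'
#' @param current Injected current, pA (vectorized).
#' @param neuron An [lif_params()] object.
#' @return Firing rate in Hz.
#' @export
lif_rate <- function(current, neuron) {
  stopifnot(inherits(neuron, "lif_params"))
  dv_inf <- current * neuron$R_in / 1000
  dv_th <- neuron$V_thresh - neuron$V_rest
  f <- numeric(length(current))
  supra <- dv_inf > dv_th
  f[supra] <- 1 / (neuron$t_ref / 1000 +
                     neuron$tau_m / 1000 *
                       log(dv_inf[supra] / (dv_inf[supra] - dv_th)))
  f
}

#' Generate a current-clamp step family from a LIF neuron
#'
#' Simulates the step protocol used for intrinsic-excitability analysis:
#' by default 24 half-second steps from -150 pA in +50 pA increments (up to
#' +1000 pA), each sweep holding a pre-step baseline, the step, and a
#' post-step tail. Subthreshold sweeps follow exact exponential charging to
#' `V_rest + I * R_in`; suprathreshold sweeps emit stereotyped spikes at the
#' integrate-and-fire interspike interval. The per-sample update uses the
#' exact exponential propagator, so the only discretization error is the
#' one-sample rounding of threshold-crossing times. Deterministic given the
#' seed (the seed only matters when `noise_sd > 0`).
#'
#' @param neuron An [lif_params()] object.
#' @param steps Injected currents, pA.
#' @param step_dur Step duration, s.
#' @param sampling_rate Hz (current-clamp acquisition default 10 kHz).
#' @param pre,post Pre-step and post-step baseline durations, s.
#' @param noise_sd Additive membrane noise SD, mV (default 0: noiseless).
#' @param seed Integer seed.
#' @return A `step_family`: list with `sweeps` (tibble: `current_pA`,
#'   `trace` list-column), `step_window` (start/end of the step, s), and
#'   `neuron` (the generating parameters).
#' @export
generate_fi_sweeps <- function(neuron = lif_params(),
                               steps = seq(-150, 1000, by = 50),
                               step_dur = 0.5, sampling_rate = 1e4,
                               pre = 0.2, post = 0.1,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(neuron, "lif_params"), all(is.finite(steps)),
            step_dur > 0, pre >= 0.1)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / sampling_rate
  n_pre <- round(pre * sampling_rate)
  n_step <- round(step_dur * sampling_rate)
  n_post <- round(post * sampling_rate)
  decay <- exp(-dt * 1000 / neuron$tau_m)
  ref_samp <- max(1L, round(neuron$t_ref / 1000 * sampling_rate))
  sim_sweep <- function(I) {
    n <- n_pre + n_step + n_post
    v <- numeric(n)
    v[seq_len(n_pre)] <- neuron$V_rest
    v_inf_step <- neuron$V_rest + I * neuron$R_in / 1000
    vi <- neuron$V_rest
    hold <- 0L  # remaining refractory samples
    i <- n_pre + 1L
    while (i <= n) {
      v_inf <- if (i <= n_pre + n_step) v_inf_step else neuron$V_rest
      if (hold > 0L) {
        vi <- neuron$V_rest
        v[i] <- vi
        hold <- hold - 1L
        i <- i + 1L
        next
      }
      vi <- v_inf + (vi - v_inf) * decay
      if (vi >= neuron$V_thresh && i <= n_pre + n_step) {
        v[i] <- neuron$spike_peak      # stereotyped one-sample spike apex
        vi <- neuron$V_rest
        hold <- ref_samp - 1L
      } else {
        v[i] <- vi
      }
      i <- i + 1L
    }
    if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
    trace(v, sampling_rate, "cclamp_voltage",
          metadata = list(kind = "synthetic_fi", current_pA = I))
  }
  sweeps <- tibble(current_pA = as.numeric(steps),
                   trace = lapply(steps, sim_sweep))
  structure(list(sweeps = sweeps, step_window = c(pre, pre + step_dur),
                 neuron = neuron),
            class = "step_family")
}

#' @export
print.step_family <- function(x, ...) {
  cat(sprintf("<step_family> %d sweeps, %g to %g pA, step %.3g-%.3g s\n",
              nrow(x$sweeps), min(x$sweeps$current_pA),
              max(x$sweeps$current_pA), x$step_window[1], x$step_window[2]))
  invisible(x)
}
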