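#' Default drug-epoch layout for synthetic neurograms
#'
#' Three consecutive 10-minute epochs (baseline, drug, washout) with
#' per-epoch multiplicative effects on burst amplitude and frequency. The
#' default drug effect (amplitude x0.6, frequency x0.2) emulates an AMPA
#' antagonist that drops burst frequency by ~80% and burst height by ~40%;
#' washout partially recovers.
#'
#' @param epoch_dur Epoch duration, s.
#' @param amp_factors,freq_factors Named or positional multipliers for
#'   (baseline, drug, washout).
#' @return Tibble: `epoch`, `start_s`, `end_s`, `amp_factor`, `freq_factor`.
#' @export
default_epochs <- function(epoch_dur = 600,
                           amp_factors = c(1, 0.6, 0.9),
                           freq_factors = c(1, 0.2, 0.8)) {
  tibble(
    epoch = c("baseline", "drug", "washout"),
    start_s = c(0, epoch_dur, 2 * epoch_dur),
    end_s = c(epoch_dur, 2 * epoch_dur, 3 * epoch_dur),
    amp_factor = as.numeric(amp_factors),
    freq_factor = as.numeric(freq_factors)
  )
}

#' Generate a two-channel integrated neurogram with ground-truth bursts
#'
#' Emulates integrated (rectified and smoothed) nerve recordings from a
#' rhythmic brainstem preparation: both channels carry positive half-sine
#' burst envelopes at shared event times over a noisy positive baseline,
#' with the second channel offset by `channel_lag`. Burst times within each
#' epoch follow a renewal process (exponential gap plus a dead time of one
#' burst duration + 1 s) whose mean interval equals
#' `1 / (rate * freq_factor)`, so recovered epoch frequencies are unbiased.
#' Per-epoch amplitude multipliers scale burst heights. Optional extra
#' bursts on one channel only produce known non-coincident events.
#'
#' @param burst_rate_per_min Baseline burst rate, bursts/min.
#' @param burst_dur Burst envelope duration, s (~1 s fictive lung breath).
#' @param burst_amp Baseline burst envelope height, integrated units.
#' @param amp_cv Lognormal coefficient of variation of burst heights.
#' @param channel_lag Onset lag of the second channel, s (|lag| should stay
#'   inside the coincidence tolerance).
#' @param epochs Epoch table as from [default_epochs()].
#' @param baseline_level Constant baseline of the integrated trace.
#' @param noise_sd Gaussian noise SD on both channels.
#' @param sampling_rate Hz (integrated traces are slow; 200 Hz default).
#' @param n_extra_cnx Number of additional bursts injected on the first
#'   channel only (ground truth marks them non-coincident).
#' @param seed Integer seed.
#' @return List with traces `cnx` and `snii` (roles `neurogram_cnx`,
#'   `neurogram_snii`) and `truth`: a list holding `bursts` (tibble:
#'   `onset_s`, `dur_s`, `amp`, `epoch`, `coincident`) and the epoch table.
#' @export
generate_neurogram <- function(burst_rate_per_min = 10, burst_dur = 1,
                               burst_amp = 3, amp_cv = 0.1,
                               channel_lag = 0.1,
                               epochs = default_epochs(),
                               baseline_level = 1, noise_sd = 0.05,
                               sampling_rate = 200, n_extra_cnx = 0L,
                               seed = 1L) {
  stopifnot(burst_rate_per_min > 0, burst_dur > 0.05, burst_amp > 0,
            sampling_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  duration <- max(epochs$end_s)
  dead <- burst_dur + 1
  onsets <- numeric(0)
  epoch_of <- character(0)
  amp_of <- numeric(0)
  for (k in seq_len(nrow(epochs))) {
    rate <- burst_rate_per_min / 60 * epochs$freq_factor[k]
    mean_gap <- 1 / rate
    if (mean_gap <= dead) {
      abort("Burst rate too high for the dead time; reduce rate or duration.",
            class = "synscale_error")
    }
    t <- epochs$start_s[k] + stats::rexp(1, 1 / (mean_gap - dead))
    while (t + burst_dur < epochs$end_s[k]) {
      onsets <- c(onsets, t)
      epoch_of <- c(epoch_of, epochs$epoch[k])
      amp_of <- c(amp_of, burst_amp * epochs$amp_factor[k] *
                    stats::rlnorm(1, -amp_cv^2 / 2, amp_cv))
      t <- t + dead + stats::rexp(1, 1 / (mean_gap - dead))
    }
  }
  coincident <- rep(TRUE, length(onsets))
  if (n_extra_cnx > 0) {
    # place extras midway between existing bursts where room allows
    gaps <- which(diff(onsets) > 2 * dead + burst_dur)
    gaps <- utils::head(gaps, n_extra_cnx)
    extra <- onsets[gaps] + (diff(onsets)[gaps]) / 2
    ep <- vapply(extra, function(t)
      epochs$epoch[which(t >= epochs$start_s & t < epochs$end_s)[1]],
      character(1))
    onsets <- c(onsets, extra)
    epoch_of <- c(epoch_of, ep)
    amp_of <- c(amp_of, rep(burst_amp, length(extra)))
    coincident <- c(coincident, rep(FALSE, length(extra)))
    o <- order(onsets)
    onsets <- onsets[o]; epoch_of <- epoch_of[o]
    amp_of <- amp_of[o]; coincident <- coincident[o]
  }
  n_samp <- round(duration * sampling_rate)
  make_channel <- function(lag, include_extras) {
    x <- baseline_level +
      (if (noise_sd > 0) stats::rnorm(n_samp, 0, noise_sd) else numeric(n_samp))
    for (i in seq_along(onsets)) {
      if (!include_extras && !coincident[i]) next
      i0 <- floor((onsets[i] + lag) * sampling_rate) + 1L
      i1 <- min(i0 + round(burst_dur * sampling_rate) - 1L, n_samp)
      if (i0 > n_samp || i1 < i0) next
      tt <- (seq(i0, i1) - i0) / sampling_rate
      x[i0:i1] <- x[i0:i1] + amp_of[i] * sin(pi * tt / burst_dur)
    }
    x
  }
  bursts <- tibble(onset_s = onsets, dur_s = burst_dur, amp = amp_of,
                   epoch = epoch_of, coincident = coincident)
  list(
    cnx = trace(make_channel(0, TRUE), sampling_rate, "neurogram_cnx",
                metadata = list(kind = "synthetic_neurogram")),
    snii = trace(make_channel(channel_lag, FALSE), sampling_rate,
                 "neurogram_snii",
                 metadata = list(kind = "synthetic_neurogram")),
    truth = list(bursts = bursts, epochs = epochs)
  )
}
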