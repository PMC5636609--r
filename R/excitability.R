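#' Input resistance from a current-clamp step family
#'
#' Ordinary least-squares slope of the steady-state voltage deflection
#' against injected current over the non-positive steps (-150 to 0 pA in
#' 50 pA increments). The steady state is the mean of the last 100 ms of
#' the step; the deflection is relative to the mean of the pre-step
#' baseline. The slope in mV/pA is converted to megaohms (x1000).
#'
#' @param family A `step_family` from [generate_fi_sweeps()] or assembled
#'   from recordings.
#' @param steady_window Length of the steady-state window at the end of the
#'   step, s.
#' @return Input resistance in megaohms.
#' @export
input_resistance <- function(family, steady_window = 0.1) {
  stopifnot(inherits(family, "step_family"))
  neg <- family$sweeps[family$sweeps$current_pA <= 0, , drop = FALSE]
  if (nrow(neg) < 2L) {
    abort("Need the non-positive current steps to compute input resistance.",
          class = "synscale_usage_error")
  }
  defl <- vapply(seq_len(nrow(neg)), function(i) {
    tr <- neg$trace[[i]]
    fs <- tr$sampling_rate
    w <- family$step_window
    i_pre <- seq_len(max(1L, round(w[1] * fs)))
    i_ss <- seq.int(round((w[2] - steady_window) * fs) + 1L, round(w[2] * fs))
    mean(tr$samples[i_ss]) - mean(tr$samples[i_pre])
  }, numeric(1))
  fit <- stats::lm(defl ~ neg$current_pA)
  unname(stats::coef(fit)[2L]) * 1000
}

#' Detect action potentials in a current-clamp trace
#'
#' Upward threshold-crossing detection (default 0 mV) with a refractory
#' period. Spike amplitude is the peak voltage minus the voltage just
#' before the upstroke (1 ms earlier); spikes of 50 mV or less are flagged
#' as below the action-potential QC criterion but still reported.
#'
#' @param x A [trace()] with role `cclamp_voltage`.
#' @param threshold Crossing threshold, mV.
#' @param refractory Minimum spike separation, ms.
#' @return Tibble: `time_s`, `peak_mV`, `amplitude_mV`, `below_qc`
#'   (amplitude <= 50 mV).
#' @export
detect_spikes <- function(x, threshold = 0, refractory = 2) {
  assert_role(x, "cclamp_voltage", "x")
  v <- x$samples
  fs <- x$sampling_rate
  up <- which(v[-1L] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) > 1L) {
    ref_samp <- refractory / 1000 * fs
    keep <- c(TRUE, diff(up) > ref_samp)
    # sequential enforcement: drop crossings inside the refractory of a kept one
    last <- up[1L]
    for (i in seq_along(up)[-1L]) {
      keep[i] <- (up[i] - last) > ref_samp
      if (keep[i]) last <- up[i]
    }
    up <- up[keep]
  }
  if (!length(up)) {
    return(tibble(time_s = numeric(0), peak_mV = numeric(0),
                  amplitude_mV = numeric(0), below_qc = logical(0)))
  }
  win <- max(1L, round(0.002 * fs))
  pre <- max(1L, round(0.001 * fs))
  peak <- vapply(up, function(i) max(v[i:min(length(v), i + win)]), numeric(1))
  base <- v[pmax(1L, up - pre)]
  tibble(time_s = x$t0 + (up - 1L) / fs,
         peak_mV = peak,
         amplitude_mV = peak - base,
         below_qc = (peak - base) <= 50)
}

#' Firing-rate-current relationship and gain
#'
#' For each non-negative current step, the firing rate is the spike count
#' within the step divided by the step duration. The F-I gain is the OLS
#' slope of rate against current over the depolarizing steps (0 to the
#' maximum, by default all of them); the rheobase is the smallest current
#' that evokes at least one spike. When every sweep is silent the gain is 0
#' and flagged.
#'
#' @param family A `step_family`.
#' @param suprathreshold_only If `TRUE`, fit the gain over steps at or above
#'   rheobase only (the default uses all non-negative steps).
#' @param spike_threshold,refractory Passed to [detect_spikes()].
#' @return Object of class `fi_result`: list with `rates` (tibble:
#'   `current_pA`, `rate_hz`), `gain` (Hz/pA), `rheobase` (pA or `NA`),
#'   `zero_activity` flag.
#' @export
fi_gain <- function(family, suprathreshold_only = FALSE, spike_threshold = 0,
                    refractory = 2) {
  stopifnot(inherits(family, "step_family"))
  pos <- family$sweeps[family$sweeps$current_pA >= 0, , drop = FALSE]
  if (!nrow(pos)) {
    abort("No non-negative current steps present.",
          class = "synscale_usage_error")
  }
  w <- family$step_window
  dur <- w[2] - w[1]
  counts <- vapply(seq_len(nrow(pos)), function(i) {
    sp <- detect_spikes(pos$trace[[i]], spike_threshold, refractory)
    t0 <- pos$trace[[i]]$t0
    sum(sp$time_s >= t0 + w[1] & sp$time_s < t0 + w[2])
  }, numeric(1))
  rates <- tibble(current_pA = pos$current_pA, rate_hz = counts / dur)
  rheobase <- if (any(counts > 0)) min(pos$current_pA[counts > 0]) else NA_real_
  zero <- all(counts == 0)
  fit_df <- if (suprathreshold_only && !zero) {
    rates[rates$current_pA >= rheobase, , drop = FALSE]
  } else rates
  gain <- if (zero || nrow(fit_df) < 2L) 0 else
    unname(stats::coef(stats::lm(rate_hz ~ current_pA, data = fit_df))[2L])
  structure(list(rates = rates, gain = gain, rheobase = rheobase,
                 zero_activity = zero),
            class = "fi_result")
}

#' @export
print.fi_result <- function(x, ...) {
  cat(sprintf("<fi_result> gain %.4g Hz/pA, rheobase %s pA%s\n", x$gain,
              format(x$rheobase), if (x$zero_activity) " (no spikes)" else ""))
  invisible(x)
}

#' @rdname fi_gain
#' @param x An `fi_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.fi_result <- function(x, ...) {
  tibble(gain_hz_per_pa = x$gain, rheobase_pA = x$rheobase,
         max_rate_hz = max(x$rates$rate_hz), zero_activity = x$zero_activity)
}

#' F-I curve plot
#' @param object An `fi_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fi_result <- function(object, ...) {
  ggplot2::ggplot(object$rates, ggplot2::aes(x = current_pA, y = rate_hz)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "blue", linewidth = 0.5) +
    ggplot2::labs(x = "injected current (pA)", y = "firing rate (Hz)")
}

#' Compare F-I slopes between two groups
#'
#' Pools the per-neuron firing-rate-current series of both groups and runs
#' a homogeneity-of-slopes ANCOVA (`rate ~ current * group`; the
#' current-by-group interaction tests whether the mean slopes differ). Also
#' reports the unpaired t test on per-neuron gains and the per-group mean
#' gains.
#'
#' @param group_a,group_b Lists of `step_family` or `fi_result` objects
#'   (>= 2 per group).
#' @param labels Character vector of two group labels.
#' @return List: `ancova` (TestResult tibble), `t_gains` (TestResult
#'   tibble), `mean_gains` (tibble: group, mean gain, n).
#' @export
compare_fi_slopes <- function(group_a, group_b, labels = c("a", "b")) {
  as_fi <- function(x) if (inherits(x, "step_family")) fi_gain(x) else x
  fa <- lapply(group_a, as_fi)
  fb <- lapply(group_b, as_fi)
  if (length(fa) < 2L || length(fb) < 2L) {
    abort("Need at least 2 neurons per group.", class = "synscale_usage_error")
  }
  long <- dplyr::bind_rows(
    purrr::imap(fa, ~ dplyr::mutate(.x$rates, group = labels[1],
                                    neuron = paste0("a", .y))),
    purrr::imap(fb, ~ dplyr::mutate(.x$rates, group = labels[2],
                                    neuron = paste0("b", .y)))
  )
  anc <- ancova_slopes(dplyr::rename(long, x = current_pA, y = rate_hz))
  gains_a <- vapply(fa, function(f) f$gain, numeric(1))
  gains_b <- vapply(fb, function(f) f$gain, numeric(1))
  list(
    ancova = anc,
    t_gains = unpaired_t(gains_a, gains_b),
    mean_gains = tibble(group = labels,
                        mean_gain_hz_per_pa = c(mean(gains_a), mean(gains_b)),
                        n = c(length(fa), length(fb)))
  )
}

#' Resting membrane potential with liquid-junction-potential correction
#'
#' Mean of the pre-step baseline (at least 100 ms) plus the liquid junction
#' potential offset, applied exactly once: a measured baseline of -45.13 mV
#' with the default -12 mV correction reports -57.13 mV. Traces whose
#' metadata already carry `ljp_corrected = TRUE` are refused when a further
#' non-zero correction is requested.
#'
#' @param x A [trace()] with role `cclamp_voltage`.
#' @param ljp Liquid junction potential, mV (pipette relative to bath;
#'   default -12).
#' @param baseline_window Pre-step window to average, s (>= 0.1).
#' @return Corrected resting potential, mV, with attribute `ljp_applied`.
#' @export
resting_potential <- function(x, ljp = -12, baseline_window = 0.1) {
  assert_role(x, "cclamp_voltage", "x")
  if (baseline_window < 0.1) {
    abort("Pre-step baseline must be at least 100 ms.",
          class = "synscale_usage_error")
  }
  if (isTRUE(x$metadata$ljp_corrected) && ljp != 0) {
    abort("Trace is already junction-potential corrected; refusing to correct twice.",
          class = "synscale_usage_error")
  }
  n <- round(baseline_window * x$sampling_rate)
  if (n > length(x$samples)) {
    abort("Trace shorter than the requested baseline window.",
          class = "synscale_usage_error")
  }
  out <- mean(x$samples[seq_len(n)]) + ljp
  attr(out, "ljp_applied") <- ljp
  out
}
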