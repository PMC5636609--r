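#' Conditioning settings for raw extracellular neurograms
#'
#' Raw nerve recordings are band-pass filtered (100-1000 Hz), full-wave
#' rectified, and smoothed with a leaky integrator (time constant 60 ms) to
#' form the integrated neurogram that burst analysis operates on. These
#' settings apply only when raw (non-integrated) input is supplied.
#'
#' @param band Band-pass edges, Hz (must lie inside Nyquist).
#' @param integrate_tau Integrator time constant, ms.
#' @return A list of class `conditioning_config`.
#' @export
conditioning_config <- function(band = c(100, 1000), integrate_tau = 60) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            integrate_tau > 0)
  structure(list(band = band, integrate_tau = integrate_tau),
            class = "conditioning_config")
}

#' Leaky integrator
#'
#' First-order low-pass recursion `y[i] = a*y[i-1] + (1-a)*x[i]` with
#' `a = exp(-dt/tau)`: the step response reaches 63% of its plateau after
#' one time constant.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param tau Time constant, ms.
#' @return Numeric vector of the same length.
#' @export
leaky_integrate <- function(x, fs, tau) {
  a <- exp(-1000 / (fs * tau))
  as.numeric(stats::filter(x * (1 - a), filter = a, method = "recursive"))
}

#' Condition a raw neurogram into an integrated trace
#'
#' Band-pass filter (4th-order Butterworth, zero-phase), full-wave rectify,
#' then leaky-integrate. The output is non-negative and carries the input's
#' channel role.
#'
#' @param raw A [trace()] (sampling rate >= 2 kHz).
#' @param config A [conditioning_config()].
#' @return Integrated [trace()].
#' @export
condition_neurogram <- function(raw, config = conditioning_config()) {
  stopifnot(is_trace(raw), inherits(config, "conditioning_config"))
  fs <- raw$sampling_rate
  if (fs < 2000) {
    abort("Raw neurogram sampling rate must be at least 2 kHz.",
          class = "synscale_usage_error")
  }
  if (config$band[2] >= fs / 2) {
    abort("Band-pass upper edge exceeds the Nyquist frequency.",
          class = "synscale_parameter_error")
  }
  bt <- signal::butter(4, config$band / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bt, raw$samples))
  integ <- leaky_integrate(abs(filt), fs, config$integrate_tau)
  trace(integ, fs, raw$channel_role, t0 = raw$t0,
        metadata = c(raw$metadata, list(conditioned = TRUE)))
}

#' Burst-detection settings
#'
#' @param k_enter Threshold for burst entry, in robust scale units (MAD)
#'   above the rolling baseline.
#' @param k_exit Hysteresis exit threshold, MAD units.
#' @param dur_range Accepted burst durations, s (fictive lung breaths are
#'   ~1 s; the default window is 0.3-3 s).
#' @param coincidence_tol Maximum onset lag between channels for a burst to
#'   count as coincident (respiratory), s.
#' @param baseline_window Rolling-median baseline window, s.
#' @return A list of class `burst_config`.
#' @export
burst_config <- function(k_enter = 4, k_exit = 2, dur_range = c(0.3, 3),
                         coincidence_tol = 0.5, baseline_window = 60) {
  stopifnot(k_enter > k_exit, k_exit >= 0, length(dur_range) == 2L,
            dur_range[2] > dur_range[1], coincidence_tol > 0)
  structure(as.list(environment()), class = "burst_config")
}

detect_bursts_channel <- function(x, config) {
  fs <- x$sampling_rate
  base <- running_baseline(x$samples, fs, config$baseline_window * 1000)
  resid <- x$samples - base
  scale <- stats::mad(resid)
  # noise-free traces have zero MAD; fall back to a threshold that is a
  # small fraction of the peak deviation so clean envelopes are still found
  if (scale == 0) scale <- 1e-3 * max(abs(resid))
  if (scale == 0) return(empty_bursts())
  enter <- config$k_enter * scale
  exit <- config$k_exit * scale
  above_exit <- resid > exit
  if (!any(above_exit)) return(empty_bursts())
  r <- rle(above_exit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]; e <- ends[r$values]
  keep <- vapply(seq_along(s), function(j) any(resid[s[j]:e[j]] > enter),
                 logical(1))
  s <- s[keep]; e <- e[keep]
  dur <- (e - s + 1L) / fs
  ok <- dur >= config$dur_range[1] & dur <= config$dur_range[2]
  s <- s[ok]; e <- e[ok]
  if (!length(s)) return(empty_bursts())
  met <- purrr::map2(s, e, function(i0, i1)
    burst_metrics(c(x$t0 + (i0 - 1L) / fs, x$t0 + (i1 - 1L) / fs), x))
  tibble(
    onset_s = x$t0 + (s - 1L) / fs,
    offset_s = x$t0 + (e - 1L) / fs,
    dur_s = (e - s + 1L) / fs,
    amplitude = vapply(met, `[[`, numeric(1), "amplitude"),
    area = vapply(met, `[[`, numeric(1), "area"),
    baseline_clipped = vapply(met, `[[`, logical(1), "baseline_clipped")
  )
}

empty_bursts <- function() {
  tibble(onset_s = numeric(0), offset_s = numeric(0), dur_s = numeric(0),
         amplitude = numeric(0), area = numeric(0),
         baseline_clipped = logical(0))
}

#' Detect respiratory bursts in a two-channel integrated neurogram
#'
#' Candidate bursts on each channel are supra-threshold excursions of the
#' baseline-subtracted integrated trace (entry at `k_enter` robust scale
#' units above a rolling-median baseline, exit at `k_exit` — hysteresis)
#' with durations inside the accepted window. A burst on the primary
#' (vagal) channel is classified as respiratory — `coincident = TRUE` —
#' when the companion (hypoglossal) channel has a burst onset within the
#' coincidence tolerance; bursts on one channel only are reported but
#' flagged non-coincident.
#'
#' @param cnx,snii Integrated [trace()]s with overlapping time bases.
#' @param config A [burst_config()].
#' @return Tibble of bursts: `channel`, `onset_s`, `offset_s`, `dur_s`,
#'   `amplitude`, `area`, `coincident`.
#' @export
detect_bursts <- function(cnx, snii, config = burst_config()) {
  stopifnot(is_trace(cnx), is_trace(snii))
  a0 <- cnx$t0; a1 <- cnx$t0 + trace_duration(cnx)
  b0 <- snii$t0; b1 <- snii$t0 + trace_duration(snii)
  if (min(a1, b1) <= max(a0, b0)) {
    abort("Channel time bases do not overlap.", class = "synscale_usage_error")
  }
  bc <- detect_bursts_channel(cnx, config)
  bs <- detect_bursts_channel(snii, config)
  near <- function(t, ref) vapply(t, function(ti)
    any(abs(ref - ti) <= config$coincidence_tol), logical(1))
  bc$coincident <- near(bc$onset_s, bs$onset_s)
  bs$coincident <- near(bs$onset_s, bc$onset_s)
  dplyr::bind_rows(
    dplyr::mutate(bc, channel = cnx$channel_role, .before = 1),
    dplyr::mutate(bs, channel = snii$channel_role, .before = 1)
  )
}

#' Amplitude and area of one burst window
#'
#' Baseline is the mean of the 1 s of trace preceding the onset (clipped
#' and flagged when the window starts near the trace beginning); amplitude
#' is the maximum within the window minus that baseline; area is the
#' integral of the baseline-subtracted trace over the window with negative
#' excursions clipped at zero.
#'
#' @param window Numeric `c(onset_s, offset_s)`.
#' @param x The integrated [trace()].
#' @param peak_smooth Moving-average window applied before taking the peak,
#'   s (0 disables). Averaging suppresses the upward bias a maximum taken
#'   over noisy samples would otherwise carry; the slight attenuation of
#'   the burst peak is multiplicative and cancels in the percent-of-baseline
#'   comparisons the pipeline reports.
#' @return List: `amplitude`, `area`, `baseline`, `baseline_clipped`.
#' @export
burst_metrics <- function(window, x, peak_smooth = 0.1) {
  stopifnot(is_trace(x), length(window) == 2L, window[2] > window[1])
  fs <- x$sampling_rate
  i0 <- round((window[1] - x$t0) * fs) + 1L
  i1 <- min(length(x$samples), round((window[2] - x$t0) * fs) + 1L)
  if (i0 < 1L || i0 > length(x$samples)) {
    abort("Burst window outside the trace.", class = "synscale_usage_error")
  }
  pre0 <- i0 - round(1 * fs)
  clipped <- pre0 < 1L
  pre0 <- max(1L, pre0)
  baseline <- if (pre0 >= i0 - 1L) x$samples[i0] else
    mean(x$samples[pre0:(i0 - 1L)])
  seg <- x$samples[i0:i1] - baseline
  w <- round(peak_smooth * fs)
  peak_sig <- if (w >= 2L && length(seg) > w) {
    as.numeric(stats::filter(seg, rep(1 / w, w), sides = 2))
  } else seg
  list(amplitude = max(peak_sig, na.rm = TRUE),
       area = sum(pmax(seg, 0)) / fs,
       baseline = baseline, baseline_clipped = clipped)
}

#' Per-epoch burst summaries relative to baseline
#'
#' Aggregates respiratory bursts (primary-channel, coincident) within each
#' epoch window: burst frequency per minute, mean amplitude, mean area, and
#' each metric as a percent of its baseline-epoch value. Absolute amplitude
#' comparisons across preparations are meaningless for extracellular
#' integrated recordings, so only these within-preparation relative
#' summaries are produced.
#'
#' @param bursts Burst tibble from [detect_bursts()].
#' @param epochs Data frame with columns `epoch`, `start_s`, `end_s`
#'   (must include an epoch named `"baseline"`).
#' @param channel Channel whose coincident bursts are counted (default the
#'   vagal channel).
#' @return Tibble: `epoch`, `start_s`, `end_s`, `n_bursts`,
#'   `frequency_per_min`, `mean_amplitude`, `mean_area`, `pct_frequency`,
#'   `pct_amplitude`, `pct_area`, `baseline_empty`.
#' @export
epoch_compare <- function(bursts, epochs, channel = "neurogram_cnx") {
  stopifnot(all(c("epoch", "start_s", "end_s") %in% names(epochs)))
  if (!"baseline" %in% epochs$epoch) {
    abort("Epoch table must contain a 'baseline' epoch.",
          class = "synscale_usage_error")
  }
  resp <- bursts[bursts$channel == channel & bursts$coincident, , drop = FALSE]
  summ <- purrr::pmap_dfr(epochs[c("epoch", "start_s", "end_s")],
    function(epoch, start_s, end_s) {
      sel <- resp[resp$onset_s >= start_s & resp$onset_s < end_s, , drop = FALSE]
      n <- nrow(sel)
      tibble(epoch = epoch, start_s = start_s, end_s = end_s, n_bursts = n,
             frequency_per_min = n / ((end_s - start_s) / 60),
             mean_amplitude = if (n) mean(sel$amplitude) else NA_real_,
             mean_area = if (n) mean(sel$area) else NA_real_)
    })
  base <- summ[summ$epoch == "baseline", , drop = FALSE]
  empty <- base$n_bursts == 0L
  pct <- function(v, b) if (empty || is.na(b)) NA_real_ else 100 * v / b
  summ$pct_frequency <- vapply(summ$frequency_per_min, pct,
                               numeric(1), b = base$frequency_per_min)
  summ$pct_amplitude <- vapply(summ$mean_amplitude, pct, numeric(1),
                               b = base$mean_amplitude)
  summ$pct_area <- vapply(summ$mean_area, pct, numeric(1), b = base$mean_area)
  summ$baseline_empty <- empty
  summ
}

#' Plot an integrated neurogram with detected bursts
#'
#' @param x Integrated [trace()].
#' @param bursts Optional burst tibble (rows for this channel) to overlay.
#' @return A ggplot object.
#' @export
plot_neurogram <- function(x, bursts = NULL) {
  stopifnot(is_trace(x))
  df <- tibble(time_s = trace_times(x), value = x$samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time_s, y = value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "integrated activity (a.u.)")
  if (!is.null(bursts) && nrow(bursts)) {
    p <- p + ggplot2::geom_rect(
      data = bursts,
      ggplot2::aes(xmin = onset_s, xmax = offset_s, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "blue")
  }
  p
}
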