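#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

CHANNEL_ROLES <- c("vclamp_current", "cclamp_voltage",
                   "neurogram_cnx", "neurogram_snii")

#' Construct a sampled electrophysiology trace
#'
#' A `trace` is the package's basic time-series record: a uniformly sampled
#' single-channel signal with a sampling rate, a channel role that fixes the
#' unit interpretation, a start time, and free-form metadata. Internal units
#' are fixed throughout the package: pA for voltage-clamp current, mV for
#' current-clamp voltage, arbitrary integrated units for neurograms; time in
#' seconds, rates in Hz, resistances in megaohms.
#'
#' @param samples Numeric vector of samples (non-empty, finite).
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param channel_role One of `"vclamp_current"`, `"cclamp_voltage"`,
#'   `"neurogram_cnx"`, `"neurogram_snii"`.
#' @param t0 Start time of the first sample in seconds.
#' @param metadata Named list of free key-value metadata (neuron id, group
#'   label, drug epoch, ...).
#'
#' @return An object of class `synscale_trace`: a list with elements
#'   `samples`, `sampling_rate`, `channel_role`, `t0`, `metadata`.
#' @examples
#' tr <- trace(rnorm(1000), sampling_rate = 1000, channel_role = "vclamp_current")
#' trace_duration(tr)
#' @export
trace <- function(samples, sampling_rate, channel_role, t0 = 0,
                  metadata = list()) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    abort("`samples` must be a non-empty numeric vector.", class = "synscale_error")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a positive finite scalar (Hz).",
          class = "synscale_error")
  }
  channel_role <- match.arg(channel_role, CHANNEL_ROLES)
  if (!is.list(metadata) || (length(metadata) > 0L && is.null(names(metadata)))) {
    abort("`metadata` must be a named list.", class = "synscale_error")
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         channel_role = channel_role,
         t0 = as.numeric(t0),
         metadata = metadata),
    class = "synscale_trace"
  )
}

#' @export
print.synscale_trace <- function(x, ...) {
  cat(sprintf("<synscale_trace> %s: %d samples @ %g Hz (%.4g s)\n",
              x$channel_role, length(x$samples), x$sampling_rate,
              trace_duration(x)))
  if (length(x$metadata)) {
    cat("  metadata:",
        paste(names(x$metadata), unlist(x$metadata), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Trace duration in seconds
#'
#' Duration is defined as `n_samples / sampling_rate`.
#' @param x A `synscale_trace`.
#' @return Duration in seconds.
#' @export
trace_duration <- function(x) {
  stopifnot(inherits(x, "synscale_trace"))
  length(x$samples) / x$sampling_rate
}

#' Sample times of a trace
#'
#' @param x A `synscale_trace`.
#' @return Numeric vector of sample times in seconds (first sample at `t0`).
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "synscale_trace"))
  x$t0 + (seq_along(x$samples) - 1L) / x$sampling_rate
}

is_trace <- function(x) inherits(x, "synscale_trace")

assert_role <- function(x, role, what) {
  if (!is_trace(x)) {
    abort(sprintf("`%s` must be a synscale_trace.", what), class = "synscale_error")
  }
  if (!x$channel_role %in% role) {
    abort(sprintf("`%s` has channel role '%s'; expected %s.", what,
                  x$channel_role, paste(role, collapse = " or ")),
          class = "synscale_usage_error")
  }
  invisible(x)
}
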