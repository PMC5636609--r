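#' Rank-order pairing of two amplitude distributions
#'
#' Sorts both samples ascending and pairs them by rank index — the
#' equal-count quantile pairing used to test for multiplicative synaptic
#' scaling. The caller must supply equal counts (e.g. by pooling the first
#' 50 events per neuron from equally sized cohorts); unequal lengths are an
#' error, never silently subsampled. Sorting is stable, so ties keep their
#' original order.
#'
#' @param control_amps,treated_amps Numeric amplitude vectors of equal,
#'   non-zero length (pA).
#' @return Tibble with columns `control` and `treated`, both non-decreasing.
#' @export
rank_order <- function(control_amps, treated_amps) {
  if (length(control_amps) == 0L || length(treated_amps) == 0L) {
    abort("Amplitude vectors must be non-empty.", class = "synscale_usage_error")
  }
  if (length(control_amps) != length(treated_amps)) {
    abort(sprintf("Unequal lengths (%d vs %d); rank pairing needs equal counts.",
                  length(control_amps), length(treated_amps)),
          class = "synscale_usage_error")
  }
  tibble(control = sort(control_amps, method = "radix"),
         treated = sort(treated_amps, method = "radix"))
}

#' Linear fit to a rank-order plot
#'
#' Ordinary least squares of treated (y) on control (x). Under pure
#' multiplicative scaling the points fall on a line through the origin whose
#' slope is the scaling factor; a slope above 1 (the unity line) indicates
#' up-scaling. The intercept is fitted freely and reported so departures
#' from proportionality are visible.
#'
#' @param pairs Tibble from [rank_order()] (>= 3 rows).
#' @return List: `slope`, `intercept`, `r2`.
#' @export
fit_rank_linear <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 3L)
  if (stats::var(pairs$control) == 0) {
    abort("Degenerate control amplitudes (zero variance); cannot fit.",
          class = "synscale_fit_error")
  }
  fit <- stats::lm(treated ~ control, data = pairs)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = summary(fit)$r.squared)
}

#' Exponential fit to a rank-order plot
#'
#' Nonlinear least squares of `y = a * exp(b * x)`, initialized from a
#' log-linear regression, with the coefficient of determination computed on
#' the original scale. A rank-order relationship better described by an
#' exponential than a line is the signature of synapse-specific potentiation
#' (LTP-like) rather than uniform scaling. Non-convergence is reported as a
#' failed fit, not an exception.
#'
#' @param pairs Tibble from [rank_order()] (>= 4 rows, positive treated
#'   amplitudes).
#' @return List: `a`, `b`, `r2`, `converged`; on failure `a`, `b`, `r2` are
#'   `NA` and `message` holds the diagnostic.
#' @export
fit_rank_exponential <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 4L, all(pairs$treated > 0))
  loglin <- stats::lm(log(treated) ~ control, data = pairs)
  start <- list(a = exp(unname(stats::coef(loglin)[1L])),
                b = unname(stats::coef(loglin)[2L]))
  fit <- tryCatch(
    minpack.lm::nlsLM(treated ~ a * exp(b * control), data = pairs,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(a = NA_real_, b = NA_real_, r2 = NA_real_,
                converged = FALSE, message = conditionMessage(fit)))
  }
  pred <- stats::predict(fit)
  ss_res <- sum((pairs$treated - pred)^2)
  ss_tot <- sum((pairs$treated - mean(pairs$treated))^2)
  co <- stats::coef(fit)
  list(a = unname(co["a"]), b = unname(co["b"]),
       r2 = 1 - ss_res / ss_tot, converged = TRUE)
}

#' Down-scale a treated amplitude distribution
#'
#' Divides every amplitude by the scaling factor and removes scaled values
#' that fall below the detection threshold: amplitudes below the threshold
#' are not represented in the control distribution, so retaining them would
#' distort the distribution comparison.
#'
#' @param treated_amps Numeric amplitudes, pA.
#' @param factor Scaling factor (> 0), typically the rank-order slope.
#' @param threshold Detection threshold, pA (default 7.5).
#' @return Numeric vector of retained scaled amplitudes, with attribute
#'   `n_excluded` (count removed below threshold).
#' @export
downscale <- function(treated_amps, factor, threshold = 7.5) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    abort("`factor` must be a positive scalar.", class = "synscale_error")
  }
  scaled <- treated_amps / factor
  keep <- scaled >= threshold
  out <- scaled[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs. Under
#' `mode = "auto"` the p-value is exact when `n_a * n_b <= 1e4` and
#' asymptotic otherwise; the mode actually used is always recorded.
#'
#' @param a,b Non-empty numeric vectors.
#' @param mode `"exact"`, `"asymptotic"`, or `"auto"`.
#' @return Tibble row: `D`, `p`, `mode`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (length(a) == 0L || length(b) == 0L) {
    abort("KS comparison needs two non-empty samples.",
          class = "synscale_usage_error")
  }
  used <- switch(mode,
                 auto = if (length(a) * length(b) <= 1e4) "exact" else "asymptotic",
                 mode)
  kt <- suppressWarnings(
    stats::ks.test(a, b, exact = identical(used, "exact"))
  )
  tibble(D = unname(kt$statistic), p = kt$p.value, mode = used,
         n_a = length(a), n_b = length(b))
}

#' Full rank-order scaling analysis
#'
#' Runs the complete multiplicative-scaling procedure on per-neuron
#' amplitude lists: take the first `n_per_neuron` amplitudes from each
#' neuron, pool within group, rank-order the pooled equal-count samples, fit
#' both the linear and exponential models, down-scale the treated
#' distribution by the linear slope with sub-threshold exclusion, and run
#' the raw and down-scaled Kolmogorov-Smirnov comparisons. The analysis is
#' called multiplicative when the linear fit beats the exponential fit
#' (r-squared), the raw distributions differ (p < alpha), and the
#' down-scaled distribution no longer differs from control (p >= alpha).
#'
#' @param control_by_neuron,treated_by_neuron Lists of per-neuron numeric
#'   amplitude vectors (each time-ordered, as from [first_n_amplitudes()]
#'   inputs).
#' @param n_per_neuron Events pooled per neuron (default 50).
#' @param threshold Detection threshold for sub-threshold exclusion, pA.
#' @param alpha Significance level for the KS decisions.
#' @param ks_mode Passed to [ks_compare()].
#' @return Object of class `scaling_result`: list with `pairs`, `linear`,
#'   `exponential`, `scaling_factor`, `n_points`, `ks_raw`, `ks_downscaled`,
#'   `n_excluded_below_threshold`, `multiplicative`, `alpha`, `shortfall`.
#' @export
scaling_pipeline <- function(control_by_neuron, treated_by_neuron,
                             n_per_neuron = 50L, threshold = 7.5,
                             alpha = 0.05, ks_mode = "auto") {
  # keep the pooled counts equal by design: when any neuron falls short of
  # n_per_neuron, use the largest count every neuron can supply (flagged)
  n_avail <- vapply(c(control_by_neuron, treated_by_neuron), length, integer(1))
  if (any(n_avail == 0L)) {
    abort("Every neuron must contribute at least one amplitude.",
          class = "synscale_usage_error")
  }
  n_eff <- min(n_per_neuron, min(n_avail))
  take <- function(v) {
    ev <- tibble(onset_s = seq_along(v), amplitude_pA = as.numeric(v))
    first_n_amplitudes(ev, n_eff)
  }
  ctrl_l <- lapply(control_by_neuron, take)
  trt_l <- lapply(treated_by_neuron, take)
  shortfall <- n_eff < n_per_neuron
  ctrl <- unlist(ctrl_l, use.names = FALSE)
  trt <- unlist(trt_l, use.names = FALSE)
  pairs <- rank_order(ctrl, trt)
  lin <- fit_rank_linear(pairs)
  expf <- fit_rank_exponential(pairs)
  ds <- downscale(trt, lin$slope, threshold)
  ks_raw <- ks_compare(ctrl, trt, ks_mode)
  ks_ds <- ks_compare(ctrl, as.numeric(ds), ks_mode)
  structure(list(
    pairs = pairs,
    linear = lin,
    exponential = expf,
    scaling_factor = lin$slope,
    n_points = nrow(pairs),
    ks_raw = ks_raw,
    ks_downscaled = ks_ds,
    n_excluded_below_threshold = attr(ds, "n_excluded"),
    multiplicative = isTRUE(lin$r2 > (expf$r2 %||% -Inf)) &&
      ks_raw$p < alpha && ks_ds$p >= alpha,
    alpha = alpha,
    shortfall = shortfall,
    n_per_neuron_used = n_eff,
    control_amps = ctrl,
    treated_amps = trt,
    downscaled_amps = as.numeric(ds)
  ), class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("<scaling_result> %d rank-order points\n", x$n_points))
  cat(sprintf("  scaling factor (linear slope): %.3f (r2 = %.3f)\n",
              x$scaling_factor, x$linear$r2))
  if (isTRUE(x$exponential$converged)) {
    cat(sprintf("  exponential fit r2: %.3f\n", x$exponential$r2))
  } else {
    cat("  exponential fit: did not converge\n")
  }
  cat(sprintf("  KS raw: D = %.3f, p = %.3g (%s)\n",
              x$ks_raw$D, x$ks_raw$p, x$ks_raw$mode))
  cat(sprintf("  KS down-scaled: D = %.3f, p = %.3g (%s); %d excluded < threshold\n",
              x$ks_downscaled$D, x$ks_downscaled$p, x$ks_downscaled$mode,
              x$n_excluded_below_threshold))
  cat(sprintf("  multiplicative: %s\n", x$multiplicative))
  invisible(x)
}

#' Tidy a scaling result
#'
#' @param x A `scaling_result`.
#' @param ... Unused.
#' @return Tibble of model terms (linear slope/intercept, exponential a/b)
#'   with estimates.
#' @exportS3Method generics::tidy
tidy.scaling_result <- function(x, ...) {
  tibble(
    model = c("linear", "linear", "exponential", "exponential"),
    term = c("slope", "intercept", "a", "b"),
    estimate = c(x$linear$slope, x$linear$intercept,
                 x$exponential$a, x$exponential$b)
  )
}

#' One-row summary of a scaling result
#'
#' @param x A `scaling_result`.
#' @param ... Unused.
#' @return One-row tibble: scaling factor, fit r-squareds, KS statistics,
#'   exclusion count, multiplicative verdict.
#' @exportS3Method generics::glance
glance.scaling_result <- function(x, ...) {
  tibble(
    scaling_factor = x$scaling_factor,
    r2_linear = x$linear$r2,
    r2_exponential = x$exponential$r2,
    n_points = x$n_points,
    ks_raw_D = x$ks_raw$D, ks_raw_p = x$ks_raw$p,
    ks_downscaled_D = x$ks_downscaled$D, ks_downscaled_p = x$ks_downscaled$p,
    n_excluded_below_threshold = x$n_excluded_below_threshold,
    multiplicative = x$multiplicative
  )
}

#' Rank-order plot of a scaling result
#'
#' Ranked treated vs control amplitudes with the unity line, the linear
#' fit, and (when converged) the exponential fit.
#'
#' @param object A `scaling_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scaling_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$pairs, ggplot2::aes(x = control, y = treated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_abline(slope = object$linear$slope,
                         intercept = object$linear$intercept,
                         colour = "blue", linetype = "dashed") +
    ggplot2::labs(x = "control mEPSC amplitude (pA)",
                  y = "treated mEPSC amplitude (pA)",
                  title = sprintf("Rank-order plot: slope %.2f (r2 %.2f)",
                                  object$linear$slope, object$linear$r2))
  if (isTRUE(object$exponential$converged)) {
    grid <- tibble(control = seq(min(object$pairs$control),
                                 max(object$pairs$control), length.out = 200))
    grid$treated <- object$exponential$a * exp(object$exponential$b * grid$control)
    p <- p + ggplot2::geom_line(data = grid, colour = "black",
                                linetype = "dashed")
  }
  p
}

#' Cumulative-distribution plot for a scaling result
#'
#' Empirical CDFs of the control, treated, and down-scaled treated
#' amplitude distributions — the standard view of a multiplicative-scaling
#' test.
#'
#' @param x A `scaling_result`.
#' @return A ggplot object.
#' @export
plot_scaling_cdf <- function(x) {
  stopifnot(inherits(x, "scaling_result"))
  df <- dplyr::bind_rows(
    tibble(amplitude_pA = x$control_amps, distribution = "control"),
    tibble(amplitude_pA = x$treated_amps, distribution = "treated"),
    tibble(amplitude_pA = x$downscaled_amps, distribution = "down-scaled")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = amplitude_pA, colour = distribution)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "mEPSC amplitude (pA)", y = "cumulative probability")
}
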