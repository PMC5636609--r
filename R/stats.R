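test_result <- function(test, statistic, df, p, tails, n_a, n_b, notes = "") {
  tibble(test = test, statistic = statistic, df = df, p = p, tails = tails,
         n_a = n_a, n_b = n_b, notes = notes)
}

#' Two-tailed unpaired t test
#'
#' Student's t (pooled variance, df = n_a + n_b - 2) or, with
#' `welch = TRUE`, Welch's unequal-variance t with Welch-Satterthwaite
#' degrees of freedom. `welch = "auto"` applies Welch's correction when an
#' F test of the two variances rejects at the 0.05 level — provided for
#' convenience but never the default, so analyses stay reproducible. Two
#' zero-variance samples with equal means return t = 0, p = 1 by
#' convention (noted).
#'
#' @param a,b Numeric samples (>= 2 each).
#' @param welch `FALSE` (Student), `TRUE` (Welch), or `"auto"`.
#' @return One-row TestResult tibble: `test`, `statistic`, `df`, `p`,
#'   `tails`, `n_a`, `n_b`, `notes`.
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  notes <- ""
  if (identical(welch, "auto")) {
    vt <- stats::var.test(a, b)
    welch <- vt$p.value < 0.05
    notes <- sprintf("auto variance check: F p=%.3g -> %s", vt$p.value,
                     if (welch) "Welch" else "Student")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(test_result("unpaired_t", if (eq) 0 else Inf,
                       length(a) + length(b) - 2, if (eq) 1 else 0,
                       "two", length(a), length(b),
                       "degenerate: zero variance in both groups"))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  test_result(if (welch) "unpaired_t_welch" else "unpaired_t",
              unname(tt$statistic), unname(tt$parameter), tt$p.value,
              "two", length(a), length(b),
              paste0(notes, if (welch) " Welch correction applied" else ""))
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value when both samples have at most 8 observations and no ties
#' are present; otherwise the normal approximation with continuity and tie
#' correction. The mode used is always recorded. The statistic is the
#' Mann-Whitney U for the first sample.
#'
#' @param a,b Numeric samples (>= 1 each).
#' @param exact_max Per-group size at or below which the exact distribution
#'   is used (ties permitting).
#' @return One-row TestResult tibble.
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  test_result("mann_whitney", unname(wt$statistic), NA_real_, wt$p.value,
              "two", length(a), length(b),
              if (exact) "exact" else
                paste0("normal approximation", if (ties) " (ties)" else ""))
}

#' Two-tailed paired t test
#'
#' t test on the within-pair differences, df = n - 1. Differences with zero
#' standard deviation are reported as degenerate (infinite t when the mean
#' difference is non-zero; t = 0, p = 1 when all differences vanish).
#'
#' @param before,after Numeric vectors of equal length (>= 2).
#' @return One-row TestResult tibble.
#' @export
paired_t <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2L)
  d <- after - before
  n <- length(d)
  if (stats::sd(d) == 0) {
    zero <- isTRUE(all.equal(mean(d), 0))
    return(test_result("paired_t", if (zero) 0 else Inf * sign(mean(d)),
                       n - 1, if (zero) 1 else 0, "two", n, n,
                       "degenerate: zero-variance differences"))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  test_result("paired_t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, "two", n, n, "")
}

#' Homogeneity-of-slopes ANCOVA
#'
#' Fits the linear model `y ~ x + group + x:group` over the pooled
#' per-neuron series and reads "the slopes differ" from the F test of the
#' `x:group` interaction. Requires at least two series per group; a
#' collinear design is an explicit error.
#'
#' @param data Data frame with columns `x`, `y`, `group` (2 levels), and
#'   optionally `neuron` (series identifier, used only to check the
#'   two-series-per-group precondition when present).
#' @return One-row TestResult tibble (`statistic` is the interaction F;
#'   `df` the interaction's denominator df; `notes` records numerator df).
#' @export
ancova_slopes <- function(data) {
  stopifnot(all(c("x", "y", "group") %in% names(data)))
  data$group <- factor(data$group)
  if (nlevels(data$group) != 2L) {
    abort("ANCOVA comparison needs exactly two groups.",
          class = "synscale_usage_error")
  }
  if ("neuron" %in% names(data)) {
    per <- table(unique(data[c("neuron", "group")])$group)
    if (any(per < 2L)) {
      abort("Need at least 2 series per group.", class = "synscale_usage_error")
    }
  }
  fit <- stats::lm(y ~ x * group, data = data)
  if (anyNA(stats::coef(fit))) {
    abort("Singular ANCOVA design (collinear predictors).",
          class = "synscale_error")
  }
  an <- stats::anova(fit)
  row <- which(rownames(an) == "x:group")
  test_result("ancova_interaction", an$`F value`[row], an$Df[nrow(an)],
              an$`Pr(>F)`[row], "two",
              sum(data$group == levels(data$group)[1]),
              sum(data$group == levels(data$group)[2]),
              sprintf("num df=%d", an$Df[row]))
}
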