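test_that("rank_order pairs sorted values and rejects unequal lengths", {
  p <- rank_order(c(3, 1, 2), c(6, 2, 4))
  expect_equal(p$control, c(1, 2, 3))
  expect_equal(p$treated, c(2, 4, 6))
  ident <- rank_order(c(5, 1, 3), c(5, 1, 3))
  expect_equal(ident$control, ident$treated)
  expect_error(rank_order(rnorm(800), rnorm(799)),
               class = "synscale_usage_error")
  expect_error(rank_order(numeric(0), numeric(0)),
               class = "synscale_usage_error")
})

test_that("linear rank fit recovers exact lines", {
  x <- seq(5, 50, length.out = 20)
  f1 <- fit_rank_linear(tibble::tibble(control = x, treated = x))
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-10)
  expect_equal(f1$r2, 1, tolerance = 1e-12)
  f2 <- fit_rank_linear(tibble::tibble(control = x, treated = 2 * x))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_error(fit_rank_linear(tibble::tibble(control = rep(1, 5),
                                              treated = 1:5)),
               class = "synscale_fit_error")
})

test_that("exponential rank fit recovers exact parameters and loses to the
           line under pure scaling", {
  x <- seq(5, 40, length.out = 30)
  fe <- fit_rank_exponential(tibble::tibble(control = x,
                                            treated = 2 * exp(0.1 * x)))
  expect_true(fe$converged)
  expect_equal(fe$a, 2, tolerance = 1e-6)
  expect_equal(fe$b, 0.1, tolerance = 1e-6)
  expect_equal(fe$r2, 1, tolerance = 1e-8)
  # pure multiplicative pairs over a wide range: linear wins
  set.seed(8)
  a <- sort(rlnorm(400, log(18), 0.45))
  b <- sort(1.51 * rlnorm(400, log(18), 0.45))
  pairs <- tibble::tibble(control = a, treated = b)
  expect_lt(fit_rank_exponential(pairs)$r2, fit_rank_linear(pairs)$r2)
})

test_that("LTP-like potentiation breaks the linear rank-order signature", {
  # synapse-specific potentiation (random 30% of synapses x3) bends the
  # rank-order plot: the linear fit deteriorates sharply relative to pure
  # scaling and the multiplicative verdict is rejected
  res <- vapply(1:40, function(s) {
    set.seed(s)
    ctl <- lapply(1:8, function(i) rlnorm(50, log(18), 0.45))
    trt <- lapply(1:8, function(i) {
      a <- rlnorm(50, log(18), 0.45)
      hit <- runif(50) < 0.3
      a[hit] <- a[hit] * 3
      a
    })
    r <- scaling_pipeline(ctl, trt)
    c(r2 = r$linear$r2, multiplicative = r$multiplicative)
  }, numeric(2))
  expect_lt(median(res["r2", ]), 0.99)
  expect_lt(mean(res["multiplicative", ]), 0.5)
})

test_that("downscale divides, truncates at threshold, and counts exclusions", {
  out <- downscale(c(15.1, 30.2), 1.51)
  expect_equal(as.numeric(out), c(10, 20), tolerance = 1e-12)
  expect_equal(attr(out, "n_excluded"), 0L)
  out2 <- downscale(9.0, 1.51)
  expect_length(out2, 0L)            # 9/1.51 = 5.96 < 7.5
  expect_equal(attr(out2, "n_excluded"), 1L)
  x <- c(8, 12, 40)
  out3 <- downscale(x, 1)
  expect_equal(as.numeric(out3), x)
  expect_error(downscale(x, 0), class = "synscale_error")
})

test_that("downscale inverts scaling exactly above the scaled threshold", {
  set.seed(42)
  for (k in c(1.2, 1.51, 2.7)) {
    x <- runif(200, 7.5 * k, 80)
    expect_equal(as.numeric(downscale(x * k, k)), as.numeric(x),
                 tolerance = 1e-12)
    expect_equal(attr(downscale(x * k, k), "n_excluded"), 0L)
  }
})

test_that("scale equivariance: scaling treated amplitudes scales the slope", {
  set.seed(7)
  a <- rlnorm(300, log(18), 0.45)
  b <- rlnorm(300, log(18), 0.45)
  s1 <- fit_rank_linear(rank_order(a, b))$slope
  for (c_ in c(0.5, 2, 3.3)) {
    sc <- fit_rank_linear(rank_order(a, c_ * b))$slope
    expect_equal(sc, c_ * s1, tolerance = 1e-10)
  }
})

test_that("ks_compare matches known small-sample results", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  r <- ks_compare(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r$D, 1)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_error(ks_compare(numeric(0), 1:3), class = "synscale_usage_error")
  big <- ks_compare(rnorm(200), rnorm(200))
  expect_equal(big$mode, "asymptotic")
})

test_that("scaling pipeline separates scaled cohorts and restores them by
           down-scaling", {
  set.seed(31)
  ctl <- lapply(1:16, function(i) rlnorm(60, log(18), 0.45))
  trt <- lapply(1:16, function(i) 1.51 * rlnorm(60, log(18), 0.45))
  res <- scaling_pipeline(ctl, trt)
  expect_s3_class(res, "scaling_result")
  expect_equal(res$n_points, 800L)
  expect_equal(res$scaling_factor, 1.51, tolerance = 0.12)
  expect_lt(res$ks_raw$p, 1e-6)
  expect_gt(res$ks_downscaled$p, 0.05)
  expect_true(res$multiplicative)
  # null case: factor 1 gives no significant difference, flag false
  trt1 <- lapply(1:16, function(i) rlnorm(60, log(18), 0.45))
  res1 <- scaling_pipeline(ctl, trt1)
  expect_false(res1$multiplicative)
  expect_gt(res1$ks_raw$p, 0.001)
})

test_that("tidy, glance and autoplot expose the scaling result", {
  set.seed(5)
  ctl <- lapply(1:4, function(i) rlnorm(55, log(18), 0.45))
  trt <- lapply(1:4, function(i) 1.5 * rlnorm(55, log(18), 0.45))
  res <- scaling_pipeline(ctl, trt)
  td <- generics::tidy(res)
  expect_equal(nrow(td), 4L)
  gl <- generics::glance(res)
  expect_equal(gl$scaling_factor, res$scaling_factor)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(plot_scaling_cdf(res), "ggplot")
})
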