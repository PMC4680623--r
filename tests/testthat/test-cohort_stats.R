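test_that("pooled pore histograms merge by concatenation on shared bins", {
  d1 <- c(50, 150, 150, 250)
  h <- merge_pore_histograms(list(d1), list(d1), 100)
  expect_identical(h$T0$counts, h$T1$counts)
  expect_identical(h$T0$edges, h$T1$edges)

  d2 <- c(40, 260)
  pooled <- merge_pore_histograms(list(d1, d2), list(d1), 100)
  single1 <- mct_hist(d1, edges = pooled$T0$edges)
  single2 <- mct_hist(d2, edges = pooled$T0$edges)
  expect_equal(pooled$T0$counts, single1$counts + single2$counts)

  set.seed(6)
  lists0 <- replicate(4, runif(30, 10, 590), simplify = FALSE)
  lists1 <- replicate(3, runif(40, 10, 640), simplify = FALSE)
  hh <- merge_pore_histograms(lists0, lists1, 10)
  expect_equal(hh$T0$counts,
               mct_hist(unlist(lists0), edges = hh$T0$edges)$counts)
  expect_equal(sum(hh$T1$counts), 120)

  expect_error(merge_pore_histograms(list(), list(d1), 10), "empty")
})

test_that("the histogram delta is the signed follow-up minus baseline", {
  e <- seq(0, 50, 10)
  a <- mct_hist(edges = e, counts = c(1, 2, 3, 4, 5))
  b <- mct_hist(edges = e, counts = c(5, 4, 3, 2, 1))
  expect_equal(delta_histogram(a, a)$counts, rep(0, 5))
  z <- mct_hist(edges = e, counts = rep(0, 5))
  expect_equal(delta_histogram(a, z)$counts, -a$counts)
  expect_equal(delta_histogram(a, b)$counts, -delta_histogram(b, a)$counts)
  expect_error(delta_histogram(a, mct_hist(edges = seq(0, 100, 20),
                                           counts = rep(1, 5))), "differ")
})

test_that("the empirical CDF is nondecreasing with terminal value one", {
  e <- seq(0, 40, 10)
  single <- empirical_cdf(mct_hist(edges = e, counts = c(0, 7, 0, 0)))
  expect_equal(single$cdf, c(0, 1, 1, 1))

  unif <- empirical_cdf(mct_hist(edges = e, counts = rep(3, 4)))
  expect_equal(unif$cdf, (1:4) / 4)

  set.seed(10)
  r <- empirical_cdf(mct_hist(edges = seq(0, 200, 10),
                              counts = rpois(20, 4)))
  expect_true(all(diff(r$cdf) >= 0))
  expect_equal(r$cdf[length(r$cdf)], 1)
  expect_error(empirical_cdf(mct_hist(edges = e, counts = rep(0, 4))),
               "empty")
})

test_that("the log-CDF fit recovers exact exponentials and matches the normal equations", {
  e <- seq(0, 100, 10)
  mids <- (e[-1] + e[-11]) / 2
  a <- -0.03; b <- -0.2
  cdf <- structure(list(edges = e, mids = mids,
                        cdf = exp(a * mids + b)), class = "mct_cdf")
  fit <- log_cdf_slope(cdf, fit_range = 1:10)
  expect_equal(unname(fit["slope"]), a, tolerance = 1e-10)
  expect_equal(unname(fit["intercept"]), b, tolerance = 1e-10)

  two <- structure(list(edges = e[1:3], mids = mids[1:2],
                        cdf = c(0.2, 0.8)), class = "mct_cdf")
  f2 <- log_cdf_slope(two, fit_range = 1:2)
  expect_equal(f2[["slope"]] * mids[1] + f2[["intercept"]], log(0.2))
  expect_equal(f2[["slope"]] * mids[2] + f2[["intercept"]], log(0.8))

  set.seed(14)
  noisy <- pmin(exp(a * mids + b) * exp(rnorm(10, 0, 0.05)), 1)
  cn <- structure(list(edges = e, mids = mids, cdf = noisy),
                  class = "mct_cdf")
  fr <- 1:5                       # default: first half of the bins
  fn <- log_cdf_slope(cn)
  X <- cbind(1, mids[fr]); y <- log(noisy[fr])
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fn["intercept"]), beta[1L], tolerance = 1e-10)
  expect_equal(unname(fn["slope"]), beta[2L], tolerance = 1e-10)

  expect_error(log_cdf_slope(structure(list(edges = e, mids = mids,
                                            cdf = c(0, 0, 0, 0.1, rep(1, 6))),
                                       class = "mct_cdf"),
                             fit_range = 1:3), "fewer than 2")
})

test_that("attenuation histograms pool across constructs and difference across time", {
  h1 <- mct_hist(c(10.2, 11.5, 12.7), edges = 10:14)
  h2 <- mct_hist(c(12.1, 13.9), edges = 12:15)
  pooled <- hu_histogram(list(h1, h2), list(h1))
  expect_equal(sum(pooled$T0$counts), 5)
  expect_equal(sum(pooled$T1$counts), 3)
  expect_equal(pooled$delta$counts, pooled$T1$counts - pooled$T0$counts)

  same <- hu_histogram(list(h1), list(h1))
  expect_true(all(same$delta$counts == 0))
  expect_error(hu_histogram(list(), list(h1)), "missing")
})

test_that("paired comparisons route by Shapiro-Wilk and match a textbook t computation", {
  set.seed(42)
  t0 <- rnorm(10, 100, 5)
  t1 <- t0 + 4 + rnorm(10, 0, 1)
  res <- paired_compare(t0, t1, parameter = "SV")
  expect_true(all(res$normality_p >= 0.05))   # this seed yields normal calls
  expect_identical(res$test_used, "paired_t")
  d <- t1 - t0
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(tstat), df = length(d) - 1)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_true(res$significant)

  set.seed(7)
  h0 <- exp(rnorm(12, 0, 1.5))^3            # heavy-tailed
  h1 <- h0 * exp(rnorm(12, 0, 0.1))
  resw <- paired_compare(h0, h1)
  expect_true(any(resw$normality_p < 0.05))
  expect_identical(resw$test_used, "wilcoxon_signed_rank")

  # route is a pure function of the normality p-values
  for (s in 1:6) {
    set.seed(s)
    a <- rnorm(8); b <- rnorm(8)
    r <- paired_compare(a, b)
    expect_identical(r$test_used,
                     if (all(r$normality_p >= 0.05)) "paired_t"
                     else "wilcoxon_signed_rank")
  }

  ident <- paired_compare(t0, t0)
  expect_true(ident$degenerate)
  expect_false(ident$significant)
  expect_equal(ident$p_value, 1)

  expect_error(paired_compare(1:4, 1:5), "unmatched")
  expect_error(paired_compare(1:2, 2:3), "3 matched pairs")
})

test_that("normality can alternatively be tested on the paired differences", {
  set.seed(3)
  t0 <- exp(rnorm(10, 3, 1))        # lognormal samples ...
  t1 <- t0 + rnorm(10, 0, 1)        # ... but normal differences
  r <- paired_compare(t0, t1, normality_on = "differences")
  expect_named(r$normality_p, "diff")
  expect_identical(r$test_used,
                   if (r$normality_p >= 0.05) "paired_t"
                   else "wilcoxon_signed_rank")
})

test_that("the cross-tool deviation is zero at equality and antisymmetric", {
  expect_identical(deviation_metric(7, 7), 0)
  expect_equal(deviation_metric(3, 1), -0.25)
  set.seed(19)
  for (i in 1:25) {
    a <- runif(1, 1e-3, 1e9); b <- runif(1, 1e-3, 1e9)
    expect_equal(deviation_metric(a, b) + deviation_metric(b, a), 0)
  }
  expect_error(deviation_metric(0, 1), "positive")
  expect_error(deviation_metric(1, -2), "positive")
})
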