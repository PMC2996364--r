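# The pairwise agreement suite: moments, CCC, decomposition, TDI, CP, ICC,
# Bland-Altman, normality.

test_that("moment summary matches hand arithmetic under the 1/n convention", {
  ms <- moment_summary(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ms$x_bar, 2)
  expect_equal(ms$sx2, 2 / 3)
  expect_equal(ms$sxy, 2 / 3)
  expect_equal(ms$msd, 0)

  ms <- moment_summary(c(0, 1, 2), c(1, 2, 3))
  expect_equal(ms$mu_d, -1)
  expect_equal(ms$sigma_d2, 0)
  expect_equal(ms$msd, 1)
  expect_equal(ms$v, 1)
  expect_equal(ms$u, -1 / sqrt(sqrt(2 / 3) * sqrt(2 / 3)))

  # n-1 convention rescales second moments only
  ms1 <- moment_summary(c(0, 1, 2), c(1, 2, 3), denominator = "n_minus_1")
  expect_equal(ms1$sx2, 1)
  expect_equal(ms1$mu_d, -1)

  expect_error(moment_summary(c(1, 2), c(1, 2)),
               class = "ccq_validation_error")
  expect_error(moment_summary(c(1, NA, 3), c(1, 2, 3)),
               class = "ccq_validation_error")
})

test_that("msd identity mu_d^2 + sigma_d2 holds on random pairs", {
  set.seed(21)
  for (i in 1:200) {
    p <- paired_normal(sample(3:40, 1), a = runif(1, -1, 1),
                       b = runif(1, 0.5, 2))
    ms <- moment_summary(p$x, p$y)
    expect_lt(abs(ms$msd - (ms$mu_d^2 + ms$sigma_d2)), 1e-12)
    expect_lt(abs(ms$msd - mean((p$x - p$y)^2)), 1e-10)
  }
})

test_that("CCC reproduces the worked examples of the printed formula", {
  set.seed(4)
  x <- rnorm(20)
  expect_equal(ccc(x, x)$estimate, 1)

  est <- ccc(c(0, 1, 2), c(1, 2, 3))$estimate
  expect_lt(abs(est - 4 / 7), 1e-12)
  # the n-1 convention changes the estimate on the same triple
  expect_lt(abs(ccc(c(0, 1, 2), c(1, 2, 3),
                    denominator = "n_minus_1")$estimate - 2 / 3), 1e-12)

  expect_equal(ccc(c(0, 1, 2), c(2, 1, 0))$estimate, -1)

  expect_error(ccc(c(1, 1, 1), c(0, 1, 2)), class = "ccq_validation_error")
})

test_that("precision/accuracy decompose the CCC exactly", {
  x <- c(0, 1, 2); y <- c(1, 2, 3)
  pa <- precision_accuracy(x, y)
  expect_equal(pa$precision, 1)
  expect_lt(abs(pa$accuracy - 4 / 7), 1e-12)

  # y = 2x with zero means: v = 1/2, u = 0, Cb = 2/(1/2 + 2) = 0.8
  x0 <- c(-1, 0, 1); y0 <- 2 * x0
  pa0 <- precision_accuracy(x0, y0)
  expect_equal(pa0$precision, 1)
  expect_equal(pa0$accuracy, 0.8)

  set.seed(31)
  for (i in 1:1000) {
    p <- paired_normal(sample(4:30, 1), a = runif(1, -2, 2),
                       b = runif(1, 0.3, 3))
    pa <- precision_accuracy(p$x, p$y)
    cc <- ccc(p$x, p$y)$estimate
    expect_lt(abs(pa$precision * pa$accuracy - cc), 1e-12)
    expect_true(pa$accuracy > 0 && pa$accuracy <= 1)
    expect_true(abs(cc) <= abs(pa$precision) + 1e-12)
    expect_true(abs(pa$precision) <= 1 + 1e-12)
  }
})

test_that("confidence limits are one-sided in the unfavourable direction", {
  set.seed(41)
  p <- paired_normal(44, sd_x = 0.4, sd_y = 0.4)
  cc <- ccc(p$x, p$y)
  expect_lt(cc$lower, cc$estimate)
  expect_true(is.na(cc$upper))
  two <- ccc(p$x, p$y, ci = "two-sided")
  expect_lt(two$lower, two$estimate)
  expect_gt(two$upper, two$estimate)
  # one-sided 95% lower limit is tighter than the two-sided one
  expect_gt(cc$lower, two$lower)

  td <- tdi(p$x, p$y)
  expect_gt(td$upper, td$estimate)
  cp <- coverage_prob(p$x, p$y)
  expect_lt(cp$lower, cp$estimate)
  pa <- precision_accuracy(p$x, p$y)
  expect_lt(pa$precision_lower, pa$precision)
  expect_lt(pa$accuracy_lower, pa$accuracy)
  ic <- icc(p$x, p$y)
  expect_lt(ic$lower, ic$estimate)
})

test_that("TDI follows the normal-approximation and exact quantile forms", {
  set.seed(5)
  x <- rnorm(10)
  td <- tdi(x, x)
  expect_equal(td$estimate, 0)
  expect_equal(td$upper, 0)

  # population check: differences ~ N(0,1) => TDI_0.9 = 1.6449
  n <- 400
  d <- exact_sd_vector(n, 1)
  p <- pairs_with_diffs(d, x = rnorm(n))
  expect_equal(tdi(p$x, p$y, p = 0.9)$estimate, qnorm(0.95),
               tolerance = 1e-6)
  # exact mode agrees with the approximation when mu_d = 0
  expect_equal(tdi(p$x, p$y, p = 0.9, mode = "exact")$estimate,
               tdi(p$x, p$y, p = 0.9)$estimate, tolerance = 1e-6)

  # monotone nondecreasing in p
  set.seed(6)
  q <- paired_normal(30, a = 0.5)
  ps <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  ests <- vapply(ps, function(pp) tdi(q$x, q$y, p = pp)$estimate, numeric(1))
  expect_true(all(diff(ests) >= 0))
  exacts <- vapply(ps, function(pp) tdi(q$x, q$y, p = pp,
                                        mode = "exact")$estimate, numeric(1))
  expect_true(all(diff(exacts) >= 0))

  # the two modes diverge when |mu_d| dominates sigma_d
  big <- pairs_with_diffs(2 + 0.05 * exact_sd_vector(50, 1), x = rnorm(50))
  expect_gt(abs(tdi(big$x, big$y)$estimate -
                  tdi(big$x, big$y, mode = "exact")$estimate), 0.1)

  expect_error(tdi(q$x, q$y, p = 1.2), class = "ccq_validation_error")
})

test_that("CP matches the normal CDF on fitted moments", {
  # construct mu_d = 0, sigma_d = 0.4 exactly (1/n convention)
  set.seed(8)
  n <- 60
  d <- exact_sd_vector(n, 0.4)
  p <- pairs_with_diffs(d, x = rnorm(n))
  cp <- coverage_prob(p$x, p$y, delta = 0.4)
  expect_equal(cp$estimate, pnorm(1) - pnorm(-1), tolerance = 1e-10)

  # delta = 0 gives an empty interval; large delta reaches full coverage
  expect_equal(coverage_prob(p$x, p$y, delta = 0)$estimate, 0)
  expect_equal(coverage_prob(p$x, p$y, delta = 100)$estimate, 1,
               tolerance = 1e-9)

  # monotone nondecreasing in delta
  deltas <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  ests <- vapply(deltas,
                 function(dd) coverage_prob(p$x, p$y, delta = dd)$estimate,
                 numeric(1))
  expect_true(all(diff(ests) >= 0))

  # constant differences: indicator of |mu_d| < delta, flagged degenerate
  q <- pairs_with_diffs(rep(0.3, 10), x = rnorm(10))
  cp0 <- coverage_prob(q$x, q$y, delta = 0.4)
  expect_true(cp0$degenerate)
  expect_equal(cp0$estimate, 1)
  expect_equal(coverage_prob(q$x, q$y, delta = 0.2)$estimate, 0)
})

test_that("ICC(A,1) mean squares agree with stats::aov and perfect agreement gives 1", {
  set.seed(9)
  x <- rnorm(25); y <- x + rnorm(25, 0.2, 0.5)
  ic <- icc(x, y)
  long <- data.frame(score = c(x, y),
                     subject = factor(rep(1:25, 2)),
                     rater = factor(rep(1:2, each = 25)))
  ms <- anova(aov(score ~ subject + rater, data = long))[["Mean Sq"]]
  expect_equal(ic$msr, ms[1])
  expect_equal(ic$msc, ms[2])
  expect_equal(ic$mse, ms[3])

  expect_equal(icc(x, x)$estimate, 1)
  expect_error(icc(rep(2, 10), rep(2, 10)), class = "ccq_validation_error")

  # independent series: estimate near zero at large n
  set.seed(10)
  a <- rnorm(4000); b <- rnorm(4000)
  expect_lt(abs(icc(a, b)$estimate), 0.05)
})

test_that("agreement categories follow the published cutoffs", {
  expect_equal(categorize_agreement(0.87), "excellent")
  expect_equal(categorize_agreement(0.74), "good")
  expect_equal(categorize_agreement(0.81), "excellent")
  expect_equal(categorize_agreement(0.80), "good")
  expect_equal(categorize_agreement(0.61), "good")
  expect_equal(categorize_agreement(0.60), "moderate")
  expect_equal(categorize_agreement(0.41), "moderate")
  expect_equal(categorize_agreement(0.40), "poor to fair")
  expect_equal(categorize_agreement(-0.5), "poor to fair")
  expect_error(categorize_agreement(1.2), class = "ccq_validation_error")
})

test_that("Bland-Altman quantities and the strict MCID band are right", {
  set.seed(12)
  x <- rnorm(10)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$within_mcid_fraction, 1)

  ba <- bland_altman(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5), delta = 0.4)
  expect_equal(ba$bias, -0.5)
  expect_equal(ba$within_mcid_fraction, 0)

  p <- pairs_with_diffs(c(0.1, -0.2, 0.3, 0.9))
  ba <- bland_altman(p$x, p$y, delta = 0.4)
  expect_equal(ba$within_mcid_fraction, 0.75)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  # strictness: a difference exactly at delta does not count as within
  # (pairs chosen so the differences are exactly representable)
  expect_equal(bland_altman(c(0.4, 0.4, 0.4, 0), c(0, 0, 0, 0),
                            delta = 0.4)$within_mcid_fraction,
               0.25)
})

test_that("Shapiro-Wilk gate passes normal data and fails skewed data", {
  pass <- vapply(1:100, function(s) {
    set.seed(s)
    normality_check(rnorm(100))$normal
  }, logical(1))
  expect_gte(mean(pass), 0.9)

  fail <- vapply(1:100, function(s) {
    set.seed(s)
    !normality_check(rnorm(200)^2)$normal
  }, logical(1))
  expect_gte(mean(fail), 0.9)

  expect_error(normality_check(rep(1, 10)), class = "ccq_validation_error")
})

test_that("suite is symmetric in x and y; bias changes sign", {
  set.seed(13)
  for (i in 1:20) {
    p <- paired_normal(25, a = runif(1, -1, 1), b = runif(1, 0.5, 2))
    expect_equal(ccc(p$x, p$y)$estimate, ccc(p$y, p$x)$estimate)
    expect_equal(tdi(p$x, p$y)$estimate, tdi(p$y, p$x)$estimate)
    expect_equal(coverage_prob(p$x, p$y)$estimate,
                 coverage_prob(p$y, p$x)$estimate)
    expect_equal(icc(p$x, p$y)$estimate, icc(p$y, p$x)$estimate)
    expect_equal(bland_altman(p$x, p$y)$bias, -bland_altman(p$y, p$x)$bias)
  }
})

test_that("location shifts hit accuracy only; common rescaling hits TDI only", {
  set.seed(14)
  x <- rnorm(40, 2, 1)
  y <- x + rnorm(40, 0, 0.3)
  base_cc <- ccc(x, y)$estimate
  base_pa <- precision_accuracy(x, y)

  for (c_shift in c(-0.8, 0.5, 1.5)) {
    cc2 <- ccc(x, y + c_shift)$estimate
    pa2 <- precision_accuracy(x, y + c_shift)
    expect_lt(cc2, base_cc)                       # accuracy penalty
    expect_equal(pa2$precision, base_pa$precision) # precision untouched
    expect_lt(pa2$accuracy, base_pa$accuracy)
  }

  for (k in c(0.5, 3)) {
    expect_equal(ccc(k * x, k * y)$estimate, base_cc)
    expect_equal(precision_accuracy(k * x, k * y)$accuracy,
                 base_pa$accuracy)
    expect_equal(icc(k * x, k * y)$estimate, icc(x, y)$estimate)
    expect_equal(tdi(k * x, k * y)$estimate, k * tdi(x, y)$estimate)
  }
})

test_that("CP and exact TDI match their Monte-Carlo oracles", {
  set.seed(15)
  n <- 1e6
  mu_d <- 0.15; sd_d <- 0.5
  d <- rnorm(n, mu_d, sd_d)
  p <- pairs_with_diffs(d, x = rnorm(n, 2, 1))
  cp <- coverage_prob(p$x, p$y, delta = 0.4)$estimate
  expect_lt(abs(cp - mean(abs(d) < 0.4)), 0.005)
  td <- tdi(p$x, p$y, p = 0.9, mode = "exact")$estimate
  expect_lt(abs(td - unname(quantile(abs(d), 0.9))), 0.01)
})

test_that("bundled agreement estimate is internally consistent", {
  set.seed(16)
  p <- paired_normal(44, sd_x = 0.4, sd_y = 0.4)
  e <- agreement_estimate(p$x, p$y)
  expect_lt(abs(e$ccc - e$precision * e$accuracy), 1e-12)
  expect_equal(e$ccc, ccc(p$x, p$y)$estimate)
  expect_equal(e$tdi, tdi(p$x, p$y)$estimate)
  expect_equal(e$cp, coverage_prob(p$x, p$y)$estimate)
  expect_equal(e$icc, icc(p$x, p$y)$estimate)
  expect_equal(e$category, categorize_agreement(e$ccc))
  expect_true(e$cp >= 0 && e$cp <= 1)
  expect_gte(e$tdi, 0)
})
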