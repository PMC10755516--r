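test_that("cycle-1 extrapolation and observed accumulation behave linearly", {
  expect_equal(predict_cumulative(0.090, 44.4), 3.996)
  expect_equal(predict_cumulative(0.43, 44.4), 19.092)
  expect_identical(predict_cumulative(0, 1000), 0)
  expect_error(predict_cumulative(-0.1, 44.4), "invalid input")

  expect_equal(observed_cumulative(rep(2.5, 6)), 15)
  set.seed(42)
  v <- runif(6, 0, 3)
  expect_equal(observed_cumulative(v), sum(v), tolerance = 1e-15)
  expect_error(observed_cumulative(numeric()), "insufficient data")

  # identical per-cycle kinetics: observed equals predicted exactly
  d1 <- 0.31
  expect_equal(observed_cumulative(rep(d1 * 7.4, 6)),
               predict_cumulative(d1, 44.4), tolerance = 1e-12)
})

test_that("relative difference reproduces the printed sign convention", {
  expect_equal(relative_difference(19, 15), 26.6667, tolerance = 1e-4)
  expect_equal(relative_difference(4.7, 2.5), 88.0)
  expect_equal(relative_difference(3, 3), 0)
  expect_lt(relative_difference(28, 30), 0) # predicted below observed
  expect_error(relative_difference(1, 0), "undefined ratio")
})

test_that("cohort summaries use the sample SD and flag degenerate input", {
  s <- cohort_summary(c(1, 2, 3))
  expect_equal(s[c("n", "mean", "sd", "min", "max")],
               list(n = 3L, mean = 2, sd = 1, min = 1, max = 3))
  expect_warning(s1 <- cohort_summary(5), "single value")
  expect_identical(s1$sd, 0)
  expect_true(s1$degenerate)
  set.seed(7)
  v <- rlnorm(40)
  s2 <- cohort_summary(v)
  expect_equal(s2$mean, sum(v) / 40)
  expect_equal(s2$sd, sqrt(sum((v - mean(v))^2) / 39))
  expect_error(cohort_summary(numeric()), "insufficient data")
})

test_that("Bonferroni adjustment caps at one and matches p.adjust", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 5), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(1.2, 5), "invalid input")
  set.seed(3)
  p <- runif(20)
  for (pp in p) {
    expect_equal(bonferroni(pp, 5),
                 stats::p.adjust(pp, "bonferroni", n = 5))
  }
})

test_that("the paired Hotelling test reduces to the squared paired t at p = 1", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    pred <- matrix(rnorm(n, 10, 2), ncol = 1)
    obs <- matrix(rnorm(n, 9, 2), ncol = 1)
    h <- hotelling_paired(pred, obs, m_comparisons = 1)
    tt <- stats::t.test(pred - obs)
    expect_equal(h$t2, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(h$p_raw, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Hotelling handles identity, rescaling invariance and rank errors", {
  set.seed(5)
  pred <- matrix(rlnorm(40, 2, 0.4), 10, 4)
  # identical matrices: no evidence of a difference
  h0 <- hotelling_paired(pred, pred)
  expect_identical(h0$t2, 0)
  expect_identical(h0$p_raw, 1)

  obs <- pred * matrix(rlnorm(40, 0, 0.1), 10, 4)
  h1 <- hotelling_paired(pred, obs, m_comparisons = 5)
  expect_gte(h1$t2, 0)
  expect_equal(h1$f_stat, h1$t2 * (10 - 4) / (4 * (10 - 1)))
  expect_equal(h1$df1, 4L)
  expect_equal(h1$df2, 6L)
  expect_equal(h1$p_adjusted, min(1, 5 * h1$p_raw))
  # common rescaling of both matrices leaves the p-value unchanged
  h2 <- hotelling_paired(pred * 1000, obs * 1000, m_comparisons = 5)
  expect_equal(h2$t2, h1$t2, tolerance = 1e-9)
  expect_equal(h2$p_raw, h1$p_raw, tolerance = 1e-9)

  expect_error(hotelling_paired(pred[1:4, ], obs[1:4, ]), "rank deficiency")
  # duplicated column makes the difference covariance singular
  pred_s <- cbind(pred, pred[, 1])
  obs_s <- cbind(obs, obs[, 1] - 1)
  expect_error(hotelling_paired(pred_s[1:6, 1:5], obs_s[1:6, 1:5]),
               "rank deficiency|singular")
})
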