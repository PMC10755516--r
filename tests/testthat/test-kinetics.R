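test_that("noiseless mono-exponential data are recovered to high precision", {
  t <- c(2, 24, 48, 168)
  fit <- fit_tac(mono_df(t, 10, 0.008), lu)
  expect_identical(fit$model, "mono")
  expect_lt(abs(fit$terms$amplitude - 10) / 10, 1e-6)
  expect_lt(abs(fit$terms$rate - 0.008) / 0.008, 1e-6)
  expect_equal(effective_half_life(fit), log(2) / 0.008, tolerance = 1e-6)

  # determinism: identical inputs give identical fits
  fit2 <- fit_tac(mono_df(t, 10, 0.008), lu)
  expect_identical(fit$terms, fit2$terms)
})

test_that("uptake-washout biexponential data select biexp and reproduce all points", {
  t <- c(2, 24, 48, 168)
  y <- 12 * exp(-0.01 * t) - 12 * exp(-0.3 * t)
  fit <- fit_tac(data.frame(time_h = t, value = y, region = "salivary_glands"),
                 lu)
  expect_identical(fit$model, "biexp")
  expect_lt(max(abs(predict_tac(fit, t) - y) / y), 1e-4)
  # analytic TIA equals the term-wise closed form of the generating model
  expect_equal(tia(fit), 12 / 0.01 - 12 / 0.3, tolerance = 1e-3)
  # predicted curve stays non-negative
  grid <- seq(0, 10 * lu$half_life_h, length.out = 400)
  expect_true(all(predict_tac(fit, grid) >= -1e-10))
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(fit_tac(mono_df(48, 5, 0.01), lu), "insufficient")
  expect_error(
    fit_tac(data.frame(time_h = c(2, 24), value = c(0, 0)), lu),
    "degenerate")
  expect_error(
    fit_tac(data.frame(time_h = c(24, 24), value = c(5, 5)), lu),
    "insufficient")
  expect_error(
    fit_tac(data.frame(time_h = c(2, 24), value = c(1, 1),
                       region = c("liver", "kidneys")), lu),
    "several regions")
})

test_that("terminal rate is clamped to the physical decay constant", {
  t <- c(2, 24, 48, 168)
  # biological washout slower than physical decay is unphysical in an
  # effective curve; feed a too-slow decay and expect the clamp
  fit <- fit_tac(mono_df(t, 10, 0.002), lu)
  expect_true(fit$clamped)
  expect_equal(min(fit$terms$rate), lu$lambda_phys)
  expect_equal(effective_half_life(fit), lu$half_life_h)
})

test_that("analytic TIA matches the closed form and rejects invalid fits", {
  expect_equal(tia(make_fit(100, 0.01)), 10000)
  expect_equal(tia(make_fit(c(12, -12), c(0.01, 0.3))), 1160)
  bad <- make_fit(c(12, -12), c(0.01, 0.3))
  bad$terms$rate[2] <- -0.3
  expect_error(tia(bad), "invalid fit")
  expect_error(tia(make_fit(100, 0.01), "hybrid"), "requires")
})

test_that("hybrid TIA respects the trapezoid convexity bound on mono data", {
  t <- c(2, 24, 48, 168)
  a0 <- 100; lam <- 0.01
  df <- mono_df(t, a0, lam)
  fit <- fit_tac(df, lu)
  t_an <- tia(fit)
  t_hy <- tia(fit, "hybrid", measurements = df)
  # trapezoid overestimates a convex integrand; per-segment error bound
  # h^3/12 * max|f''| with f'' = a0 lam^2 exp(-lam t0)
  h <- diff(t)
  bound <- sum(h^3 / 12 * a0 * lam^2 * exp(-lam * t[-length(t)]))
  expect_gte(t_hy, t_an - 1e-9)
  expect_lt(t_hy - t_an, bound * (1 + 1e-6))
})

test_that("TIA is scaling-equivariant and unit-consistent", {
  t <- c(2, 24, 48, 168)
  df <- mono_df(t, 50, 0.012)
  fit <- fit_tac(df, lu)
  for (c_scale in c(0.25, 3, 117)) {
    df_c <- df; df_c$value <- df_c$value * c_scale
    fit_c <- fit_tac(df_c, lu)
    expect_equal(tia(fit_c), c_scale * tia(fit), tolerance = 1e-9)
    expect_equal(tia(fit_c, "hybrid", df_c),
                 c_scale * tia(fit, "hybrid", df), tolerance = 1e-9)
  }
  # hours -> days leaves the physical result unchanged
  lu_d <- nuclide(half_life_h = lu$half_life_h / 24) # "hours" now mean days
  df_d <- df; df_d$time_h <- df_d$time_h / 24
  fit_d <- fit_tac(df_d, lu_d)
  expect_equal(tia(fit_d) * 24, tia(fit), tolerance = 1e-9)
  expect_equal(effective_half_life(fit_d) * 24, effective_half_life(fit),
               tolerance = 1e-9)
})

test_that("analytic TIA of clamped fits is finite", {
  for (s in 1:10) {
    set.seed(s)
    t <- c(2, 24, 48, 168)
    lam <- runif(1, 0.0005, 0.003) # slower than physical decay
    fit <- fit_tac(mono_df(t, runif(1, 1, 100), lam), lu)
    v <- tia(fit)
    expect_true(is.finite(v))
    expect_gte(v, 0)
  }
})

test_that("normalized disintegrations divide TIA by injected activity", {
  expect_equal(normalized_disintegrations(10000, 7400), 1.35135, tolerance = 1e-5)
  expect_identical(normalized_disintegrations(0, 7400), 0)
  expect_identical(normalized_disintegrations(7400, 7400), 1)
  expect_error(normalized_disintegrations(100, 0), "invalid activity")
})

test_that("effective half-life is log(2) over the terminal rate", {
  expect_equal(effective_half_life(make_fit(10, 0.01)), 69.31, tolerance = 1e-3)
  expect_equal(effective_half_life(make_fit(10, 0.008)), 86.64, tolerance = 1e-3)
  expect_equal(effective_half_life(make_fit(10, lu$lambda_phys)),
               lu$half_life_h)
  # biexp: terminal = smallest rate
  expect_equal(effective_half_life(make_fit(c(5, 5), c(0.3, 0.01))),
               log(2) / 0.01)
})
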