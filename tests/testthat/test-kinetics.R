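test_that("noiseless fits recover the generating rate constant exactly", {
  for (k_true in c(0.0069, 0.0253, 0.1865)) {
    sim <- noiseless_series(setNames(k_true, "100"))
    fit <- first_order_fit(response ~ time_min, sim,
                           replicate = "replicate", temperature = 100)
    expect_equal(fit$k, k_true, tolerance = 1e-10)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
    expect_equal(fit$k_sd, 0, tolerance = 1e-12)
    expect_equal(fit$n_replicates, 3L)
  }
})

test_that("per-replicate aggregation reports mean +/- SD of replicate slopes", {
  # two exact exponentials with k = 0.05 and 0.07
  times <- c(0, 15, 30, 45, 60)
  df <- data.frame(
    time_min = rep(times, 2),
    response = c(exp(-0.05 * times), exp(-0.07 * times)),
    replicate = rep(1:2, each = length(times)))
  fit <- first_order_fit(response ~ time_min, df, replicate = "replicate")
  expect_equal(fit$k, 0.06, tolerance = 1e-12)
  expect_equal(fit$k_sd, sd(c(0.05, 0.07)), tolerance = 1e-12)
  expect_equal(fit$k_sd, 0.01414, tolerance = 1e-3)
  # independent closed-form OLS oracle on one replicate
  y <- log(exp(-0.07 * times))
  expect_equal(fit$replicate_fits[["2"]]$k, -ols_slope(times, y),
               tolerance = 1e-12)
  # pooled alternative fits all points jointly
  pooled <- first_order_fit(response ~ time_min, df,
                            replicate = "replicate", aggregate = "pooled")
  expect_equal(pooled$k, -ols_slope(rep(times, 2), log(df$response)),
               tolerance = 1e-12)
})

test_that("k, R2 are invariant to rescaling all responses", {
  sim <- noiseless_series(c(`115` = 0.0253))
  sim$response <- sim$response * rlnorm(1, 0, 0)  # keep deterministic
  f1 <- first_order_fit(response ~ time_min, sim, replicate = "replicate")
  sim2 <- sim; sim2$response <- sim2$response * 37.5
  f2 <- first_order_fit(response ~ time_min, sim2,
                        replicate = "replicate")
  expect_equal(f1$k, f2$k, tolerance = 1e-12)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
})

test_that("half-life and D-value identities hold", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(decimal_reduction(log(10)), 1)
  expect_equal(half_life(0.1865), 3.717, tolerance = 1e-3)
  expect_equal(decimal_reduction(0.1865), 12.346, tolerance = 1e-4)
  expect_equal(half_life(0.0069), 100.46, tolerance = 1e-4)
  for (k in c(0.001, 0.0485, 1.7)) {
    expect_equal(decimal_reduction(k) / half_life(k), log2(10),
                 tolerance = 1e-12)
    expect_equal(half_life(k) * log(10), decimal_reduction(k) * log(2),
                 tolerance = 1e-12)
  }
  expect_warning(expect_true(is.na(half_life(0))), "undefined")
  expect_warning(expect_true(is.na(decimal_reduction(-1))), "undefined")
})

test_that("retention prediction is the first-order survival", {
  expect_equal(predict_retention(0, 1e3), 1)
  expect_equal(predict_retention(5, 0), 1)
  expect_equal(predict_retention(0.1865, 60), 1.40e-5, tolerance = 1e-3)
  expect_error(predict_retention(0.1, -1), "non-negative")
  expect_error(predict_retention(-0.1, 1), "non-negative")
})

test_that("degenerate and invalid series are handled", {
  # constant series: k = 0, half-life undefined
  df <- data.frame(time_min = c(0, 15, 30, 45), response = 1,
                   replicate = 1)
  fit <- first_order_fit(response ~ time_min, df)
  expect_equal(fit$k, 0, tolerance = 1e-14)
  expect_true(is.na(fit$t_half))
  expect_true(is.na(fit$d_value))

  # fewer than 3 usable points
  expect_error(first_order_fit(response ~ time_min,
                               data.frame(time_min = c(0, 15),
                                          response = c(1, 0.5))),
               "at least 3")

  # non-positive responses excluded with a warning, fit proceeds
  df2 <- data.frame(time_min = c(0, 15, 30, 45, 60),
                    response = c(1, exp(-0.1 * 15), exp(-0.1 * 30),
                                 0, exp(-0.1 * 60)))
  expect_warning(fit2 <- first_order_fit(response ~ time_min, df2),
                 "non-positive")
  expect_equal(fit2$k, 0.1, tolerance = 1e-10)
  expect_equal(fit2$n_points, 4L)
})

test_that("alternative estimators agree on noiseless data", {
  sim <- noiseless_series(c(`135` = 0.0737), replicates = 1)
  for (m in c("free_intercept", "through_origin", "nonlinear")) {
    fit <- first_order_fit(response ~ time_min, sim, method = m)
    expect_equal(fit$k, 0.0737, tolerance = 1e-6)
  }
})

test_that("parameter recovery is unbiased at the design noise level", {
  # 500 simulated triplicate series at 3% noise: mean fitted k within 2%
  k_true <- 0.0253
  des <- degradation_design(temperatures = 115, noise_cv = 0.03)
  ks <- vapply(seq_len(500), function(i) {
    sim <- simulate_degradation(des, k = c(`115` = k_true), seed = 1000 + i)
    first_order_fit(response ~ time_min, sim, replicate = "replicate")$k
  }, numeric(1))
  expect_equal(mean(ks), k_true, tolerance = 0.02)
})

test_that("fit methods (coef, predict, residuals, summary) are consistent", {
  sim <- noiseless_series(c(`95` = 0.0138))
  fit <- first_order_fit(response ~ time_min, sim,
                         replicate = "replicate", temperature = 95,
                         analyte = "TAC")
  co <- coef(fit)
  expect_named(co, c("k", "t_half", "d_value"))
  expect_equal(unname(co[["t_half"]]), log(2) / co[["k"]])
  expect_equal(predict(fit, times = c(0, 30)),
               c(1, exp(-0.0138 * 30)), tolerance = 1e-10)
  expect_true(all(abs(residuals(fit)) < 1e-10))
  s <- summary(fit)
  expect_equal(s$temperature_C, 95)
  expect_equal(s$analyte, "TAC")
  expect_output(print(fit), "t_1/2")
})
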