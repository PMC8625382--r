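test_that("noiseless generation is the exact exponential", {
  des <- degradation_design(temperatures = 155, times = c(0, 30, 60),
                            replicates = 1, noise_cv = 0)
  sim <- simulate_degradation(des, k = c(`155` = 0.1865), c0 = 1)
  expect_equal(sim$response[sim$time_min == 60], exp(-0.1865 * 60),
               tolerance = 1e-12)
  expect_equal(sim$response[sim$time_min == 60], 1.40e-5, tolerance = 1e-3)

  # k = 0 leaves the response at c0 everywhere
  sim0 <- simulate_degradation(des, k = c(`155` = 0), c0 = 2.5)
  expect_true(all(sim0$response == 2.5))

  # ln(response/c0) = -k t to machine precision across a full design
  full <- noiseless_series(c(`75` = 0.0069, `155` = 0.1865))
  expect_equal(log(full$response),
               -ifelse(full$temperature_C == 75, 0.0069, 0.1865) *
                 full$time_min,
               tolerance = 1e-13)
})

test_that("lognormal noise has median c0 exp(-kt) and responses stay positive", {
  des <- degradation_design(temperatures = 115, times = c(0, 30),
                            replicates = 200, noise_cv = 0.03)
  sim <- simulate_degradation(des, k = c(`115` = 0.0253), seed = 42)
  at30 <- sim$response[sim$time_min == 30]
  expect_equal(median(at30), exp(-0.0253 * 30), tolerance = 0.01)
  expect_true(all(sim$response > 0))
  # realised CV close to the design CV
  expect_equal(sd(at30) / mean(at30), 0.03, tolerance = 0.35)
})

test_that("generation is bit-reproducible under a seed and leaves the RNG alone", {
  des <- degradation_design()
  k <- c(`75` = 0.0069, `95` = 0.0138, `115` = 0.0253, `135` = 0.0737,
         `155` = 0.1865)
  s1 <- simulate_degradation(des, k, seed = 11)
  s2 <- simulate_degradation(des, k, seed = 11)
  expect_identical(s1, s2)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_degradation(des, k, seed = 11))
  expect_identical(rnorm(1), before)

  d1 <- simulate_dose_response(2.4, 25, noise_sd = 3, seed = 5)
  d2 <- simulate_dose_response(2.4, 25, noise_sd = 3, seed = 5)
  expect_identical(d1, d2)
})

test_that("design and truth inputs are validated", {
  expect_error(degradation_design(temperatures = c(95, 75)),
               "strictly increasing")
  expect_error(degradation_design(times = c(15, 30)), "include 0")
  expect_error(degradation_design(noise_cv = -0.1), "non-negative")
  expect_error(degradation_design(replicates = 0), "positive integer")
  des <- degradation_design(temperatures = c(75, 95))
  expect_error(simulate_degradation(des, k = c(`75` = 0.01)),
               "no rate constant")
  expect_error(simulate_degradation(des, k = c(`75` = 0.01, `95` = -1)),
               "non-negative")
  expect_error(simulate_dose_response(2, 20, concentrations = c(-1, 5)),
               "positive")
})

test_that("Arrhenius rate generation inverts the model exactly", {
  temps <- c(75, 95, 115, 135, 155)
  # lnA chosen so k(75 degC) = 0.0069 at Ea = 50
  lnA <- log(0.0069) + 50 * 1000 / (8.314 * (75 + 273.15))
  k <- arrhenius_rates(Ea = 50, lnA = lnA, temperatures = temps)
  expect_equal(unname(k[1]), 0.0069, tolerance = 1e-12)
  expect_true(all(diff(k) > 0))  # Ea > 0 => k increasing in T
  fit <- arrhenius_fit(temps, k)
  expect_equal(fit$Ea, 50, tolerance = 1e-9)
  expect_equal(fit$lnA, lnA, tolerance = 1e-9)

  flat <- arrhenius_rates(Ea = 0, lnA = 1.5, temperatures = temps)
  expect_true(all(flat == exp(1.5)))
})

test_that("dose-response generator follows the linear-in-log model and clips", {
  d <- simulate_dose_response(ic50 = 1, slope = 20,
                              concentrations = c(0.1, 1, 10),
                              replicates = 1, noise_sd = 0)
  expect_equal(d$inhibition_pct[d$concentration_ug_mL == 1], 50)
  expect_equal(d$inhibition_pct[d$concentration_ug_mL == 10], 70)
  expect_equal(d$inhibition_pct[d$concentration_ug_mL == 0.1], 30)

  # extreme slope far above the ic50 saturates at 100
  sat <- simulate_dose_response(ic50 = 0.01, slope = 80,
                                concentrations = c(0.5, 1, 5),
                                replicates = 1, noise_sd = 0)
  expect_true(all(sat$inhibition_pct <= 100))
  expect_equal(max(sat$inhibition_pct), 100)
})
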