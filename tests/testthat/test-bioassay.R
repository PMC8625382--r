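test_that("percent inhibition is control-relative and clipped", {
  expect_equal(inhibition_percent(0.8, 0.8), 0)
  expect_equal(inhibition_percent(0.8, 0), 100)
  expect_equal(inhibition_percent(0.8, 0.2), 75)
  expect_warning(out <- inhibition_percent(0.5, 0.7), "clipped")
  expect_equal(out, 0)
  expect_error(inhibition_percent(0, 0.2), "positive")
})

test_that("log-linear IC50 interpolates the 50% crossing", {
  # two symmetric points: geometric midpoint
  fit <- ic50_loglinear(c(0.5, 5), c(30, 70))
  expect_equal(fit$ic50, sqrt(0.5 * 5), tolerance = 1e-10)
  expect_equal(fit$ic50, 1.581, tolerance = 1e-3)
  expect_false(fit$extrapolated)

  # an exact 50% reading at c with symmetric neighbours returns c
  fit2 <- ic50_loglinear(c(1, 2, 4), c(35, 50, 65))
  expect_equal(fit2$ic50, 2, tolerance = 1e-10)

  # independent closed-form oracle for the line and the crossing
  conc <- c(0.5, 1, 5); inh <- c(38, 47, 66)
  b1 <- ols_slope(log10(conc), inh)
  b0 <- ols_intercept(log10(conc), inh)
  fit3 <- ic50_loglinear(conc, inh)
  expect_equal(fit3$ic50, 10^((50 - b0) / b1), tolerance = 1e-12)
  expect_equal(fit3$slope, b1, tolerance = 1e-12)

  expect_error(ic50_loglinear(c(1, 2), c(70, 30)), "slope")
  expect_error(ic50_loglinear(c(2, 2), c(40, 60)), "distinct")
})

test_that("IC50 generator round trip is exact at zero noise", {
  for (true in c(0.57, 1.02, 2.40, 4.57)) {
    d <- simulate_dose_response(ic50 = true, slope = 25, noise_sd = 0)
    fit <- ic50_loglinear(d)
    expect_equal(fit$ic50, true, tolerance = 1e-9)
    expect_equal(fit$slope, 25, tolerance = 1e-9)
  }
})

test_that("median IC50 recovery is within 5% under assay noise", {
  true <- 2.40
  est <- vapply(seq_len(500), function(i) {
    d <- simulate_dose_response(ic50 = true, slope = 25, noise_sd = 3,
                                seed = 2000 + i)
    ic50_loglinear(d)$ic50
  }, numeric(1))
  expect_equal(median(est), true, tolerance = 0.05)
})

test_that("raising all inhibition values lowers the estimated IC50", {
  conc <- c(0.5, 1, 5); inh <- c(35, 45, 68)
  base <- ic50_loglinear(conc, inh)$ic50
  up <- ic50_loglinear(conc, inh + 8)$ic50
  expect_lt(up, base)
})

test_that("extrapolated IC50s are flagged", {
  d <- simulate_dose_response(ic50 = 20, slope = 25, noise_sd = 0)
  fit <- ic50_loglinear(d)
  expect_true(fit$extrapolated)
  expect_equal(fit$ic50, 20, tolerance = 1e-8)
})

test_that("Tukey letters reproduce the published group assignments", {
  ref <- reference_ic50()
  for (enz in unique(ref$enzyme)) {
    sub <- ref[ref$enzyme == enz, ]
    got <- tukey_letters(mean = sub$ic50_ug_mL, sd = sub$sd, n = sub$n,
                         labels = sub$sample)
    want <- setNames(sub$letter, sub$sample)
    expect_identical(setNames(got$letter, got$label)[names(want)], want,
                     label = paste("letters for", enz))
  }
})

test_that("summary-statistic Tukey agrees with TukeyHSD on exact raw data", {
  # raw replicates reconstructed to the exact means/SDs
  means <- c(1.8, 2.1, 4.9); sds <- c(0.3, 0.4, 0.5)
  raw <- data.frame(
    y = c(exact_group(means[1], sds[1]), exact_group(means[2], sds[2]),
          exact_group(means[3], sds[3])),
    g = factor(rep(c("a1", "a2", "a3"), each = 3)))
  hsd <- TukeyHSD(aov(y ~ g, raw))$g[, "p adj"]
  got <- tukey_letters(mean = means, sd = sds, n = rep(3, 3),
                       labels = c("a1", "a2", "a3"))
  p <- attr(got, "p_adj")
  expect_equal(unname(p["a2", "a1"]), unname(hsd[["a2-a1"]]),
               tolerance = 1e-8)
  expect_equal(unname(p["a3", "a1"]), unname(hsd[["a3-a1"]]),
               tolerance = 1e-8)
  expect_equal(unname(p["a3", "a2"]), unname(hsd[["a3-a2"]]),
               tolerance = 1e-8)
  # a1,a2 share a letter; a3 differs from both
  l <- setNames(got$letter, got$label)
  expect_identical(unname(l["a1"]), unname(l["a2"]))
  expect_false(any(strsplit(l[["a3"]], "")[[1]] %in%
                     strsplit(l[["a1"]], "")[[1]]))
})

test_that("letters are a cover compatible with the significance partition", {
  set.seed(31)
  for (rep in 1:20) {
    g <- sample(2:5, 1)
    means <- runif(g, 0, 10)
    sds <- runif(g, 0.2, 1.5)
    got <- tukey_letters(mean = means, sd = sds, n = rep(3, g))
    expect_true(all(nchar(got$letter) >= 1))
    p <- attr(got, "p_adj")
    for (i in seq_len(g - 1)) for (j in (i + 1):g) {
      share <- any(strsplit(got$letter[i], "")[[1]] %in%
                     strsplit(got$letter[j], "")[[1]])
      if (p[i, j] < 0.05) expect_false(share)
    }
  }
})

test_that("identical groups share one letter and tiny groups are dropped", {
  same <- tukey_letters(mean = c(2, 2, 2), sd = c(0.5, 0.5, 0.5),
                        n = c(3, 3, 3))
  expect_true(all(same$letter == "a"))
  expect_warning(
    got <- tukey_letters(mean = c(1, 2, 3), sd = c(0.1, 0.1, 0.1),
                         n = c(3, 1, 3), labels = c("x", "y", "z")),
    "excluded")
  expect_identical(sort(got$label), c("x", "z"))
})
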