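test_that("percent inhibition is the blank-corrected activity ratio", {
  expect_equal(percent_inhibition(1.0, 1.0, 0.2), 0)
  expect_equal(percent_inhibition(0.2, 1.0, 0.2), 100)
  expect_equal(percent_inhibition(0.6, 1.0, 0.2), 50)
  expect_error(percent_inhibition(0.5, 0.2, 0.2), "positive")
  # antitone in the sample signal
  s <- seq(0.2, 1.0, by = 0.1)
  expect_true(all(diff(percent_inhibition(s, 1.0, 0.1)) < 0))
})

test_that("the two-point log-linear fit lands on the midpoint", {
  fit <- fit_ic50(data.frame(concentration = c(1, 10),
                             inhibition = c(25, 75)))
  expect_equal(fit$value, 10^0.5, tolerance = 1e-12)
  expect_false(fit$censored)
})

test_that("noise-free synthetic curves are recovered exactly", {
  for (true in c(0.05, 2.74, 40)) {
    curve <- simulate_dose_response(ic50 = true, slope = 40, noise_sd = 0,
                                    seed = 1)
    fit <- fit_ic50(curve)
    expect_lt(abs(fit$value - true) / true, 1e-9)
    expect_equal(fit$slope, 40, tolerance = 1e-9)
  }
})

test_that("curves topping out below 50% are censored at the top concentration", {
  curve <- data.frame(concentration = c(10, 100, 1000),
                      inhibition = c(4.1, 11.9, 22.5),
                      units = "umol/L")
  fit <- fit_ic50(curve)
  expect_true(fit$censored)
  expect_true(is.na(fit$value))
  expect_equal(fit$label, "> 1000 umol/L")
  # true IC50 beyond the simulated grid maximum is likewise censored
  sim <- simulate_dose_response(ic50 = 5000, slope = 40, noise_sd = 0,
                                concentrations = c(10, 100, 1000), seed = 2)
  expect_true(fit_ic50(sim)$censored)
})

test_that("degenerate dose-response inputs are rejected", {
  expect_error(fit_ic50(data.frame(concentration = c(0, 1),
                                   inhibition = c(10, 60))), "positive")
  expect_error(fit_ic50(data.frame(concentration = c(2, 2),
                                   inhibition = c(10, 60))), "distinct")
  down <- data.frame(concentration = c(1, 10, 100),
                     inhibition = c(80, 50, 20))
  expect_true(fit_ic50(down)$censored)  # non-positive slope
})

test_that("replicates are averaged per concentration before fitting", {
  curve <- data.frame(concentration = rep(c(1, 10), each = 3),
                      inhibition = c(20, 25, 30, 70, 75, 80),
                      replicate = rep(1:3, 2))
  fit <- fit_ic50(curve)
  expect_equal(fit$value, 10^0.5, tolerance = 1e-12)
})

test_that("the logistic alternative agrees with log-linear near the midpoint", {
  curve <- simulate_dose_response(ic50 = 3, slope = 40, noise_sd = 0,
                                  model = "logistic", seed = 4)
  fit <- fit_ic50(curve, method = "logistic")
  expect_equal(fit$value, 3, tolerance = 1e-6)
})

test_that("IC50 estimates are unbiased at assay-scale noise", {
  true <- 2.74
  est <- vapply(1:500, function(i) {
    curve <- simulate_dose_response(ic50 = true, slope = 40, noise_sd = 3,
                                    seed = i)
    fit_ic50(curve)$value
  }, numeric(1))
  expect_lt(abs(mean(est) - true) / true, 0.05)
  # individual estimates fall within 3 delta-method standard errors
  one <- fit_ic50(simulate_dose_response(ic50 = true, slope = 40,
                                         noise_sd = 3, seed = 999))
  expect_lt(abs(one$value - true), 3 * one$se + 1e-12)
})

test_that("the serving model reproduces the printed cheese amounts", {
  expect_equal(estimate_serving(1.90, 63.54), 15)
  expect_equal(estimate_serving(2.74, 63.54), 22)
  expect_equal(estimate_serving(0, 63.54), 0)
  # linear in IC50 and inversely proportional to peptide content
  g1 <- estimate_serving(1, 60, round = FALSE)
  expect_equal(estimate_serving(3, 60, round = FALSE), 3 * g1)
  expect_equal(estimate_serving(1, 120, round = FALSE), g1 / 2)
  expect_error(estimate_serving(1, -2), "positive")
})
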