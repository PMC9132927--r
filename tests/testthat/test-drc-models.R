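test_that("analytic landmark values hold for the link-based models", {
  # Logit crosses 0.5 where alpha + beta*log10(c) = 0
  d <- drc("Logit", alpha = 2, beta = 1.5)
  expect_equal(evaluate_drc(d, 10^(-2 / 1.5)), 0.5)
  # Weibull crosses 1 - exp(-1) at the same landmark
  w <- drc("Weibull", alpha = 1, beta = 2)
  expect_equal(evaluate_drc(w, 10^(-1 / 2)), 1 - exp(-1))
  # Hill-three approaches its asymptote gamma from below
  h <- drc("Hill_three", alpha = 10, beta = 1.2, gamma = 0.6)
  big <- evaluate_drc(h, 10^seq(4, 9, by = 1))
  expect_true(all(diff(big) > 0))
  expect_true(all(big < 0.6))
  expect_equal(evaluate_drc(h, 1e12), 0.6, tolerance = 1e-6)
  expect_equal(drc_max_effect(h), 0.6)
})

test_that("every registered model is monotone over six decades", {
  grid <- 10^seq(-3, 3, length.out = 61)
  for (d in registry_examples()) {
    eff <- evaluate_drc(d, grid)
    expect_true(all(diff(eff) >= -1e-12), label = d$model_id)
    expect_true(all(eff >= 0 & eff <= 1), label = d$model_id)
  }
})

test_that("inversion round-trips to 1e-8 across the registry", {
  for (d in registry_examples()) {
    lo <- drc_min_effect(d); hi <- drc_max_effect(d)
    e <- lo + (hi - lo) * seq(0.01, 0.99, length.out = 25)
    back <- evaluate_drc(d, inverse_drc(d, e))
    expect_lt(max(abs(back - e)), 1e-8)
  }
  # analytic inversion landmark: Logit EC50 = 10^(-alpha/beta)
  d <- drc("Logit", alpha = 2, beta = 1.5)
  expect_equal(inverse_drc(d, 0.5), 10^(-2 / 1.5))
})

test_that("unattainable and invalid effects raise the right conditions", {
  h <- drc("Hill_three", alpha = 10, beta = 1, gamma = 0.6)
  expect_error(inverse_drc(h, 0.7), class = "mixadd_unattainable")
  expect_error(inverse_drc(h, 0.6), class = "mixadd_unattainable")
  expect_error(inverse_drc(h, 0), "effect must be")
  expect_error(inverse_drc(h, -0.2), "effect must be")
  expect_error(evaluate_drc(h, 0), "strictly positive")
  expect_error(evaluate_drc(h, -1), "strictly positive")
})

test_that("the registry rejects unknown models and wrong arities", {
  expect_error(drc("NoSuchModel", 1, 2), "unknown DRC model")
  expect_error(drc("Logit", 1, 2, 0.5), "takes 2 parameters")
  expect_error(drc("Hill_three", 1, 2), "takes 3 parameters")
  expect_error(drc("Hill_three", 1, -2, 0.5), "beta")
  expect_error(drc("Hill_three", 1, 2, 1.5), "gamma")
  expect_true(all(c("Hill", "Hill_two", "Hill_three", "Hill_four",
                    "Weibull", "Weibull_three", "Weibull_four",
                    "Logit", "Logit_three", "Logit_four",
                    "BCW", "BCL", "GL") %in% drc_models()))
})

test_that("Box-Cox models report their restricted effect ranges", {
  # positive exponent: nonzero effect floor at c -> 0
  b <- drc("BCW", alpha = 0.3, beta = 1.2, gamma = 0.4)
  expect_gt(drc_min_effect(b), 0)
  expect_equal(drc_max_effect(b), 1)
  # negative exponent: ceiling below 1 at c -> Inf
  b2 <- drc("BCL", alpha = 0.3, beta = 1.2, gamma = -0.4)
  expect_equal(drc_min_effect(b2), 0)
  expect_lt(drc_max_effect(b2), 1)
  expect_equal(evaluate_drc(b2, 1e10), drc_max_effect(b2), tolerance = 1e-4)
})
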