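truth_pars <- list(
  Hill = c(0.5, 1.8), Hill_two = c(0.5, 0.8), Hill_three = c(0.5, 1.8, 0.65),
  Hill_four = c(0.5, 1.8, 0.8, 0.1), Weibull = c(0.4, 1.6),
  Weibull_three = c(0.4, 1.6, 0.7), Weibull_four = c(0.4, 1.6, 0.85, 0.08),
  Logit = c(0.5, 1.7), Logit_three = c(0.5, 1.7, 0.7),
  Logit_four = c(0.5, 1.7, 0.85, 0.08), BCW = c(0.3, 1.2, 0.4),
  BCL = c(0.3, 1.2, 0.4), GL = c(0.5, 1.7, 1.5))

test_that("noise-free generate-and-refit recovers every model's parameters", {
  x <- 10^seq(-3, 2, length.out = 12)
  for (m in names(truth_pars)) {
    tp <- truth_pars[[m]]
    d0 <- do.call(drc, c(list(m), as.list(tp)))
    fit <- fit_drc(x, evaluate_drc(d0, x), m)
    expect_lt(max(abs(fit$par - tp) / pmax(abs(tp), 1e-8)), 1e-4)
    expect_lt(fit$rss, 1e-10)
  }
})

test_that("too few points for the model arity is refused", {
  expect_error(fit_drc(c(1, 10), c(0.2, 0.8), "Hill_three"),
               "insufficient points")
  expect_error(fit_drc(c(1, 10, 100), c(0.2, 0.5, 0.8), "Hill_four"),
               "insufficient points")
  expect_error(fit_drc(c(-1, 1, 10), c(0.1, 0.3, 0.8), "Logit"),
               "strictly positive")
  expect_error(fit_drc(c(1, 2, 3), c(0.1, 0.3, 1.8), "Logit"),
               "\\[0, 1\\]")
})

test_that("the multi-start search lands on the same optimum from noisy data", {
  # mildly noisy Logit data: all five deterministic starts must agree
  d0 <- drc("Logit", alpha = 0.8, beta = 2.2)
  x <- 10^seq(-2.5, 1.5, length.out = 15)
  set.seed(42)
  e <- pmin(1, pmax(0, evaluate_drc(d0, x) + rnorm(15, sd = 0.02)))
  f1 <- fit_drc(x, e, "Logit")
  f2 <- fit_drc(rev(x), rev(e), "Logit")   # order must not matter
  expect_equal(f1$par, f2$par, tolerance = 1e-6)
  expect_equal(unname(f1$par["beta"]), 2.2, tolerance = 0.15)
  expect_true(!is.null(f1$vcov))
})

test_that("the predictable range truncates at the weakest component", {
  full <- list(make_logit(1), make_weibull(5))
  r <- predictable_effect_range(full)
  expect_equal(c(r$lo, r$hi), c(0.1, 0.9))

  part <- c(full, list(make_hill3(10, 1, gamma = 0.65)))
  r2 <- predictable_effect_range(part)
  expect_equal(c(r2$lo, r2$hi), c(0.1, 0.6))
  expect_equal(r2$grid, seq(0.1, 0.6, by = 0.1))

  # a boundary asymptote is NOT attainable (strict inequality)
  r3 <- predictable_effect_range(list(make_hill3(10, 1, gamma = 0.6)))
  expect_equal(r3$hi, 0.5)

  expect_error(predictable_effect_range(list(make_hill3(1, 1, gamma = 0.05))),
               class = "mixadd_unattainable")
  expect_error(predictable_effect_range(list()), "empty")
})
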