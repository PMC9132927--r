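test_that("model selection is validated and per-model errors are isolated", {
  gen <- generate_synthetic_mixture(4, seed = 3L)
  expect_error(predict_mixture(gen$spec, character(0)), "empty")
  expect_error(predict_mixture(gen$spec, "Bliss"), "unknown model")
  # SimpleCA lacks endpoints here, CA still computes
  p <- predict_mixture(gen$spec, c("CA", "SimpleCA"))
  expect_null(p$results$CA$error)
  expect_match(p$results$SimpleCA$error, "summary endpoint")
  expect_length(p$results$CA$ec, 9)
  # TSP without structures: input error, CA unaffected
  p2 <- predict_mixture(gen$spec, c("TSP", "CA"))
  expect_match(p2$results$TSP$error, "structure")
  expect_null(p2$results$CA$error)
})

test_that("an endpoint-only spec yields a scalar Simple-CA result and no curve", {
  comps <- list(
    mixture_component("a", 0.6, endpoint_value = conc_value(10, "mg/L")),
    mixture_component("b", 0.3, endpoint_value = conc_value(50, "mg/L")))
  sp <- mixture_spec(comps, output_unit = "mg/L")
  p <- predict_mixture(sp, "SimpleCA")
  r <- p$results$SimpleCA
  expect_null(r$error)
  expect_null(r$grid)
  expect_equal(r$scalar$value, 1 / (0.6 / 10 + 0.3 / 50))
  expect_equal(p$lowest$value, r$scalar$value)
  expect_equal(nrow(prediction_table(p)), 0)
})

test_that("the grid is truncated to the predictable range across models", {
  drcs <- list(make_logit(1, 2), make_hill3(5, 1.2, gamma = 0.65))
  sp <- make_mixture(drcs, c(0.5, 0.5))
  p <- predict_mixture(sp, c("CA", "IA", "GCA"))
  for (m in c("CA", "IA", "GCA"))
    expect_equal(max(p$results[[m]]$grid), 0.6)
  # lowest ECx reference stays at 50% because it is attainable
  expect_equal(p$lowest$effect, 0.5)
  # with an even weaker component the reference drops to the grid top
  sp2 <- make_mixture(list(make_logit(1, 2), make_hill3(5, 1.2, 0.45)),
                      c(0.5, 0.5))
  p2 <- predict_mixture(sp2, "CA")
  expect_equal(p2$lowest$effect, 0.4)
})

test_that("bootstrap intervals bracket the point estimate and respect the seed", {
  gen <- generate_synthetic_mixture(3, seed = 11L)
  p1 <- predict_mixture(gen$spec, "CA", bootstrap_n = 50, seed = 5L)
  p2 <- predict_mixture(gen$spec, "CA", bootstrap_n = 50, seed = 5L)
  r <- p1$results$CA
  expect_length(r$ci_lo, length(r$grid))
  expect_true(all(r$ci_lo <= r$ci_hi))
  expect_true(all(r$ci_lo <= r$ec * 1.05 & r$ci_hi >= r$ec * 0.95))
  expect_identical(p1$results$CA$ci_lo, p2$results$CA$ci_lo)
  # the RNG stream outside is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(predict_mixture(gen$spec, "CA", bootstrap_n = 5,
                                          seed = 1L)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the lowest predicted ECx picks the most sensitive model", {
  drcs <- list(make_logit(1, 2), make_logit(6, 1.4))
  sp <- make_mixture(drcs, c(0.5, 0.5))
  p <- predict_mixture(sp, c("CA", "IA"))
  tab <- prediction_table(p)
  i50 <- which(tab$effect == 50)
  expect_equal(p$lowest$value, min(tab$CA[i50], tab$IA[i50]))
  expect_true(p$lowest$model %in% c("CA", "IA"))
})
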