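grid9 <- seq(0.1, 0.9, by = 0.1)

test_that("sham additivity: CA and GCA of self-mixtures reproduce the single curve", {
  d <- drc("Logit", alpha = 1.2, beta = 2.1, conc_unit = "uM")
  for (fr in list(c(0.5, 0.5), c(0.3, 0.7), c(0.2, 0.3, 0.5))) {
    sp <- make_mixture(rep(list(d), length(fr)), fr)
    single <- inverse_drc(d, grid9)
    expect_rel_equal(ca_effective_concentration(sp, grid9), single, 1e-9)
    expect_rel_equal(gca_effective_concentration(sp, grid9), single, 1e-6)
  }
  # IA self-consistency holds for the single-component dose: a mixture of
  # one chemical "with itself" scales doses back to the whole
  sp1 <- make_mixture(list(d, d), c(0.5, 0.5))
  cc <- inverse_drc(d, 0.5)
  expect_equal(ia_effect(sp1, cc), 1 - (1 - evaluate_drc(d, 0.5 * cc))^2)
})

test_that("IA is the product formula and inverts consistently", {
  d1 <- make_logit(1, 2); d2 <- make_logit(4, 1.5)
  sp <- make_mixture(list(d1, d2), c(0.5, 0.5))
  cc <- 3.7
  expect_equal(ia_effect(sp, cc),
               1 - (1 - evaluate_drc(d1, 0.5 * cc)) *
                   (1 - evaluate_drc(d2, 0.5 * cc)))
  # two components each at effect 0.3 combine to 0.51
  da <- make_logit(1, 2)
  spa <- make_mixture(list(da, da), c(0.5, 0.5))
  c03 <- 2 * inverse_drc(da, 0.3)   # scaled dose hits 0.3 per component
  expect_equal(ia_effect(spa, c03), 1 - 0.7^2)
  # roundtrip
  for (e in c(0.15, 0.42, 0.8))
    expect_equal(ia_effect(sp, ia_effective_concentration(sp, e)), e,
                 tolerance = 1e-8)
  # above the attainable supremum
  dp <- make_hill3(1, 1, 0.3)
  spp <- make_mixture(list(dp, dp), c(0.5, 0.5))
  expect_error(ia_effective_concentration(spp, 0.9),
               class = "mixadd_unattainable")
})

test_that("single-component identities hold at the spec boundary", {
  # one chemical at p = 1 carried as two half-shares of the same curve
  d <- make_logit(2.5, 1.8)
  sp <- make_mixture(list(d, d), c(0.5, 0.5))
  expect_equal(ca_effective_concentration(sp, 0.5), inverse_drc(d, 0.5),
               tolerance = 1e-9)
})

test_that("GCA matches CA for full agonists and the Hill-1 closed form for partials", {
  # full agonists: the definitions coincide on the whole grid
  sp <- make_mixture(list(make_logit(1, 2), make_weibull(4, 1.5),
                          make_logit(0.3, 2.5)), c(0.2, 0.5, 0.3))
  expect_rel_equal(gca_effective_concentration(sp, grid9),
                   ca_effective_concentration(sp, grid9), 1e-6)

  # two slope-1 Hill partial agonists: E = sum(g_i x_i / K_i) / (1 + sum(x_i / K_i))
  h1 <- make_hill3(2, 1, 0.6); h2 <- make_hill3(5, 1, 0.9)
  sp2 <- make_mixture(list(h1, h2), c(0.4, 0.6))
  for (cc in c(0.5, 3, 8, 40)) {
    x1 <- 0.4 * cc; x2 <- 0.6 * cc
    closed <- (0.6 * x1 / 2 + 0.9 * x2 / 5) / (1 + x1 / 2 + x2 / 5)
    expect_equal(gca_effect(sp2, cc), closed, tolerance = 1e-10)
  }
  # GCA reaches past the weaker partial agonist's asymptote
  e_above <- 0.7  # > 0.6, unattainable for h1 alone
  cc <- gca_effective_concentration(sp2, e_above)
  expect_equal(gca_effect(sp2, cc), e_above, tolerance = 1e-8)
  expect_error(inverse_drc(h1, e_above), class = "mixadd_unattainable")
})

test_that("two-component CA and IA agree with a 1e5-point grid-search oracle", {
  # oracle built from the closed-form Logit algebra, independent of the
  # package's inversion machinery
  p <- c(0.35, 0.65); a <- c(0.4, -0.8); b <- c(2.2, 1.4)
  ec <- function(e, i) 10^((log(e / (1 - e)) - a[i]) / b[i])
  sp <- make_mixture(list(drc("Logit", a[1], b[1]), drc("Logit", a[2], b[2])),
                     p)
  cgrid <- 10^seq(-4, 3, length.out = 1e5)
  for (e in c(0.2, 0.5, 0.8)) {
    # CA: toxic units sum to 1
    tu <- p[1] * cgrid / ec(e, 1) + p[2] * cgrid / ec(e, 2)
    ca_oracle <- cgrid[which.min(abs(tu - 1))]
    expect_rel_equal(ca_effective_concentration(sp, e), ca_oracle, 1e-3)
    # IA: product of non-responses
    eff <- 1 - (1 - plogis(a[1] + b[1] * log10(p[1] * cgrid))) *
               (1 - plogis(a[2] + b[2] * log10(p[2] * cgrid)))
    ia_oracle <- cgrid[which.min(abs(eff - e))]
    expect_rel_equal(ia_effective_concentration(sp, e), ia_oracle, 1e-3)
  }
})

test_that("unit choice does not change the prediction (mw supplied)", {
  # fractions are interpreted on the working unit's basis, so predictions
  # are unit-invariant whenever the unit change rescales every component
  # identically: always within a unit family, and across the molar/mass
  # boundary when molecular weights are equal.
  drcs <- list(make_logit(2, 2), make_logit(8, 1.5))
  e <- c(0.2, 0.5, 0.8)
  sp_um <- make_mixture(drcs, c(0.4, 0.6), unit = "uM")
  sp_nm <- make_mixture(drcs, c(0.4, 0.6), unit = "nM")
  expect_rel_equal(ca_effective_concentration(sp_nm, e),
                   1000 * ca_effective_concentration(sp_um, e), 1e-9)
  expect_rel_equal(ia_effective_concentration(sp_nm, e),
                   1000 * ia_effective_concentration(sp_um, e), 1e-9)
  mws <- c(200, 200)
  sp_mg <- make_mixture(drcs, c(0.4, 0.6), unit = "mg/L", mws = mws)
  s <- convert_concentration(1, "mg/L", mw = 200, from = "uM")
  expect_rel_equal(ca_effective_concentration(sp_mg, e),
                   s * ca_effective_concentration(sp_um, e), 1e-9)
  expect_rel_equal(ia_effective_concentration(sp_mg, e),
                   s * ia_effective_concentration(sp_um, e), 1e-9)
})

test_that("predicted effective concentrations increase strictly with effect", {
  gen <- generate_synthetic_mixture(6, fraction_scheme = "dirichlet",
                                    seed = 7L)
  sp <- gen$spec
  expect_true(all(diff(ca_effective_concentration(sp, grid9)) > 0))
  expect_true(all(diff(ia_effective_concentration(sp, grid9)) > 0))
  expect_true(all(diff(gca_effective_concentration(sp, grid9)) > 0))
})

test_that("Simple-CA implements the unnormalized harmonic rule", {
  # sham additivity
  expect_equal(simple_ca_ec50(c(0.5, 0.5), c(10, 10), units = "mg/L")$value,
               10)
  # weights are used exactly as entered (sum < 1 allowed)
  expect_equal(simple_ca_ec50(0.9, 9, units = "mg/L")$value, 10)
  expect_error(simple_ca_ec50(c(0.5, 0.6), c(0, 10), units = "mg/L"),
               "> 0")
  expect_error(simple_ca_ec50(c(0.5, 1.2), c(5, 10), units = "mg/L"),
               "weights")
  # unit mixing with molar/mass conversion
  v <- simple_ca_ec50(c(0.5, 0.5), list(conc_value(10, "mg/L"),
                                        conc_value(100, "uM")),
                      output_unit = "mg/L", mws = c(NA, 100))
  expect_equal(v$value, 1 / (0.5 / 10 + 0.5 / 10))
})
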