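# Builders for small, fully-known mixtures used across the suite.

# Logit curve parameterized by its EC50 and slope (base-10).
make_logit <- function(ec50, slope = 2, unit = "uM")
  drc("Logit", alpha = -slope * log10(ec50), beta = slope, conc_unit = unit)

# Weibull curve through effect 0.5 at ec50.
make_weibull <- function(ec50, slope = 2, unit = "uM")
  drc("Weibull", alpha = log(log(2)) - slope * log10(ec50), beta = slope,
      conc_unit = unit)

make_hill3 <- function(ec50, slope = 1, gamma = 0.6, unit = "uM")
  drc("Hill_three", alpha = ec50, beta = slope, gamma = gamma,
      conc_unit = unit)

make_mixture <- function(drcs, fractions = NULL, unit = "uM", mws = NULL) {
  n <- length(drcs)
  if (is.null(fractions)) fractions <- rep(1 / n, n)
  comps <- lapply(seq_len(n), function(i)
    mixture_component(name = paste0("chem", i), fraction = fractions[i],
                      mw = if (is.null(mws)) NA_real_ else mws[i],
                      drc = drcs[[i]]))
  mixture_spec(comps, output_unit = unit)
}

# One representative valid parameter set per registered model, spanning
# 2-, 3- and 4-parameter families.
registry_examples <- function(unit = "uM") {
  list(
    Hill          = drc("Hill", 1.3, 1.9, conc_unit = unit),
    Hill_two      = drc("Hill_two", 0.8, 0.85, conc_unit = unit),
    Hill_three    = drc("Hill_three", 1.3, 1.9, 0.7, conc_unit = unit),
    Hill_four     = drc("Hill_four", 1.3, 1.9, 0.85, 0.1, conc_unit = unit),
    Weibull       = drc("Weibull", 0.4, 1.6, conc_unit = unit),
    Weibull_three = drc("Weibull_three", 0.4, 1.6, 0.7, conc_unit = unit),
    Weibull_four  = drc("Weibull_four", 0.4, 1.6, 0.85, 0.08,
                        conc_unit = unit),
    Logit         = drc("Logit", 0.5, 1.7, conc_unit = unit),
    Logit_three   = drc("Logit_three", 0.5, 1.7, 0.7, conc_unit = unit),
    Logit_four    = drc("Logit_four", 0.5, 1.7, 0.85, 0.08,
                        conc_unit = unit),
    BCW           = drc("BCW", 0.3, 1.2, 0.4, conc_unit = unit),
    BCL           = drc("BCL", 0.3, 1.2, 0.4, conc_unit = unit),
    GL            = drc("GL", 0.5, 1.7, 1.5, conc_unit = unit))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
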