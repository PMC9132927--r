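# Nonlinear least-squares fitting of DRC models.
#
# Fitting is seedless and reproducible: five deterministic starting points
# are derived from the data (link-scale linear regression for the
# location/slope parameters, observed-effect quantiles for asymptotes),
# and the Levenberg-Marquardt optimum with the lowest residual sum of
# squares wins.

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Link-regression starting values per model family.
drc_start_values <- function(model_id, conc, effect) {
  x <- log10(conc)
  gmax <- clamp(1.02 * max(effect), 0.05, 1)
  dmin <- clamp(0.98 * min(effect), 0, gmax - 0.02)
  lin <- function(z) {
    fit <- stats::lm(z ~ x)
    b <- unname(stats::coef(fit))
    if (!is.finite(b[2]) || b[2] <= 0) b[2] <- 1
    c(a = b[1], b = b[2])
  }
  e1 <- clamp(effect, 1e-4, 1 - 1e-4)
  base <- switch(model_id,
    Hill = {
      ab <- lin(logit(e1)); c(alpha = 10^(-ab["a"] / ab["b"]), beta = ab["b"])
    },
    Hill_two = {
      b0 <- min(1, gmax)
      a0 <- stats::median(conc * (b0 - clamp(effect, 1e-4, b0 - 1e-4)) /
                            clamp(effect, 1e-4, b0 - 1e-4))
      c(alpha = max(a0, 1e-9), beta = b0)
    },
    Hill_three = {
      ab <- lin(logit(clamp(effect / gmax, 1e-4, 1 - 1e-4)))
      c(alpha = 10^(-ab["a"] / ab["b"]), beta = ab["b"], gamma = gmax)
    },
    Hill_four = {
      z <- clamp((effect - dmin) / (gmax - dmin), 1e-4, 1 - 1e-4)
      ab <- lin(logit(z))
      c(alpha = 10^(-ab["a"] / ab["b"]), beta = ab["b"],
        gamma = gmax, delta = dmin)
    },
    Weibull = { ab <- lin(loglog(e1)); c(alpha = ab["a"], beta = ab["b"]) },
    Weibull_three = {
      ab <- lin(loglog(clamp(effect / gmax, 1e-4, 1 - 1e-4)))
      c(alpha = ab["a"], beta = ab["b"], gamma = gmax)
    },
    Weibull_four = {
      z <- clamp((effect - dmin) / (gmax - dmin), 1e-4, 1 - 1e-4)
      ab <- lin(loglog(z))
      c(alpha = ab["a"], beta = ab["b"], gamma = gmax, delta = dmin)
    },
    Logit = { ab <- lin(logit(e1)); c(alpha = ab["a"], beta = ab["b"]) },
    Logit_three = {
      ab <- lin(logit(clamp(effect / gmax, 1e-4, 1 - 1e-4)))
      c(alpha = ab["a"], beta = ab["b"], gamma = gmax)
    },
    Logit_four = {
      z <- clamp((effect - dmin) / (gmax - dmin), 1e-4, 1 - 1e-4)
      ab <- lin(logit(z))
      c(alpha = ab["a"], beta = ab["b"], gamma = gmax, delta = dmin)
    },
    BCW = { ab <- lin(loglog(e1))
      # at gamma -> small the Box-Cox axis ~ ln(c) = log10(c) * ln 10
      c(alpha = ab["a"], beta = ab["b"] / log(10), gamma = 0.1) },
    BCL = { ab <- lin(logit(e1))
      c(alpha = ab["a"], beta = ab["b"] / log(10), gamma = 0.1) },
    GL = { ab <- lin(logit(e1))
      c(alpha = ab["a"], beta = ab["b"], gamma = 1) },
    stop("no starting-value rule for model ", model_id, call. = FALSE))
  names(base) <- drc_model_entry(model_id)$pnames
  base
}

# Five deterministic start perturbations (multiplicative on slope,
# additive/multiplicative on location depending on family).
drc_start_set <- function(model_id, conc, effect) {
  base <- drc_start_values(model_id, conc, effect)
  tweaks <- list(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.5), c(1, 2))
  lapply(tweaks, function(t) {
    s <- base
    if (names(s)[1] == "alpha" && model_id %in%
          c("Hill", "Hill_two", "Hill_three", "Hill_four")) {
      s["alpha"] <- s["alpha"] * t[1]     # concentration-scale location
    } else {
      s["alpha"] <- s["alpha"] + log(t[1])
    }
    s["beta"] <- s["beta"] * t[2]
    s
  })
}

#' Fit a DRC model to concentration-effect data
#'
#' Least-squares fit by Levenberg-Marquardt with five deterministic
#' starting points derived from the data; the converged fit with the
#' lowest residual sum of squares is returned.
#'
#' @param conc Strictly positive concentrations.
#' @param effect Fractional effects in `[0, 1]` (same length as `conc`).
#' @param model_id Registered model id, see [drc_models()].
#' @param conc_unit Concentration unit recorded on the result.
#' @return A [drc()] object with `rss` and `vcov` filled in.
#' @examples
#' d0 <- drc("Logit", alpha = 2, beta = 1.5)
#' x <- 10^seq(-3, 2, length.out = 12)
#' fit_drc(x, evaluate_drc(d0, x), "Logit")
#' @export
fit_drc <- function(conc, effect, model_id, conc_unit = "uM") {
  entry <- drc_model_entry(model_id)
  if (!is.numeric(conc) || any(conc <= 0))
    stop("concentrations must be strictly positive", call. = FALSE)
  if (length(conc) != length(effect))
    stop("conc and effect lengths differ", call. = FALSE)
  if (length(conc) < entry$npar + 1L)
    stop("insufficient points: model ", model_id, " needs at least ",
         entry$npar + 1L, " concentration-effect pairs, got ", length(conc),
         call. = FALSE)
  if (any(effect < 0) || any(effect > 1))
    stop("effects must lie in [0, 1]", call. = FALSE)

  dat <- data.frame(conc = conc, effect = effect)
  fn <- entry$eval
  pn <- entry$pnames
  form <- switch(as.character(entry$npar),
    "2" = effect ~ fn(c(alpha = alpha, beta = beta), conc),
    "3" = effect ~ fn(c(alpha = alpha, beta = beta, gamma = gamma), conc),
    "4" = effect ~ fn(c(alpha = alpha, beta = beta, gamma = gamma,
                        delta = delta), conc))
  best <- NULL
  for (start in drc_start_set(model_id, conc, effect)) {
    start <- stats::setNames(
      clamp(start, entry$lower + 1e-9,
            ifelse(is.finite(entry$upper), entry$upper - 1e-9, Inf)),
      entry$pnames)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = as.list(start),
                        lower = entry$lower, upper = entry$upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("fit failure: model ", model_id,
         " did not converge from any starting point", call. = FALSE)
  p <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  drc(model_id,
      alpha = p[["alpha"]], beta = p[["beta"]],
      gamma = if ("gamma" %in% pn) p[["gamma"]] else NULL,
      delta = if ("delta" %in% pn) p[["delta"]] else NULL,
      conc_unit = conc_unit, rss = best$rss, vcov = vc)
}

#' Predictable effect range of a set of DRCs
#'
#' Determines the part of a requested effect grid that every component
#' curve can reach, so that mixture predictions are reported only where
#' all component inverses exist.  The upper bound is the largest grid
#' effect strictly below every curve's maximum attainable effect;
#' likewise at the lower end for curves with a nonzero effect floor.
#' Grid effects outside the returned range are omitted from reports
#' rather than reported as failures.
#'
#' @param drcs List of [drc()] objects (non-empty).
#' @param grid Requested fractional effect grid (default the decadal
#'   10-90% grid).
#' @return List with `lo`, `hi` (fractional effects) and `grid`, the
#'   attainable subset of the request.
#' @examples
#' full <- drc("Logit", 2, 1.5)
#' part <- drc("Hill_three", 10, 1, 0.65)
#' predictable_effect_range(list(full, part))$hi  # 0.6
#' @export
predictable_effect_range <- function(drcs, grid = seq(0.1, 0.9, by = 0.1)) {
  if (!length(drcs)) stop("empty DRC list", call. = FALSE)
  if (inherits(drcs, "fitted_drc")) drcs <- list(drcs)
  maxe <- min(vapply(drcs, drc_max_effect, numeric(1)))
  mine <- max(vapply(drcs, drc_min_effect, numeric(1)))
  keep <- grid > mine & grid < maxe
  if (!any(keep))
    stop_unattainable(sprintf(
      "no predictable range: no requested effect lies strictly inside (%.3g, %.3g)",
      mine, maxe))
  sub <- grid[keep]
  list(lo = min(sub), hi = max(sub), grid = sub)
}
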