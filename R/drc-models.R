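# Dose-response curve (DRC) model registry.
#
# Every model maps a strictly positive concentration to a fractional effect
# in [0, 1] and is monotone non-decreasing for valid parameters (beta > 0).
# Parameters are serialized in (alpha, beta, gamma, delta) order; trailing
# parameters are omitted for lower-arity models.  gamma is the upper
# asymptote for the *_three / *_four families (partial agonists have
# gamma < 1); delta is the lower asymptote of the *_four family.
# For the Box-Cox families gamma is the Box-Cox exponent instead.

signed_pow <- function(u, p) sign(u) * abs(u)^p

stop_unattainable <- function(msg) {
  stop(structure(class = c("mixadd_unattainable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

loglog <- function(e) log(-log1p(-e))       # ln(-ln(1-e)), Weibull link
logit <- function(e) log(e / (1 - e))
boxcox <- function(c, g) (c^g - 1) / g

# Each entry: npar, pnames, bounds (lower/upper for fitting), validate,
# eval(par, conc), inv(par, e) closed-form inverse (valid strictly inside
# (min_effect, max_effect)), min_effect(par), max_effect(par),
# inv_recip_ext(par, e): 1 / inverse extended beyond the asymptote where
# the family admits the generalized-concentration-addition extension
# (Hill family), NULL otherwise.

.drc_registry <- new.env(parent = emptyenv())

register_drc_model <- function(id, entry) {
  entry$model_id <- id
  assign(id, entry, envir = .drc_registry)
  invisible(id)
}

#' List registered DRC model identifiers
#' @return Character vector of model ids usable in [drc()] and [fit_drc()].
#' @export
drc_models <- function() sort(ls(.drc_registry))

drc_model_entry <- function(id) {
  if (!is.character(id) || length(id) != 1L || !exists(id, envir = .drc_registry))
    stop("unknown DRC model id: ", id,
         " (registered: ", paste(drc_models(), collapse = ", "), ")",
         call. = FALSE)
  get(id, envir = .drc_registry)
}

local({
  pos <- function(p, nm) if (p[nm] <= 0)
    stop(nm, " must be > 0", call. = FALSE)
  frac <- function(p, nm) if (p[nm] <= 0 || p[nm] > 1)
    stop(nm, " must be in (0, 1]", call. = FALSE)

  register_drc_model("Hill", list(
    npar = 2L, pnames = c("alpha", "beta"),
    lower = c(1e-12, 1e-6), upper = c(Inf, Inf),
    validate = function(p) { pos(p, "alpha"); pos(p, "beta") },
    eval = function(p, conc) 1 / (1 + (p[["alpha"]] / conc)^p[["beta"]]),
    inv = function(p, e) p[["alpha"]] / (1 / e - 1)^(1 / p[["beta"]]),
    min_effect = function(p) 0,
    max_effect = function(p) 1,
    inv_recip_ext = function(p, e)
      signed_pow(1 / e - 1, 1 / p[["beta"]]) / p[["alpha"]]))

  register_drc_model("Hill_two", list(
    npar = 2L, pnames = c("alpha", "beta"),
    lower = c(1e-12, 1e-6), upper = c(Inf, 1),
    validate = function(p) { pos(p, "alpha"); frac(p, "beta") },
    eval = function(p, conc) p[["beta"]] * conc / (p[["alpha"]] + conc),
    inv = function(p, e) p[["alpha"]] * e / (p[["beta"]] - e),
    min_effect = function(p) 0,
    max_effect = function(p) p[["beta"]],
    inv_recip_ext = function(p, e)
      (p[["beta"]] - e) / (p[["alpha"]] * e)))

  register_drc_model("Hill_three", list(
    npar = 3L, pnames = c("alpha", "beta", "gamma"),
    lower = c(1e-12, 1e-6, 1e-6), upper = c(Inf, Inf, 1),
    validate = function(p) { pos(p, "alpha"); pos(p, "beta"); frac(p, "gamma") },
    eval = function(p, conc)
      p[["gamma"]] / (1 + (p[["alpha"]] / conc)^p[["beta"]]),
    inv = function(p, e)
      p[["alpha"]] / (p[["gamma"]] / e - 1)^(1 / p[["beta"]]),
    min_effect = function(p) 0,
    max_effect = function(p) p[["gamma"]],
    inv_recip_ext = function(p, e)
      signed_pow(p[["gamma"]] / e - 1, 1 / p[["beta"]]) / p[["alpha"]]))

  register_drc_model("Hill_four", list(
    npar = 4L, pnames = c("alpha", "beta", "gamma", "delta"),
    lower = c(1e-12, 1e-6, 1e-6, 0), upper = c(Inf, Inf, 1, 1),
    validate = function(p) {
      pos(p, "alpha"); pos(p, "beta"); frac(p, "gamma")
      if (p[["delta"]] < 0 || p[["delta"]] >= p[["gamma"]])
        stop("delta must satisfy 0 <= delta < gamma", call. = FALSE)
    },
    eval = function(p, conc)
      p[["delta"]] + (p[["gamma"]] - p[["delta"]]) /
        (1 + (p[["alpha"]] / conc)^p[["beta"]]),
    inv = function(p, e)
      p[["alpha"]] *
        ((e - p[["delta"]]) / (p[["gamma"]] - e))^(1 / p[["beta"]]),
    min_effect = function(p) p[["delta"]],
    max_effect = function(p) p[["gamma"]],
    inv_recip_ext = function(p, e)
      signed_pow((p[["gamma"]] - e) / (e - p[["delta"]]), 1 / p[["beta"]]) /
        p[["alpha"]]))

  register_drc_model("Weibull", list(
    npar = 2L, pnames = c("alpha", "beta"),
    lower = c(-Inf, 1e-6), upper = c(Inf, Inf),
    validate = function(p) pos(p, "beta"),
    eval = function(p, conc)
      -expm1(-exp(p[["alpha"]] + p[["beta"]] * log10(conc))),
    inv = function(p, e) 10^((loglog(e) - p[["alpha"]]) / p[["beta"]]),
    min_effect = function(p) 0,
    max_effect = function(p) 1,
    inv_recip_ext = NULL))

  register_drc_model("Weibull_three", list(
    npar = 3L, pnames = c("alpha", "beta", "gamma"),
    lower = c(-Inf, 1e-6, 1e-6), upper = c(Inf, Inf, 1),
    validate = function(p) { pos(p, "beta"); frac(p, "gamma") },
    eval = function(p, conc)
      p[["gamma"]] * -expm1(-exp(p[["alpha"]] + p[["beta"]] * log10(conc))),
    inv = function(p, e)
      10^((loglog(e / p[["gamma"]]) - p[["alpha"]]) / p[["beta"]]),
    min_effect = function(p) 0,
    max_effect = function(p) p[["gamma"]],
    inv_recip_ext = NULL))

  register_drc_model("Weibull_four", list(
    npar = 4L, pnames = c("alpha", "beta", "gamma", "delta"),
    lower = c(-Inf, 1e-6, 1e-6, 0), upper = c(Inf, Inf, 1, 1),
    validate = function(p) {
      pos(p, "beta"); frac(p, "gamma")
      if (p[["delta"]] < 0 || p[["delta"]] >= p[["gamma"]])
        stop("delta must satisfy 0 <= delta < gamma", call. = FALSE)
    },
    eval = function(p, conc)
      p[["delta"]] + (p[["gamma"]] - p[["delta"]]) *
        -expm1(-exp(p[["alpha"]] + p[["beta"]] * log10(conc))),
    inv = function(p, e)
      10^((loglog((e - p[["delta"]]) / (p[["gamma"]] - p[["delta"]])) -
             p[["alpha"]]) / p[["beta"]]),
    min_effect = function(p) p[["delta"]],
    max_effect = function(p) p[["gamma"]],
    inv_recip_ext = NULL))

  register_drc_model("Logit", list(
    npar = 2L, pnames = c("alpha", "beta"),
    lower = c(-Inf, 1e-6), upper = c(Inf, Inf),
    validate = function(p) pos(p, "beta"),
    eval = function(p, conc)
      stats::plogis(p[["alpha"]] + p[["beta"]] * log10(conc)),
    inv = function(p, e) 10^((logit(e) - p[["alpha"]]) / p[["beta"]]),
    min_effect = function(p) 0,
    max_effect = function(p) 1,
    inv_recip_ext = NULL))

  register_drc_model("Logit_three", list(
    npar = 3L, pnames = c("alpha", "beta", "gamma"),
    lower = c(-Inf, 1e-6, 1e-6), upper = c(Inf, Inf, 1),
    validate = function(p) { pos(p, "beta"); frac(p, "gamma") },
    eval = function(p, conc)
      p[["gamma"]] * stats::plogis(p[["alpha"]] + p[["beta"]] * log10(conc)),
    inv = function(p, e)
      10^((logit(e / p[["gamma"]]) - p[["alpha"]]) / p[["beta"]]),
    min_effect = function(p) 0,
    max_effect = function(p) p[["gamma"]],
    inv_recip_ext = NULL))

  register_drc_model("Logit_four", list(
    npar = 4L, pnames = c("alpha", "beta", "gamma", "delta"),
    lower = c(-Inf, 1e-6, 1e-6, 0), upper = c(Inf, Inf, 1, 1),
    validate = function(p) {
      pos(p, "beta"); frac(p, "gamma")
      if (p[["delta"]] < 0 || p[["delta"]] >= p[["gamma"]])
        stop("delta must satisfy 0 <= delta < gamma", call. = FALSE)
    },
    eval = function(p, conc)
      p[["delta"]] + (p[["gamma"]] - p[["delta"]]) *
        stats::plogis(p[["alpha"]] + p[["beta"]] * log10(conc)),
    inv = function(p, e)
      10^((logit((e - p[["delta"]]) / (p[["gamma"]] - p[["delta"]])) -
             p[["alpha"]]) / p[["beta"]]),
    min_effect = function(p) p[["delta"]],
    max_effect = function(p) p[["gamma"]],
    inv_recip_ext = NULL))

  # Box-Cox transformed concentration axis; gamma is the Box-Cox exponent.
  # For gamma > 0 the effect at conc -> 0+ has a positive floor; for
  # gamma < 0 the effect at conc -> Inf has a ceiling below 1.
  bc_lims <- function(p, link_inv) {
    at <- link_inv(p[["alpha"]] - p[["beta"]] / p[["gamma"]])
    if (p[["gamma"]] > 0) c(at, 1) else c(0, at)
  }
  wlink_inv <- function(z) -expm1(-exp(z))
  llink_inv <- function(z) stats::plogis(z)

  register_drc_model("BCW", list(
    npar = 3L, pnames = c("alpha", "beta", "gamma"),
    lower = c(-Inf, 1e-6, -Inf), upper = c(Inf, Inf, Inf),
    validate = function(p) {
      pos(p, "beta")
      if (p[["gamma"]] == 0) stop("gamma must be nonzero", call. = FALSE)
    },
    eval = function(p, conc)
      -expm1(-exp(p[["alpha"]] + p[["beta"]] * boxcox(conc, p[["gamma"]]))),
    inv = function(p, e) {
      t <- (loglog(e) - p[["alpha"]]) / p[["beta"]]
      (1 + p[["gamma"]] * t)^(1 / p[["gamma"]])
    },
    min_effect = function(p) bc_lims(p, wlink_inv)[1],
    max_effect = function(p) bc_lims(p, wlink_inv)[2],
    inv_recip_ext = NULL))

  register_drc_model("BCL", list(
    npar = 3L, pnames = c("alpha", "beta", "gamma"),
    lower = c(-Inf, 1e-6, -Inf), upper = c(Inf, Inf, Inf),
    validate = function(p) {
      pos(p, "beta")
      if (p[["gamma"]] == 0) stop("gamma must be nonzero", call. = FALSE)
    },
    eval = function(p, conc)
      stats::plogis(p[["alpha"]] + p[["beta"]] * boxcox(conc, p[["gamma"]])),
    inv = function(p, e) {
      t <- (logit(e) - p[["alpha"]]) / p[["beta"]]
      (1 + p[["gamma"]] * t)^(1 / p[["gamma"]])
    },
    min_effect = function(p) bc_lims(p, llink_inv)[1],
    max_effect = function(p) bc_lims(p, llink_inv)[2],
    inv_recip_ext = NULL))

  register_drc_model("GL", list(
    npar = 3L, pnames = c("alpha", "beta", "gamma"),
    lower = c(-Inf, 1e-6, 1e-6), upper = c(Inf, Inf, Inf),
    validate = function(p) { pos(p, "beta"); pos(p, "gamma") },
    eval = function(p, conc)
      (1 + exp(-p[["alpha"]] - p[["beta"]] * log10(conc)))^(-p[["gamma"]]),
    inv = function(p, e)
      10^((-p[["alpha"]] - log(e^(-1 / p[["gamma"]]) - 1)) / p[["beta"]]),
    min_effect = function(p) 0,
    max_effect = function(p) 1,
    inv_recip_ext = NULL))
})

#' Construct a fitted dose-response curve
#'
#' Pairs a registered regression model with its parameters and the
#' concentration unit the curve was fitted in.  All models are monotone
#' non-decreasing in concentration; the attainable effect is the open
#' interval between [drc_min_effect()] and [drc_max_effect()] (for the
#' three-parameter asymptote families the maximum equals `gamma`).
#'
#' @param model_id Registered model id, see [drc_models()].
#' @param alpha,beta First two regression parameters (location/slope,
#'   model-specific; for the Hill family `alpha` is the concentration of
#'   half-asymptotic effect).
#' @param gamma Third parameter (upper asymptote, or Box-Cox exponent for
#'   the `BCW`/`BCL` models); omit for 2-parameter models.
#' @param delta Lower asymptote of the 4-parameter models.
#' @param conc_unit Concentration unit of the curve, see
#'   [concentration_units()].
#' @param rss Optional residual sum of squares from fitting.
#' @param vcov Optional parameter covariance matrix from fitting (used by
#'   the parametric bootstrap).
#' @return An object of class `fitted_drc`.
#' @examples
#' d <- drc("Hill_three", alpha = 10, beta = 1.2, gamma = 0.6, conc_unit = "uM")
#' evaluate_drc(d, 10)    # half of the 0.6 asymptote
#' @export
drc <- function(model_id, alpha, beta, gamma = NULL, delta = NULL,
                conc_unit = "uM", rss = NULL, vcov = NULL) {
  entry <- drc_model_entry(model_id)
  par <- c(alpha = alpha, beta = beta)
  if (!is.null(gamma) && !is.na(gamma)) par <- c(par, gamma = gamma)
  if (!is.null(delta) && !is.na(delta)) par <- c(par, delta = delta)
  if (length(par) != entry$npar)
    stop("model ", model_id, " takes ", entry$npar,
         " parameters (", paste(entry$pnames, collapse = ", "),
         "), got ", length(par), call. = FALSE)
  names(par) <- entry$pnames
  if (any(!is.finite(par))) stop("DRC parameters must be finite", call. = FALSE)
  entry$validate(par)
  structure(list(model_id = model_id, par = par,
                 conc_unit = normalize_unit(conc_unit),
                 rss = rss, vcov = vcov),
            class = "fitted_drc")
}

#' @export
print.fitted_drc <- function(x, ...) {
  cat(sprintf("<fitted_drc %s (%s): %s; max effect %.4g>\n",
              x$model_id, x$conc_unit,
              paste(sprintf("%s=%.6g", names(x$par), x$par), collapse = ", "),
              drc_max_effect(x)))
  invisible(x)
}

#' Evaluate a DRC at given concentrations
#'
#' @param drc A [drc()] object.
#' @param conc Strictly positive concentration(s) in `drc$conc_unit`.
#' @return Fractional effect(s) in `[0, 1]`.
#' @export
evaluate_drc <- function(drc, conc) {
  stopifnot(inherits(drc, "fitted_drc"))
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc <= 0))
    stop("concentration must be strictly positive and finite", call. = FALSE)
  entry <- drc_model_entry(drc$model_id)
  pmin(1, pmax(0, entry$eval(drc$par, conc)))
}

#' Maximum attainable effect of a DRC
#' @param drc A [drc()] object.
#' @return Supremum of the curve's effect as concentration grows without
#'   bound (equals `gamma` for the three-parameter asymptote families).
#' @export
drc_max_effect <- function(drc) {
  entry <- drc_model_entry(drc$model_id)
  min(1, entry$max_effect(drc$par))
}

#' Minimum effect of a DRC (limit at zero concentration)
#' @param drc A [drc()] object.
#' @return Infimum of the curve's effect; 0 except for Box-Cox models with
#'   positive exponent.
#' @export
drc_min_effect <- function(drc) {
  entry <- drc_model_entry(drc$model_id)
  max(0, entry$min_effect(drc$par))
}

#' Invert a DRC: concentration producing a given effect
#'
#' Uses the model's closed-form inverse where the registry provides one,
#' otherwise deterministic bisection on log10(concentration).  Effects at
#' or above the curve's maximum attainable effect raise a condition of
#' class `mixadd_unattainable` (this drives predictable-range truncation).
#'
#' @param drc A [drc()] object.
#' @param effect Fractional effect(s), strictly inside the attainable range.
#' @return Concentration(s) in `drc$conc_unit`.
#' @export
inverse_drc <- function(drc, effect) {
  stopifnot(inherits(drc, "fitted_drc"))
  if (!is.numeric(effect) || any(!is.finite(effect)) || any(effect <= 0))
    stop("effect must be in (0, max attainable effect)", call. = FALSE)
  hi <- drc_max_effect(drc)
  lo <- drc_min_effect(drc)
  if (any(effect >= hi))
    stop_unattainable(sprintf(
      "effect %.4g unattainable: %s curve's maximum attainable effect is %.4g",
      max(effect), drc$model_id, hi))
  if (any(effect <= lo))
    stop_unattainable(sprintf(
      "effect %.4g below the %s curve's minimum effect %.4g",
      min(effect), drc$model_id, lo))
  entry <- drc_model_entry(drc$model_id)
  if (!is.null(entry$inv)) {
    vapply(effect, function(e) entry$inv(drc$par, e), numeric(1))
  } else {
    vapply(effect, function(e) drc_inverse_bisect(drc, e), numeric(1))
  }
}

# Deterministic bisection on log10(concentration) for monotone curves;
# bracket auto-expanded one decade at a time from the model midpoint.
drc_inverse_bisect <- function(drc, e, tol = 1e-9) {
  f <- function(x) evaluate_drc(drc, 10^x) - e
  x0 <- 0
  lo <- x0; hi <- x0
  for (i in 1:320) { if (f(lo) < 0) break; lo <- lo - 1 }
  for (i in 1:320) { if (f(hi) > 0) break; hi <- hi + 1 }
  if (f(lo) > 0 || f(hi) < 0)
    stop_unattainable("no concentration bracket attains the requested effect")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol && (hi - lo) < 1e-12) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

# Reciprocal of the inverse, extended past the asymptote for the Hill
# family (the generalized-concentration-addition extension); used by the
# GCA solver.  Returns 1 / f^{-1}(e); negative above the asymptote.
drc_inv_recip_ext <- function(drc, e) {
  entry <- drc_model_entry(drc$model_id)
  if (!is.null(entry$inv_recip_ext)) return(entry$inv_recip_ext(drc$par, e))
  hi <- drc_max_effect(drc)
  if (e >= hi)
    stop_unattainable(sprintf(
      "model %s has no inverse-function extension above its maximum effect %.4g",
      drc$model_id, hi))
  1 / inverse_drc(drc, e)
}

# Does the model family admit the GCA extension past its asymptote?
drc_has_extension <- function(drc) {
  !is.null(drc_model_entry(drc$model_id)$inv_recip_ext)
}
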