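# The additivity predictors: CA, IA, GCA and Simple-CA.
#
# All functions work on a mixture_spec whose components carry DRCs
# (Simple-CA needs only summary endpoints) and express concentrations in
# the spec's output unit.  Composition fractions p_i are on the same
# basis as that unit.

# Deterministic bisection on log10(concentration) of a monotone
# non-decreasing effect function; absolute tolerance on effect 1e-9.
bisect_log_conc <- function(fun, target, x_init = 0, tol = 1e-9) {
  g <- function(x) fun(10^x) - target
  lo <- x_init; hi <- x_init
  for (i in 1:320) { if (g(lo) < 0) break; lo <- lo - 1 }
  for (i in 1:320) { if (g(hi) > 0) break; hi <- hi + 1 }
  if (g(lo) > 0 || g(hi) < 0)
    stop_unattainable("target effect outside the attainable range")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) < tol && (hi - lo) < 1e-12) break
    if (gm < 0) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

#' Concentration-addition effective concentration
#'
#' The CA (Loewe additivity) mixture concentration producing a given
#' effect: the reciprocal of the fraction-weighted sum of reciprocal
#' component effective concentrations,
#' `c = 1 / sum_i(p_i / EC_{effect,i})`.
#'
#' @param spec A [mixture_spec()] whose components all carry DRCs.
#' @param effect Fractional effect level(s) within the predictable range.
#' @return Mixture concentration(s) in `spec$output_unit`.
#' @export
ca_effective_concentration <- function(spec, effect) {
  stopifnot(inherits(spec, "mixture_spec"))
  s <- spec_conv_scales(spec)
  drcs <- spec_drcs(spec)
  p <- spec_fractions(spec)
  vapply(effect, function(e) {
    ec <- mapply(function(d, si) inverse_drc(d, e) * si, drcs, s)
    1 / sum(p / ec)
  }, numeric(1))
}

#' Independent-action mixture effect
#'
#' The IA (Bliss independence, response addition) effect of the mixture
#' at total concentration `conc`:
#' `E = 1 - prod_i(1 - f_i(p_i * conc))`.  A component whose scaled dose
#' falls below its curve's numerical domain contributes no effect
#' (factor 1).
#'
#' @param spec A [mixture_spec()] whose components all carry DRCs.
#' @param conc Strictly positive mixture concentration(s) in
#'   `spec$output_unit`.
#' @return Fractional mixture effect(s).
#' @export
ia_effect <- function(spec, conc) {
  stopifnot(inherits(spec, "mixture_spec"))
  p <- spec_fractions(spec)
  s <- spec_conv_scales(spec)
  drcs <- spec_drcs(spec)
  vapply(conc, function(cc) {
    if (cc <= 0) stop("concentration must be strictly positive", call. = FALSE)
    eff <- mapply(function(d, pi, si) {
      dose <- pi * cc / si           # back to the curve's own unit
      if (dose <= 0) 0 else evaluate_drc(d, dose)
    }, drcs, p, s)
    1 - prod(1 - eff)
  }, numeric(1))
}

# Supremum of the IA mixture effect.
ia_max_effect <- function(spec) {
  1 - prod(1 - vapply(spec_drcs(spec), drc_max_effect, numeric(1)))
}

#' Independent-action effective concentration
#'
#' Numeric inversion of [ia_effect()] by bisection on
#' log10(concentration).
#'
#' @inheritParams ca_effective_concentration
#' @return Mixture concentration(s) in `spec$output_unit`.
#' @export
ia_effective_concentration <- function(spec, effect) {
  stopifnot(inherits(spec, "mixture_spec"))
  supe <- ia_max_effect(spec)
  vapply(effect, function(e) {
    if (e <= 0 || e >= supe)
      stop_unattainable(sprintf(
        "effect %.4g outside IA's attainable range (0, %.4g)", e, supe))
    bisect_log_conc(function(cc) ia_effect(spec, cc), e)
  }, numeric(1))
}

#' Generalized-concentration-addition mixture effect
#'
#' The GCA mixture effect at total concentration `conc`: the effect `E`
#' solving `sum_i (p_i * conc) / f_i^{-1}(E) = 1`, where `f_i^{-1}` is
#' each component's inverse dose-response function.  For effect levels
#' above a Hill-family component's asymptote the inverse-function
#' extension of the regression model is used (its reciprocal passes
#' smoothly through zero and goes negative), which is what lets GCA
#' interpolate mixtures containing partial agonists.  Non-Hill components
#' cap the feasible effect at their own asymptote.
#'
#' @param spec A [mixture_spec()] whose components all carry DRCs.
#' @param conc Strictly positive mixture concentration(s) in
#'   `spec$output_unit`.
#' @return Fractional mixture effect(s).
#' @export
gca_effect <- function(spec, conc) {
  stopifnot(inherits(spec, "mixture_spec"))
  p <- spec_fractions(spec)
  s <- spec_conv_scales(spec)
  drcs <- spec_drcs(spec)
  ext <- vapply(drcs, drc_has_extension, logical(1))
  caps <- vapply(drcs, drc_max_effect, numeric(1))
  e_hi <- if (all(ext)) 1 - 1e-12 else min(caps[!ext]) - 1e-12
  vapply(conc, function(cc) {
    if (cc <= 0) stop("concentration must be strictly positive", call. = FALSE)
    # h(E) is strictly decreasing: +Inf at E -> 0+, so a root of h = 0 in
    # (0, e_hi) exists iff h(e_hi) < 0.
    h <- function(E) {
      sum(mapply(function(d, pi, si)
        pi * cc * drc_inv_recip_ext(d, E) / si, drcs, p, s)) - 1
    }
    lo <- max(1e-12,
              max(vapply(drcs, drc_min_effect, numeric(1))) + 1e-12)
    hi <- e_hi
    if (h(hi) > 0) return(e_hi)   # effect pinned at the feasibility cap
    if (h(lo) < 0) return(lo)     # dose so small the effect sits at the floor
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (h(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-13) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Generalized-concentration-addition effective concentration
#'
#' Numeric inversion of [gca_effect()] by bisection on
#' log10(concentration).
#'
#' @inheritParams ca_effective_concentration
#' @return Mixture concentration(s) in `spec$output_unit`.
#' @export
gca_effective_concentration <- function(spec, effect) {
  stopifnot(inherits(spec, "mixture_spec"))
  vapply(effect, function(e) {
    if (e <= 0 || e >= 1)
      stop_unattainable("effect must lie strictly inside (0, 1)")
    bisect_log_conc(function(cc) gca_effect(spec, cc), e)
  }, numeric(1))
}

#' Simple-CA mixture EC50 from summary endpoints
#'
#' Estimates a mixture EC50/LC50 from component summary endpoints alone
#' (no DRCs): `EC50_mix = 1 / sum_i(w_i / EC50_i)`.  The weights are used
#' exactly as entered and are NOT renormalized; their sum may be below 1
#' when a composition range's extremes are used (worst-case scenarios).
#'
#' @param weights Composition fractions in (0, 1], as entered.
#' @param ec50s List of [conc_value()] endpoints (or a numeric vector,
#'   then `units` supplies their shared unit).
#' @param output_unit Unit of the returned endpoint.
#' @param mws Molecular weights (g/mol), needed only when a conversion
#'   crosses the molar/mass boundary.
#' @param units Unit(s) for a bare numeric `ec50s`.
#' @return The mixture endpoint as a [conc_value()] in `output_unit`.
#' @examples
#' simple_ca_ec50(c(0.75, 0.05, 0.05, 0.05),
#'                c(11.5, 1983, 1000, 9268), units = "mg/L",
#'                output_unit = "mg/L")
#' @export
simple_ca_ec50 <- function(weights, ec50s, output_unit = "mg/L",
                           mws = NULL, units = NULL) {
  if (is.numeric(ec50s)) {
    if (is.null(units)) stop("`units` required for numeric ec50s", call. = FALSE)
    units <- rep_len(units, length(ec50s))
    ec50s <- mapply(conc_value, ec50s, units, SIMPLIFY = FALSE)
  }
  if (length(weights) != length(ec50s))
    stop("weights and ec50s lengths differ", call. = FALSE)
  if (any(weights <= 0 | weights > 1))
    stop("weights must lie in (0, 1]", call. = FALSE)
  if (is.null(mws)) mws <- rep(NA_real_, length(weights))
  vals <- mapply(function(ec, mw) {
    if (ec$value <= 0) stop("EC50 values must be > 0", call. = FALSE)
    convert_concentration(ec, output_unit,
                          mw = if (is.na(mw)) NULL else mw)$value
  }, ec50s, mws)
  conc_value(1 / sum(weights / vals), output_unit)
}
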