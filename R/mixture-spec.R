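# Mixture specification: components, fractions, endpoints, curves.

#' A single mixture component
#'
#' @param name Chemical name (required).
#' @param fraction Composition fraction in (0, 1], on the same basis as
#'   the working concentration unit (molar fractions for molar units,
#'   mass fractions for mass units).
#' @param cas CAS registry number (text), optional.
#' @param mw Molecular weight in g/mol, optional (required when the
#'   component's concentrations must cross the molar/mass unit boundary).
#' @param endpoint_value Optional summary endpoint (EC50/LC50) as a
#'   [conc_value()].
#' @param drc Optional fitted dose-response curve, a [drc()] object.
#'   At least one of `endpoint_value` or `drc` is needed for any
#'   prediction.
#' @param structure Optional structure reference: a SMILES string.
#' @return An object of class `mixture_component`.
#' @export
mixture_component <- function(name, fraction, cas = NA_character_,
                              mw = NA_real_, endpoint_value = NULL,
                              drc = NULL, structure = NULL) {
  if (!is.character(name) || !nzchar(name))
    stop("component name is required", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop("fraction must lie in (0, 1] (component ", name, ")", call. = FALSE)
  if (!is.null(endpoint_value) && !inherits(endpoint_value, "conc_value"))
    stop("endpoint_value must be a conc_value (component ", name, ")",
         call. = FALSE)
  if (!is.null(drc) && !inherits(drc, "fitted_drc"))
    stop("drc must be a fitted_drc (component ", name, ")", call. = FALSE)
  structure(list(name = name, cas = as.character(cas), fraction = fraction,
                 mw = as.numeric(mw), endpoint_value = endpoint_value,
                 drc = drc, structure = structure),
            class = "mixture_component")
}

needs_mw <- function(comp, output_unit) {
  u <- c(if (!is.null(comp$drc)) comp$drc$conc_unit,
         if (!is.null(comp$endpoint_value)) comp$endpoint_value$unit)
  any(unit_family(u) != unit_family(output_unit))
}

#' A mixture specification
#'
#' An ordered set of at least two components with a common output
#' concentration unit and endpoint type.  Components with fraction 0 are
#' dropped with a warning; duplicated CAS numbers are allowed (a
#' sub-mixture may repeat a chemical) but warned about.
#'
#' @param components List of [mixture_component()] objects (>= 2 after
#'   dropping zero fractions).
#' @param product_name Product label used in reports.
#' @param output_unit Concentration unit of all predictions.
#' @param endpoint_type `"EC50"` or `"LC50"` (report label only).
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, product_name = "mixture",
                         output_unit = "uM", endpoint_type = "EC50") {
  if (!is.list(components) ||
      !all(vapply(components, inherits, logical(1), "mixture_component")))
    stop("components must be a list of mixture_component objects",
         call. = FALSE)
  zero <- vapply(components, function(x) x$fraction == 0, logical(1))
  if (any(zero)) {
    warning("dropping ", sum(zero), " component(s) with fraction 0: ",
            paste(vapply(components[zero], `[[`, "", "name"), collapse = ", "),
            call. = FALSE)
    components <- components[!zero]
  }
  if (length(components) < 2L)
    stop("a mixture needs at least two components", call. = FALSE)
  endpoint_type <- match.arg(toupper(endpoint_type), c("EC50", "LC50"))
  output_unit <- normalize_unit(output_unit)
  cas <- vapply(components, `[[`, "", "cas")
  dup <- unique(cas[!is.na(cas) & nzchar(cas) & duplicated(cas)])
  if (length(dup))
    warning("duplicated CAS number(s) in mixture: ",
            paste(dup, collapse = ", "), call. = FALSE)
  for (comp in components) {
    if (is.null(comp$endpoint_value) && is.null(comp$drc))
      next  # allowed at spec level; prediction-time validation names the model
    if (needs_mw(comp, output_unit) && (is.na(comp$mw) || comp$mw <= 0))
      stop("component ", comp$name, ": molecular weight required to convert ",
           "its concentrations to ", output_unit, call. = FALSE)
  }
  structure(list(product_name = product_name, components = components,
                 output_unit = output_unit, endpoint_type = endpoint_type),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec '%s': %d components, unit %s, endpoint %s>\n",
              x$product_name, length(x$components), x$output_unit,
              x$endpoint_type))
  for (comp in x$components)
    cat(sprintf("  %-28s p=%.4g %s%s\n", comp$name, comp$fraction,
                if (!is.null(comp$drc)) paste0("[", comp$drc$model_id, "] ") else "",
                if (!is.null(comp$endpoint_value))
                  sprintf("%s=%.4g %s", x$endpoint_type,
                          comp$endpoint_value$value, comp$endpoint_value$unit)
                else ""))
  invisible(x)
}

spec_fractions <- function(spec)
  vapply(spec$components, `[[`, numeric(1), "fraction")

spec_drcs <- function(spec) lapply(spec$components, `[[`, "drc")

spec_has_drcs <- function(spec)
  all(!vapply(spec_drcs(spec), is.null, logical(1)))

# Multiplicative scale turning a concentration in a component DRC's own
# unit into `unit` (unit conversions are linear, so this is computed once
# and reused in solver loops).
spec_conv_scales <- function(spec) {
  vapply(spec$components, function(comp) {
    if (is.null(comp$drc)) return(NA_real_)
    convert_concentration(1, spec$output_unit,
                          mw = if (is.na(comp$mw)) NULL else comp$mw,
                          from = comp$drc$conc_unit)
  }, numeric(1))
}

# Concentration-at-effect for one component, expressed in `unit`.
component_inverse <- function(comp, effect, unit) {
  if (is.null(comp$drc))
    stop("component ", comp$name, " has no DRC", call. = FALSE)
  c_model <- inverse_drc(comp$drc, effect)
  convert_concentration(c_model, unit, mw = comp$mw, from = comp$drc$conc_unit)
}

# Effect of one component at a concentration given in `unit`.
component_effect <- function(comp, conc, unit) {
  if (is.null(comp$drc))
    stop("component ", comp$name, " has no DRC", call. = FALSE)
  c_model <- convert_concentration(conc, comp$drc$conc_unit, mw = comp$mw,
                                   from = unit)
  evaluate_drc(comp$drc, c_model)
}
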