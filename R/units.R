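# Concentration units and inter-conversion.
#
# Five units are supported, in two families:
#   molar: nM, uM, mM        (stored internally as mol/L)
#   mass : ug/L, mg/L        (stored internally as g/L)
# Crossing the family boundary requires a molecular weight (g/mol).

.unit_table <- data.frame(
  unit   = c("nM", "uM", "mM", "ug/L", "mg/L"),
  family = c("molar", "molar", "molar", "mass", "mass"),
  factor = c(1e-9, 1e-6, 1e-3, 1e-6, 1e-3),
  stringsAsFactors = FALSE
)

#' Supported concentration units
#'
#' @return Character vector of the five recognised concentration units.
#' @export
concentration_units <- function() .unit_table$unit

#' Normalise a concentration unit string
#'
#' Accepts common spelling variants (`"µM"`, `"μM"`, `"ug/l"`,
#' `"µg/L"`, case differences) and returns the canonical form used
#' throughout the package (`"nM"`, `"uM"`, `"mM"`, `"ug/L"`, `"mg/L"`).
#'
#' @param unit Character scalar (or vector) naming a unit.
#' @return Canonical unit string(s).
#' @export
normalize_unit <- function(unit) {
  if (length(unit) == 0L || any(is.na(unit)))
    stop("concentration unit is missing", call. = FALSE)
  u <- trimws(as.character(unit))
  # micro sign (U+00B5) and Greek mu (U+03BC) both map to "u"
  u <- gsub("µ|μ", "u", u)
  canon <- c("nm" = "nM", "um" = "uM", "mm" = "mM",
             "ug/l" = "ug/L", "mg/l" = "mg/L")
  out <- canon[tolower(u)]
  if (any(is.na(out)))
    stop("unknown concentration unit: ",
         paste(unique(u[is.na(out)]), collapse = ", "),
         " (supported: ", paste(concentration_units(), collapse = ", "), ")",
         call. = FALSE)
  unname(out)
}

unit_family <- function(unit) {
  .unit_table$family[match(normalize_unit(unit), .unit_table$unit)]
}

unit_factor <- function(unit) {
  .unit_table$factor[match(normalize_unit(unit), .unit_table$unit)]
}

#' Concentration value with unit
#'
#' Lightweight container pairing a non-negative magnitude with one of the
#' five supported concentration units.
#'
#' @param value Non-negative numeric magnitude(s).
#' @param unit Unit string, see [concentration_units()].
#' @return An object of class `conc_value` with fields `value` and `unit`.
#' @examples
#' conc_value(11.5, "mg/L")
#' @export
conc_value <- function(value, unit) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0))
    stop("concentration value must be finite and non-negative", call. = FALSE)
  structure(list(value = as.numeric(value), unit = normalize_unit(unit)),
            class = "conc_value")
}

#' @export
print.conc_value <- function(x, ...) {
  cat(paste(format(x$value), x$unit), sep = "\n")
  invisible(x)
}

#' Convert a concentration between units
#'
#' Converts within the molar chain (nM, uM, mM) or the mass chain
#' (ug/L, mg/L) by exact metric arithmetic; conversions crossing the
#' molar/mass boundary additionally require the molecular weight.
#'
#' @param x A [conc_value()], or a numeric magnitude (then `from` is
#'   required).
#' @param target_unit Unit to convert to.
#' @param mw Molecular weight in g/mol; required only for molar <-> mass
#'   conversions.
#' @param from Source unit when `x` is a bare numeric.
#' @return A `conc_value` in `target_unit` (or a bare numeric if `x` was
#'   numeric).
#' @examples
#' convert_concentration(conc_value(1, "mg/L"), "uM", mw = 100) # 10 uM
#' convert_concentration(1000, "uM", from = "nM")               # 1
#' @export
convert_concentration <- function(x, target_unit, mw = NULL, from = NULL) {
  bare <- is.numeric(x)
  if (bare) {
    if (is.null(from)) stop("`from` unit required for numeric input", call. = FALSE)
    x <- conc_value(x, from)
  }
  src <- x$unit
  dst <- normalize_unit(target_unit)
  fam_s <- unit_family(src)
  fam_d <- unit_family(dst)
  v <- x$value * unit_factor(src)        # mol/L or g/L
  if (fam_s != fam_d) {
    if (is.null(mw) || is.na(mw) || !is.numeric(mw) || mw <= 0)
      stop("molecular weight required to convert ", src, " to ", dst,
           call. = FALSE)
    v <- if (fam_s == "molar") v * mw else v / mw   # mol/L*g/mol = g/L
  }
  out <- v / unit_factor(dst)
  if (bare) out else conc_value(out, dst)
}
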