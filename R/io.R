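# Reading mixture templates and structure files; writing reports.
#
# The template is UTF-8 delimited text (comma for .csv, tab for .tsv/.txt),
# dot decimal, one row per component, with the fixed column set below.
# Compositions are carried as percent in files (GUI convention) and as
# fractions inside the engine; the conversion happens only at this
# boundary.

.template_columns <- c("name", "cas", "component_type", "physical_state",
                       "composition_pct", "mw", "endpoint_type",
                       "endpoint_value", "endpoint_unit", "drc_model",
                       "drc_unit", "alpha", "beta", "gamma", "delta",
                       "smiles")
.mandatory_columns <- c("name", "composition_pct")

#' Template column names
#' @return Character vector of the mixture-template columns; the
#'   mandatory ones are `name` and `composition_pct`.
#' @export
template_columns <- function() .template_columns

blankish <- function(x) is.na(x) | (is.character(x) & !nzchar(trimws(x)))

#' Read a mixture specification from a delimited-text template
#'
#' Parses and validates a component table (see [template_columns()]),
#' returning a [mixture_spec()].  Percent compositions are converted to
#' fractions; DRC parameter fields must be all-present or all-absent per
#' row (to the model's arity).  Rows with neither an endpoint value nor a
#' DRC limit model availability; a warning per such row is collected in
#' the `warnings` attribute of the result.
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt` (tab) template.
#' @param output_unit Concentration unit for predictions.
#' @param product_name Product label; defaults to the file name.
#' @param endpoint_type `"EC50"` or `"LC50"`.
#' @return A [mixture_spec()]; attribute `warnings` holds row-addressed
#'   validation notes.
#' @export
read_mixture_table <- function(path, output_unit = "uM",
                               product_name = NULL, endpoint_type = "EC50") {
  if (!file.exists(path)) stop("template not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(.mandatory_columns, names(df))
  if (length(missing_cols))
    stop("template missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in setdiff(.template_columns, names(df))) df[[col]] <- NA
  warnings <- character()
  comps <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    where <- sprintf("row %d (%s)", i, row$name)
    if (blankish(row$name))
      stop("row ", i, ": mandatory field 'name' is empty", call. = FALSE)
    if (is.na(row$composition_pct) || row$composition_pct <= 0 ||
        row$composition_pct > 100)
      stop(where, ": composition_pct must lie in (0, 100]", call. = FALSE)
    ep <- NULL
    if (!blankish(row$endpoint_value)) {
      if (blankish(row$endpoint_unit))
        stop(where, ": endpoint_value given without endpoint_unit",
             call. = FALSE)
      ep <- conc_value(as.numeric(row$endpoint_value), row$endpoint_unit)
    }
    dr <- NULL
    drc_fields <- c(!blankish(row$drc_model), !blankish(row$alpha),
                    !blankish(row$beta))
    if (any(drc_fields)) {
      if (!all(drc_fields))
        stop(where, ": DRC fields (drc_model, alpha, beta) must be ",
             "all-present or all-absent", call. = FALSE)
      entry <- drc_model_entry(as.character(row$drc_model))
      need3 <- entry$npar >= 3L
      if (need3 && blankish(row$gamma))
        stop(where, ": model ", row$drc_model, " needs gamma", call. = FALSE)
      if (entry$npar >= 4L && blankish(row$delta))
        stop(where, ": model ", row$drc_model, " needs delta", call. = FALSE)
      if (blankish(row$drc_unit))
        stop(where, ": DRC given without drc_unit", call. = FALSE)
      dr <- drc(as.character(row$drc_model),
                alpha = as.numeric(row$alpha), beta = as.numeric(row$beta),
                gamma = if (need3) as.numeric(row$gamma) else NULL,
                delta = if (entry$npar >= 4L) as.numeric(row$delta) else NULL,
                conc_unit = as.character(row$drc_unit))
    }
    if (is.null(ep) && is.null(dr))
      warnings <- c(warnings, paste0(
        where, ": no toxicity information; only models that do not need ",
        "it will be available"))
    comps[[i]] <- mixture_component(
      name = as.character(row$name),
      cas = if (blankish(row$cas)) NA_character_ else as.character(row$cas),
      fraction = row$composition_pct / 100,
      mw = if (blankish(row$mw)) NA_real_ else as.numeric(row$mw),
      endpoint_value = ep, drc = dr,
      structure = if (blankish(row$smiles)) NULL else as.character(row$smiles))
  }
  spec <- mixture_spec(comps,
                       product_name = product_name %||%
                         tools::file_path_sans_ext(basename(path)),
                       output_unit = output_unit,
                       endpoint_type = endpoint_type)
  attr(spec, "warnings") <- warnings
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mixture specification as a template
#'
#' Inverse of [read_mixture_table()]; a written spec reads back
#' identically.
#'
#' @param spec A [mixture_spec()].
#' @param path Output `.csv` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_mixture_table <- function(spec, path) {
  stopifnot(inherits(spec, "mixture_spec"))
  rows <- lapply(spec$components, function(comp) {
    d <- comp$drc
    np <- if (is.null(d)) 0L else drc_model_entry(d$model_id)$npar
    data.frame(
      name = comp$name, cas = comp$cas %||% NA,
      component_type = "substance", physical_state = NA,
      composition_pct = 100 * comp$fraction, mw = comp$mw,
      endpoint_type = spec$endpoint_type,
      endpoint_value = if (is.null(comp$endpoint_value)) NA
                       else comp$endpoint_value$value,
      endpoint_unit = if (is.null(comp$endpoint_value)) NA
                      else comp$endpoint_value$unit,
      drc_model = if (is.null(d)) NA else d$model_id,
      drc_unit = if (is.null(d)) NA else d$conc_unit,
      alpha = if (is.null(d)) NA else unname(d$par["alpha"]),
      beta = if (is.null(d)) NA else unname(d$par["beta"]),
      gamma = if (np >= 3L) unname(d$par["gamma"]) else NA,
      delta = if (np >= 4L) unname(d$par["delta"]) else NA,
      smiles = if (is.null(comp$structure)) NA else as.character(comp$structure),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read structures and key them to components
#'
#' Accepts a SMILES list (`.smi`/`.smiles`: one `SMILES name` pair per
#' line, or a delimited file with `smiles` and optional `cas` columns), a
#' single MOL file, or a (multi-record) SDF.  SDF records are associated
#' with components by a `CAS` data field when one is present in every
#' record, otherwise by order.
#'
#' @param path Structure file.
#' @param spec Optional [mixture_spec()] to key against (checks counts
#'   and CAS correspondence).
#' @return A `ChemmineR::SDFset` whose ids are component names (when
#'   `spec` is given) or record ids.
#' @export
read_structures <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "smiles")) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    parts <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(parts, `[[`, "", 1)
    nms <- vapply(parts, function(x) if (length(x) > 1) x[2] else NA, "")
    if (any(is.na(nms))) nms <- paste0("record", seq_along(smi))
    sdf <- parse_smiles(smi, nms)
  } else if (ext %in% c("mol", "sdf")) {
    sdf <- tryCatch(ChemmineR::read.SDFset(path),
                    error = function(e)
                      stop("cannot parse ", path, ": ", conditionMessage(e),
                           call. = FALSE))
    valid <- ChemmineR::validSDF(sdf)
    if (!all(valid))
      stop("corrupt structure record(s) in ", basename(path), ": record ",
           paste(which(!valid), collapse = ", "), call. = FALSE)
  } else stop("unsupported structure format: .", ext, call. = FALSE)

  if (!is.null(spec)) {
    n <- length(spec$components)
    if (length(sdf) != n)
      stop("record count mismatch: ", length(sdf), " structures for ", n,
           " components", call. = FALSE)
    nms <- vapply(spec$components, `[[`, "", "name")
    cas_spec <- vapply(spec$components, `[[`, "", "cas")
    db <- ChemmineR::datablock(sdf)
    cas_sdf <- vapply(seq_along(sdf), function(i) {
      d <- db[[i]]
      if (length(d) && "CAS" %in% names(d)) unname(d[["CAS"]])
      else NA_character_
    }, character(1))
    if (!any(is.na(cas_sdf)) && !any(is.na(cas_spec)) &&
        setequal(cas_sdf, cas_spec)) {
      sdf <- sdf[match(cas_spec, cas_sdf)]
    }
    ChemmineR::cid(sdf) <- make.unique(nms)
  }
  sdf
}

#' Attach structures to a mixture specification
#'
#' Stores each molecule's canonical SMILES on the matching component.
#'
#' @param spec A [mixture_spec()].
#' @param sdf An `SDFset` from [read_structures()] (keyed by order).
#' @return The updated spec.
#' @export
attach_structures <- function(spec, sdf) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (length(sdf) != length(spec$components))
    stop("structure count mismatch", call. = FALSE)
  smi <- ChemmineR::sdf2smiles(sdf)
  for (i in seq_along(spec$components))
    spec$components[[i]]$structure <- as.character(smi)[i]
  spec
}

#' Write a prediction report
#'
#' Emits, under `dir`: `summary.json` (product, lowest predicted ECx,
#' per-model status, top-5 components by fraction), `effect_table.csv`
#' (the 10-90% effect grid per model, with CI columns when
#' bootstrapped), `input_echo.csv` (the input template echoed back) and
#' `results.json` (the full machine-readable grid).
#'
#' @param pred A [predict_mixture()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(pred, dir) {
  stopifnot(inherits(pred, "mixture_prediction"))
  ok <- vapply(pred$results, function(r) is.null(r$error), logical(1))
  if (!length(pred$results) || !any(ok))
    stop("empty results: nothing to report", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create report directory ", dir,
                             call. = FALSE)
  spec <- pred$spec
  p <- spec_fractions(spec)
  ord <- order(p, decreasing = TRUE)
  top <- utils::head(ord, 5)
  summary <- list(
    product_name = pred$product_name,
    endpoint_type = pred$endpoint_type,
    unit = pred$unit,
    models = pred$models,
    model_status = lapply(pred$results, function(r)
      if (is.null(r$error)) "ok" else r$error),
    lowest_predicted = pred$lowest,
    composition_top5 = data.frame(
      name = vapply(spec$components[top], `[[`, "", "name"),
      cas = vapply(spec$components[top], `[[`, "", "cas"),
      fraction = p[top]),
    scalar_endpoints = Filter(Negate(is.null), lapply(pred$results,
      function(r) if (is.null(r$scalar)) NULL
      else list(model = r$model, value = r$scalar$value,
                unit = r$scalar$unit))))
  files <- file.path(dir, c("summary.json", "effect_table.csv",
                            "input_echo.csv", "results.json"))
  jsonlite::write_json(summary, files[1], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  tab <- prediction_table(pred)
  utils::write.csv(tab, files[2], row.names = FALSE, na = "")
  write_mixture_table(spec, files[3])
  jsonlite::write_json(
    list(product_name = pred$product_name, unit = pred$unit,
         table = tab, lowest_predicted = pred$lowest),
    files[4], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(files)
}
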