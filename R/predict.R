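# Effect-grid prediction over selected additivity models, with optional
# parametric-bootstrap confidence intervals.

.model_names <- c("CA", "IA", "GCA", "TSP", "SimpleCA")

normalize_model_selection <- function(models) {
  if (!length(models)) stop("empty model selection", call. = FALSE)
  m <- gsub("[-_ ]", "", toupper(as.character(models)))
  map <- c(CA = "CA", IA = "IA", GCA = "GCA", TSP = "TSP",
           QSARTSP = "TSP", SIMPLECA = "SimpleCA")
  out <- map[m]
  if (any(is.na(out)))
    stop("unknown model(s): ", paste(models[is.na(out)], collapse = ", "),
         " (choose from ", paste(.model_names, collapse = ", "), ")",
         call. = FALSE)
  unique(unname(out))
}

# Effective concentrations for one model over a fractional-effect grid;
# NA where the level is not attainable for that model.
model_effective_concentrations <- function(spec, model, grid,
                                           clustering = NULL) {
  ec_at <- function(e) {
    tryCatch(switch(model,
      CA  = ca_effective_concentration(spec, e),
      IA  = ia_effective_concentration(spec, e),
      GCA = gca_effective_concentration(spec, e),
      TSP = tsp_effective_concentration(spec, clustering, e)),
      mixadd_unattainable = function(cond) NA_real_)
  }
  vapply(grid, ec_at, numeric(1))
}

draw_perturbed_drc <- function(d, rel_sd = 0.05) {
  entry <- drc_model_entry(d$model_id)
  for (try_i in 1:20) {
    p <- if (!is.null(d$vcov) && all(dim(d$vcov) == length(d$par))) {
      as.numeric(MASS::mvrnorm(1, mu = d$par, Sigma = d$vcov))
    } else {
      d$par * (1 + stats::rnorm(length(d$par), sd = rel_sd))
    }
    names(p) <- names(d$par)
    ok <- tryCatch({ entry$validate(p); all(is.finite(p)) },
                   error = function(e) FALSE)
    if (ok) {
      d2 <- d; d2$par <- p
      return(d2)
    }
  }
  d
}

bootstrap_model_ci <- function(spec, model, grid, clustering, n, rel_sd = 0.05) {
  draws <- matrix(NA_real_, nrow = n, ncol = length(grid))
  for (b in seq_len(n)) {
    comps <- lapply(spec$components, function(comp) {
      comp$drc <- draw_perturbed_drc(comp$drc, rel_sd)
      comp
    })
    spec_b <- spec
    spec_b$components <- comps
    draws[b, ] <- tryCatch(
      model_effective_concentrations(spec_b, model, grid, clustering),
      error = function(e) rep(NA_real_, length(grid)))
  }
  list(lo = apply(draws, 2, stats::quantile, probs = 0.025, na.rm = TRUE),
       hi = apply(draws, 2, stats::quantile, probs = 0.975, na.rm = TRUE))
}

#' Predict mixture toxicity with the selected additivity models
#'
#' Computes effective concentrations of the mixture on an effect grid
#' (default 10-90% in decadal steps, truncated to the predictable range
#' of the component curves) for each selected model, plus the
#' report-level lowest predicted ECx: the smallest effective
#' concentration at the reference effect (50% when attainable, else the
#' highest attainable grid effect) across the selected models.
#'
#' `SimpleCA` uses component summary endpoints only and yields a single
#' scalar endpoint, no curve.  `TSP` additionally needs component
#' structures (SMILES) unless a `clustering` is supplied.  A selected
#' model whose required inputs are missing is reported as a per-model
#' input error; the other models are still computed.
#'
#' Confidence intervals (when `bootstrap_n > 0`) come from a parametric
#' bootstrap of the component DRC parameters: draws from the fitted
#' parameter covariance when one is attached to the curve, otherwise
#' from a 5% relative Gaussian perturbation; reported as the
#' `[2.5th; 97.5th]` percentiles of the re-predicted grid.
#'
#' @param spec A [mixture_spec()].
#' @param models Subset of `c("CA", "IA", "GCA", "TSP", "SimpleCA")`.
#' @param grid Fractional effect levels requested (default
#'   `seq(0.1, 0.9, 0.1)`).
#' @param bootstrap_n Number of bootstrap draws for confidence intervals
#'   (0 disables them).
#' @param seed Integer seed for the bootstrap and, when TSP clustering is
#'   computed here, for k-means.
#' @param clustering Optional precomputed [cluster_mixture_moa()] result
#'   for TSP.
#' @param k Optional user-chosen number of clusters for TSP.
#' @return An object of class `mixture_prediction`.
#' @export
predict_mixture <- function(spec, models = c("CA", "IA"),
                            grid = seq(0.1, 0.9, by = 0.1),
                            bootstrap_n = 0, seed = 1L,
                            clustering = NULL, k = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  models <- normalize_model_selection(models)
  if (any(grid <= 0 | grid >= 1)) stop("grid effects must lie in (0, 1)",
                                       call. = FALSE)
  grid <- sort(unique(grid))

  results <- list()
  common_grid <- NULL
  drc_models_sel <- intersect(models, c("CA", "IA", "GCA", "TSP"))

  if (length(drc_models_sel) && spec_has_drcs(spec))
    common_grid <- predictable_effect_range(spec_drcs(spec), grid)$grid

  for (model in models) {
    res <- list(model = model, error = NULL, grid = NULL, ec = NULL,
                ci_lo = NULL, ci_hi = NULL, scalar = NULL)
    if (model == "SimpleCA") {
      missing_ep <- vapply(spec$components,
                           function(x) is.null(x$endpoint_value), logical(1))
      if (any(missing_ep)) {
        res$error <- paste0("SimpleCA requires a summary endpoint for every ",
                            "component; missing for: ",
                            paste(vapply(spec$components[missing_ep], `[[`,
                                         "", "name"), collapse = ", "))
      } else {
        res$scalar <- simple_ca_ec50(
          spec_fractions(spec),
          lapply(spec$components, `[[`, "endpoint_value"),
          output_unit = spec$output_unit,
          mws = vapply(spec$components, `[[`, numeric(1), "mw"))
      }
      results[[model]] <- res
      next
    }
    if (!spec_has_drcs(spec)) {
      res$error <- paste0(model, " requires a fitted DRC for every component")
      results[[model]] <- res
      next
    }
    clus <- clustering
    if (model == "TSP" && is.null(clus)) {
      clus <- tryCatch(cluster_mixture_moa(spec, k = k, seed = seed),
                       error = function(e) e)
      if (inherits(clus, "error")) {
        res$error <- paste0("TSP input error: ", conditionMessage(clus))
        results[[model]] <- res
        next
      }
    }
    res$grid <- common_grid
    res$ec <- model_effective_concentrations(spec, model, common_grid, clus)
    keep <- !is.na(res$ec)
    res$grid <- res$grid[keep]
    res$ec <- res$ec[keep]
    if (model == "TSP") res$clustering <- clus
    if (bootstrap_n > 0 && length(res$grid)) {
      old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      ci <- bootstrap_model_ci(spec, model, res$grid, clus, bootstrap_n)
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      res$ci_lo <- ci$lo
      res$ci_hi <- ci$hi
    }
    results[[model]] <- res
  }

  # Lowest predicted ECx at the reference effect
  ref <- if (!is.null(common_grid) && any(abs(common_grid - 0.5) < 1e-9))
    0.5 else if (!is.null(common_grid)) max(common_grid) else 0.5
  lowest <- NULL
  for (res in results) {
    val <- if (!is.null(res$scalar) && abs(ref - 0.5) < 1e-9)
      res$scalar$value
    else if (length(res$grid)) {
      i <- which(abs(res$grid - ref) < 1e-9)
      if (length(i)) res$ec[i] else NA_real_
    } else NA_real_
    if (!is.null(val) && length(val) && !is.na(val) &&
        (is.null(lowest) || val < lowest$value))
      lowest <- list(model = res$model, effect = ref, value = val,
                     unit = spec$output_unit)
  }

  structure(list(product_name = spec$product_name, unit = spec$output_unit,
                 endpoint_type = spec$endpoint_type, models = models,
                 results = results, lowest = lowest, spec = spec),
            class = "mixture_prediction")
}

#' Tabulate a mixture prediction
#'
#' @param x A [predict_mixture()] result.
#' @param percent Report effect levels in percent (default) rather than
#'   fractions.
#' @return A data.frame with one row per effect level and one column per
#'   model (plus CI columns when bootstrapped).
#' @export
prediction_table <- function(x, percent = TRUE) {
  stopifnot(inherits(x, "mixture_prediction"))
  grids <- lapply(x$results, `[[`, "grid")
  grid <- sort(unique(unlist(grids)))
  if (!length(grid)) return(data.frame())
  out <- data.frame(effect = if (percent) 100 * grid else grid)
  for (res in x$results) {
    if (is.null(res$grid) || !length(res$grid)) next
    i <- match(round(res$grid, 9), round(grid, 9))
    v <- rep(NA_real_, length(grid)); v[i] <- res$ec
    out[[res$model]] <- v
    if (!is.null(res$ci_lo)) {
      lo <- rep(NA_real_, length(grid)); lo[i] <- res$ci_lo
      hi <- rep(NA_real_, length(grid)); hi[i] <- res$ci_hi
      out[[paste0(res$model, "_lo")]] <- lo
      out[[paste0(res$model, "_hi")]] <- hi
    }
  }
  out
}

#' @export
print.mixture_prediction <- function(x, ...) {
  cat(sprintf("Mixture toxicity prediction for '%s' (%s, %s)\n",
              x$product_name, x$endpoint_type, x$unit))
  for (res in x$results) {
    if (!is.null(res$error)) {
      cat(sprintf("  %-8s ERROR: %s\n", res$model, res$error))
    } else if (!is.null(res$scalar)) {
      cat(sprintf("  %-8s mixture %s = %.4g %s (scalar; no DRC plotted)\n",
                  res$model, x$endpoint_type, res$scalar$value, x$unit))
    }
  }
  tab <- prediction_table(x)
  if (nrow(tab)) {
    cat(sprintf("  Effect grid (%% vs %s):\n", x$unit))
    fmt <- function(res, i) {
      v <- tab[[res$model]][i]
      if (is.na(v)) return("-")
      if (!is.null(res$ci_lo))
        sprintf("%.3f [%.3f; %.3f]", v, tab[[paste0(res$model, "_lo")]][i],
                tab[[paste0(res$model, "_hi")]][i])
      else sprintf("%.3f", v)
    }
    mods <- names(x$results)[vapply(x$results,
                                    function(r) length(r$grid) > 0, logical(1))]
    cat(sprintf("    %6s %s\n", "effect",
                paste(sprintf("%-24s", mods), collapse = "")))
    for (i in seq_len(nrow(tab)))
      cat(sprintf("    %5.0f%% %s\n", tab$effect[i],
                  paste(vapply(x$results[mods], fmt, "", i = i),
                        collapse = "  ")))
  }
  if (!is.null(x$lowest))
    cat(sprintf("  Lowest predicted EC%.0f: %.4g %s (%s)\n",
                100 * x$lowest$effect, x$lowest$value, x$unit,
                x$lowest$model))
  invisible(x)
}
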