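# Packaged case-study inputs and a seeded synthetic-mixture generator.

#' Load a packaged case-study mixture
#'
#' Three worked examples covering the three prediction situations:
#'
#' * `cs1` — a 23-component pesticide mixture with mixed modes of action
#'   (uM unit, per-component DRCs, structures included) for the CA / IA /
#'   TSP comparison.  The compositions and regression parameters are
#'   synthetic stand-ins (see the fixture file header); the structures
#'   are real pesticides.
#' * `cs2` — a coating product (adhesive primer) described only by its
#'   safety data sheet: worst-case composition percentages and summary
#'   Daphnia magna EC50s, no curves, so only Simple-CA applies.  These
#'   values are the published SDS figures.
#' * `cs3` — three perfluorinated carboxylic acids acting as partial
#'   agonists (Hill-three curves with sub-maximal asymptotes, synthetic
#'   stand-in parameters); the decadal effect grid truncates at 60%,
#'   exercising predictable-range determination and GCA.
#'
#' @param id One of `"cs1"`, `"cs2"`, `"cs3"`.
#' @return A [mixture_spec()].
#' @export
case_study_fixture <- function(id) {
  files <- c(cs1 = "cs1_pesticides_synthetic.csv",
             cs2 = "cs2_coating_sds.csv",
             cs3 = "cs3_pfca_synthetic.csv")
  units <- c(cs1 = "uM", cs2 = "mg/L", cs3 = "uM")
  names_ <- c(cs1 = "pesticide mixture (23 components)",
              cs2 = "coating product (adhesive primer)",
              cs3 = "perfluorinated carboxylic acid mixture")
  if (!is.character(id) || length(id) != 1L || !id %in% names(files))
    stop("unknown case study id: ", paste(id, collapse = ", "),
         " (use cs1, cs2 or cs3)", call. = FALSE)
  path <- system.file("extdata", files[[id]], package = "mixadd",
                      mustWork = TRUE)
  read_mixture_table(path, output_unit = units[[id]],
                     product_name = names_[[id]])
}

#' Generate a random synthetic mixture with known ground truth
#'
#' Draws a reproducible mixture of components with known DRCs, for
#' testing every engine path without external data.  EC50s are
#' log-uniform over `ec50_range`, slopes uniform over `slope_range`;
#' a `partial_fraction` share of components get a Hill-three curve with
#' an asymptote below 0.9 (partial agonists), the rest the full-agonist
#' models in `families`.
#'
#' @param n_components Number of components (>= 2).
#' @param families Full-agonist model families sampled from.
#' @param ec50_range Range of EC50s (in `unit`), log-uniform.
#' @param slope_range Range of slope parameters.
#' @param partial_fraction Fraction of components that are partial
#'   agonists (gamma drawn in `[0.5, 0.9)`).
#' @param fraction_scheme `"equal"` or `"dirichlet"` composition
#'   fractions.
#' @param unit Concentration unit of curves and predictions.
#' @param seed Integer seed; generation is reproducible.
#' @return List with `spec` (a [mixture_spec()]) and `truth` (a
#'   data.frame of the generating parameters).
#' @export
generate_synthetic_mixture <- function(n_components = 5,
                                       families = c("Logit", "Weibull"),
                                       ec50_range = c(0.05, 20),
                                       slope_range = c(1.2, 3.5),
                                       partial_fraction = 0,
                                       fraction_scheme = c("equal",
                                                           "dirichlet"),
                                       unit = "uM", seed = 1L) {
  stopifnot(n_components >= 2)
  fraction_scheme <- match.arg(fraction_scheme)
  with_seed(seed, {
    ec50 <- 10^stats::runif(n_components, log10(ec50_range[1]),
                            log10(ec50_range[2]))
    slope <- stats::runif(n_components, slope_range[1], slope_range[2])
    n_part <- round(partial_fraction * n_components)
    is_part <- seq_len(n_components) <= n_part
    model <- ifelse(is_part, "Hill_three",
                    sample(families, n_components, replace = TRUE))
    gamma <- ifelse(is_part, stats::runif(n_components, 0.5, 0.9 - 1e-9),
                    NA_real_)
    frac <- switch(fraction_scheme,
      equal = rep(1 / n_components, n_components),
      dirichlet = { g <- stats::rgamma(n_components, 2, 1); g / sum(g) })
    comps <- lapply(seq_len(n_components), function(i) {
      d <- switch(model[i],
        Logit = drc("Logit", alpha = -slope[i] * log10(ec50[i]),
                    beta = slope[i], conc_unit = unit),
        Weibull = drc("Weibull",
                      alpha = log(log(2)) - slope[i] * log10(ec50[i]),
                      beta = slope[i], conc_unit = unit),
        Hill_three = drc("Hill_three", alpha = ec50[i], beta = slope[i],
                         gamma = gamma[i], conc_unit = unit))
      mixture_component(name = sprintf("synthetic-%02d", i),
                        cas = sprintf("9999-%02d-%d", i, i %% 10),
                        fraction = frac[i], drc = d)
    })
    list(spec = mixture_spec(comps, product_name = "synthetic mixture",
                             output_unit = unit),
         truth = data.frame(name = sprintf("synthetic-%02d",
                                           seq_len(n_components)),
                            model = model, ec50 = ec50, slope = slope,
                            gamma = gamma, fraction = frac))
  })
}

#' Count possible mixtures of a chemical inventory
#'
#' Exact binomial-coefficient arithmetic: the number of distinct
#' mixtures of `size` components choosable from `n_chemicals` (a range
#' `c(lo, hi)` sums the counts over sizes `lo..hi`).  Twenty chemicals
#' give 190 binary combinations and over a million mixtures of three or
#' more.
#'
#' @param n_chemicals Inventory size.
#' @param size Mixture size, or a length-2 range.
#' @return The exact count.
#' @examples
#' enumerate_mixture_count(20, 2)        # 190
#' enumerate_mixture_count(20, c(3, 20)) # > 1e6
#' @export
enumerate_mixture_count <- function(n_chemicals, size) {
  stopifnot(n_chemicals >= 1, all(size >= 0))
  sizes <- if (length(size) == 2L) seq(size[1], size[2]) else size
  if (any(sizes > n_chemicals))
    stop("mixture size exceeds the number of chemicals", call. = FALSE)
  sum(choose(n_chemicals, sizes))
}
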