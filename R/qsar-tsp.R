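# QSAR-based two-stage prediction (TSP).
#
# Components are grouped into putative mode-of-action (MoA) clusters from
# structure alone: molecular descriptors -> PCA -> k-means.  Mixture
# toxicity is then predicted sequentially, CA within each cluster and IA
# across clusters.  Binary mixtures skip clustering: an ECFP6 Tanimoto
# similarity above 0.7 selects CA, otherwise IA.
#
# Structure handling (SMILES/SDF parsing, OpenBabel property and
# fingerprint calculation) is delegated to ChemmineR/ChemmineOB.

parse_smiles <- function(smiles, names = NULL) {
  if (is.null(names)) names <- paste0("mol", seq_along(smiles))
  if (any(!nzchar(smiles) | is.na(smiles)))
    stop("missing structure for component(s): ",
         paste(names[!nzchar(smiles) | is.na(smiles)], collapse = ", "),
         call. = FALSE)
  sdfs <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[i],
                                                             names[i]))),
      error = function(e) NULL)
    ok <- !is.null(sdf) && length(sdf) == 1 &&
      nrow(ChemmineR::atomblock(sdf[[1]])) > 0
    if (!ok)
      stop("unparseable structure for component ", names[i], ": ",
           smiles[i], call. = FALSE)
    sdfs[[i]] <- sdf
  }
  out <- Reduce(function(a, b) c(a, b), sdfs)
  ChemmineR::cid(out) <- make.unique(names)
  out
}

as_sdfset <- function(structures, names = NULL) {
  if (methods::is(structures, "SDFset")) return(structures)
  parse_smiles(as.character(structures), names)
}

#' Molecular descriptor matrix for a set of structures
#'
#' Builds a numeric descriptor matrix (components x descriptors) from an
#' open descriptor set: OpenBabel physicochemical properties (logP, TPSA,
#' molar refractivity, H-bond donor/acceptor counts, ...), element
#' counts, and hashed path- (FP2) and circular-environment (ECFP6)
#' fingerprint occupancy features as structural keys.
#' Constant and undefined descriptors are dropped and the remaining
#' columns are standardized (zero mean, unit variance) ready for PCA.
#'
#' @param structures SMILES character vector or a `ChemmineR::SDFset`
#'   (>= 3 structures for the clustering path).
#' @param names Optional component names used in error messages and row
#'   names.
#' @return Standardized numeric matrix; attribute `raw_dim` records the
#'   descriptor count before filtering.
#' @export
compute_descriptor_matrix <- function(structures, names = NULL) {
  sdf <- as_sdfset(structures, names)
  if (length(sdf) < 3L)
    stop("descriptor clustering needs at least 3 structures", call. = FALSE)
  props <- ChemmineR::propOB(sdf)
  num <- props[, vapply(props, is.numeric, logical(1)), drop = FALSE]
  counts <- ChemmineR::atomcountMA(sdf, addH = FALSE)
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")@fpma
  circ <- ChemmineR::fingerprintOB(sdf, "ECFP6")@fpma
  m <- cbind(as.matrix(num), counts, fp, circ)
  rownames(m) <- ChemmineR::cid(sdf)
  m <- m[, apply(m, 2, function(x) all(is.finite(x))), drop = FALSE]
  raw_dim <- ncol(m)
  sds <- apply(m, 2, stats::sd)
  m <- m[, sds > 0, drop = FALSE]
  if (!ncol(m))
    stop("degenerate structure set: all descriptors constant", call. = FALSE)
  m <- scale(m)
  attr(m, "raw_dim") <- raw_dim
  m
}

#' Reduce a descriptor matrix by PCA
#'
#' Retains the smallest number of principal components whose cumulative
#' explained variance reaches `threshold`.  Sign convention: each
#' component is flipped so that its largest-magnitude loading is
#' positive, making scores reproducible bit-for-bit.
#'
#' @param m Standardized descriptor matrix (>= 3 rows).
#' @param threshold Cumulative explained-variance target in (0, 1].
#' @return Score matrix (components x retained PCs) with attribute
#'   `explained_variance` (per retained PC) and `n_pcs`.
#' @export
pca_reduce <- function(m, threshold = 0.95) {
  if (nrow(m) < 3L) stop("PCA reduction needs at least 3 rows", call. = FALSE)
  if (all(apply(m, 2, function(x) max(x) - min(x) == 0)))
    stop("degenerate input: all rows identical", call. = FALSE)
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  varex <- pc$sdev^2 / sum(pc$sdev^2)
  n_pcs <- which(cumsum(varex) >= threshold - 1e-12)[1]
  if (is.na(n_pcs)) n_pcs <- length(varex)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(n_pcs)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  attr(scores, "explained_variance") <- varex[seq_len(n_pcs)]
  attr(scores, "n_pcs") <- n_pcs
  scores
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(expr)
}

#' k-means clustering of PCA scores into MoA groups
#'
#' @param scores PCA score matrix (n >= 3 rows).
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @param seed Clustering seed (fixed default for reproducibility).
#' @param n_init Number of random restarts.
#' @return Integer cluster labels, renumbered by first occurrence so the
#'   labelling is stable.
#' @export
cluster_moa <- function(scores, k, seed = 20220525L, n_init = 25L) {
  n <- nrow(scores)
  if (k < 2L || k > n - 1L)
    stop("k must satisfy 2 <= k <= n - 1 (n = ", n, ")", call. = FALSE)
  km <- with_seed(seed, stats::kmeans(scores, centers = k, nstart = n_init,
                                      iter.max = 100))
  labels <- km$cluster
  # stable relabeling: clusters numbered in order of first appearance
  first <- unique(labels)
  match(labels, first)
}

#' Choose the number of MoA clusters by silhouette
#'
#' Maximizes the mean silhouette width over `k in 2..min(n - 1, k_max)`,
#' breaking ties toward the smaller k.  A user-supplied `k` short-circuits
#' the search.
#'
#' @param scores PCA score matrix.
#' @param k Optional user override.
#' @param k_max Largest k tried.
#' @param seed Clustering seed passed to [cluster_moa()].
#' @return The chosen k with attribute `silhouette` (its mean silhouette
#'   width, NA for a user override).
#' @export
select_k <- function(scores, k = NULL, k_max = 8L, seed = 20220525L) {
  if (!is.null(k)) {
    k <- as.integer(k)
    return(structure(k, silhouette = NA_real_))
  }
  n <- nrow(scores)
  cand <- 2:min(n - 1L, k_max)
  d <- stats::dist(scores)
  sil <- vapply(cand, function(kk) {
    labels <- cluster_moa(scores, kk, seed = seed)
    if (length(unique(labels)) < 2L) return(-Inf)
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  }, numeric(1))
  best <- cand[which.max(sil)]   # which.max takes the first (smallest k) tie
  structure(best, silhouette = max(sil))
}

#' ECFP6 Tanimoto similarity of two structures
#'
#' Circular fingerprints of diameter 6 (radius 3), hashed to the
#' fingerprint backend's native 4096-bit width (kept unfolded: folding
#' inflates collision-induced similarity error); similarity is the
#' Tanimoto coefficient `|A & B| / |A | B|`.
#'
#' @param a,b SMILES strings (or single-molecule `SDFset`s).
#' @return Similarity in `[0, 1]`; symmetric; 1 iff the fingerprints are
#'   identical.
#' @export
ecfp6_tanimoto <- function(a, b) {
  sdf <- if (methods::is(a, "SDFset") && methods::is(b, "SDFset"))
    c(a, b)
  else
    as_sdfset(c(as.character(a), as.character(b)), c("a", "b"))
  fp <- ChemmineR::fingerprintOB(sdf, "ECFP6")@fpma > 0
  A <- fp[1, ]; B <- fp[2, ]
  un <- sum(A | B)
  if (un == 0) return(1)  # two empty fingerprints are identical
  sum(A & B) / un
}

#' Binary-mixture MoA rule
#'
#' For a two-component mixture: structural similarity strictly above 0.7
#' implies a shared mode of action, hence CA; otherwise IA.
#'
#' @param similarity Tanimoto similarity in `[0, 1]`.
#' @return `"CA"` or `"IA"`.
#' @export
binary_moa_rule <- function(similarity) {
  stopifnot(is.numeric(similarity), similarity >= 0, similarity <= 1)
  if (similarity > 0.7) "CA" else "IA"
}

#' Cluster mixture components into putative MoA groups
#'
#' The full structure-based grouping pipeline.  For three or more
#' components: descriptors ([compute_descriptor_matrix()]) -> PCA
#' ([pca_reduce()]) -> k selection ([select_k()]) -> k-means
#' ([cluster_moa()]).  For binary mixtures the ECFP6 Tanimoto rule
#' decides between one shared cluster (CA) and two singletons (IA).
#'
#' @param spec A [mixture_spec()] whose components carry structures
#'   (SMILES), or a character vector of SMILES.
#' @param k Optional user-chosen number of clusters.
#' @param seed Clustering seed.
#' @param pca_threshold Cumulative explained-variance target for PCA.
#' @return An object of class `moa_clustering` with fields
#'   `n_components_in`, `descriptor_dim`, `n_pcs`, `k`, `labels`, `seed`,
#'   and for binary mixtures `binary_similarity` and `binary_choice`.
#' @export
cluster_mixture_moa <- function(spec, k = NULL, seed = 20220525L,
                                pca_threshold = 0.95) {
  if (inherits(spec, "mixture_spec")) {
    smiles <- vapply(spec$components,
                     function(x) if (is.null(x$structure)) NA_character_
                     else as.character(x$structure), character(1))
    nms <- vapply(spec$components, `[[`, "", "name")
  } else {
    smiles <- as.character(spec)
    nms <- if (!is.null(names(spec))) names(spec)
           else paste0("component", seq_along(smiles))
  }
  if (any(is.na(smiles)))
    stop("structure (SMILES) missing for component(s): ",
         paste(nms[is.na(smiles)], collapse = ", "), call. = FALSE)
  n <- length(smiles)
  if (n < 2L) stop("MoA grouping needs at least 2 components", call. = FALSE)
  if (n == 2L) {
    sim <- ecfp6_tanimoto(smiles[1], smiles[2])
    choice <- binary_moa_rule(sim)
    labels <- if (choice == "CA") c(1L, 1L) else c(1L, 2L)
    out <- list(n_components_in = n, descriptor_dim = NA_integer_,
                n_pcs = NA_integer_, k = max(labels), labels = labels,
                seed = seed, binary_similarity = sim, binary_choice = choice,
                silhouette = NA_real_, explained_variance = NULL)
  } else {
    m <- compute_descriptor_matrix(smiles, names = nms)
    scores <- pca_reduce(m, threshold = pca_threshold)
    kk <- select_k(scores, k = k, seed = seed)
    labels <- cluster_moa(scores, as.integer(kk), seed = seed)
    out <- list(n_components_in = n, descriptor_dim = attr(m, "raw_dim"),
                n_pcs = attr(scores, "n_pcs"), k = as.integer(kk),
                labels = labels, seed = seed,
                binary_similarity = NULL, binary_choice = NULL,
                silhouette = attr(kk, "silhouette"),
                explained_variance = attr(scores, "explained_variance"))
  }
  structure(out, class = "moa_clustering")
}

#' @export
print.moa_clustering <- function(x, ...) {
  if (!is.null(x$binary_choice))
    cat(sprintf("<moa_clustering binary: Tanimoto %.3f -> %s>\n",
                x$binary_similarity, x$binary_choice))
  else
    cat(sprintf(
      "<moa_clustering: %d components, %d descriptors, %d PCs, k = %d (%s)>\n",
      x$n_components_in, x$descriptor_dim, x$n_pcs, x$k,
      paste(x$labels, collapse = " ")))
  invisible(x)
}

# ---- Two-stage prediction -------------------------------------------------

# CA effect of one cluster at cluster dose `conc` (already in the output
# unit; `scales` convert each member's curve unit); internal fractions q
# sum to 1 within the cluster.
cluster_ca_effect <- function(drcs, scales, q, conc) {
  if (length(drcs) == 1L) return(evaluate_drc(drcs[[1]], conc / scales[1]))
  maxe <- min(vapply(drcs, drc_max_effect, numeric(1)))
  mine <- max(vapply(drcs, drc_min_effect, numeric(1)))
  h <- function(E) {
    sum(mapply(function(d, si, qi)
      qi * conc / (inverse_drc(d, E) * si), drcs, scales, q)) - 1
  }
  lo <- mine + 1e-12
  hi <- maxe * (1 - 1e-12)
  if (h(hi) > 0) return(maxe)  # dose beyond the cluster's asymptote
  if (h(lo) < 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-13) break
  }
  (lo + hi) / 2
}

#' Two-stage mixture effect (CA within clusters, IA across clusters)
#'
#' Stage 1 treats each MoA cluster `g` (total fraction `P_g`, internal
#' fractions `q_i = p_i / P_g`) as a pseudo-chemical whose effect at dose
#' `c` is defined implicitly by CA.  Stage 2 combines the clusters by
#' independent action: `E(c) = 1 - prod_g(1 - f_g(P_g * c))`.
#'
#' @param spec A [mixture_spec()] with DRCs for every component.
#' @param clustering A [cluster_mixture_moa()] result (or any object with
#'   integer `labels` matching the components).
#' @param conc Strictly positive mixture concentration(s).
#' @return Fractional mixture effect(s).
#' @export
tsp_effect <- function(spec, clustering, conc) {
  labels <- clustering$labels
  if (length(labels) != length(spec$components))
    stop("clustering labels do not match the mixture components",
         call. = FALSE)
  p <- spec_fractions(spec)
  s <- spec_conv_scales(spec)
  drcs <- spec_drcs(spec)
  vapply(conc, function(cc) {
    if (cc <= 0) stop("concentration must be strictly positive", call. = FALSE)
    fac <- 1
    for (g in unique(labels)) {
      idx <- which(labels == g)
      Pg <- sum(p[idx])
      fg <- cluster_ca_effect(drcs[idx], s[idx], p[idx] / Pg, Pg * cc)
      fac <- fac * (1 - fg)
    }
    1 - fac
  }, numeric(1))
}

tsp_max_effect <- function(spec, clustering) {
  labels <- clustering$labels
  fac <- 1
  for (g in unique(labels)) {
    idx <- which(labels == g)
    mg <- min(vapply(spec$components[idx],
                     function(x) drc_max_effect(x$drc), numeric(1)))
    fac <- fac * (1 - mg)
  }
  1 - fac
}

#' Two-stage effective concentration
#'
#' Numeric inversion of [tsp_effect()] by bisection on
#' log10(concentration).
#'
#' @inheritParams tsp_effect
#' @param effect Fractional effect level(s).
#' @return Mixture concentration(s) in `spec$output_unit`.
#' @export
tsp_effective_concentration <- function(spec, clustering, effect) {
  supe <- tsp_max_effect(spec, clustering)
  vapply(effect, function(e) {
    if (e <= 0 || e >= supe)
      stop_unattainable(sprintf(
        "effect %.4g outside TSP's attainable range (0, %.4g)", e, supe))
    bisect_log_conc(function(cc) tsp_effect(spec, clustering, cc), e)
  }, numeric(1))
}
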