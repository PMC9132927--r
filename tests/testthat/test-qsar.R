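smi3 <- c(benzene = "c1ccccc1", toluene = "Cc1ccccc1",
          hexanoate = "CCCCCC(=O)O")

test_that("the descriptor matrix is finite, informative and deterministic", {
  m <- compute_descriptor_matrix(smi3, names = names(smi3))
  expect_equal(nrow(m), 3)
  expect_gte(ncol(m), 50)
  expect_true(all(is.finite(m)))
  # standardized columns
  expect_lt(max(abs(colMeans(m))), 1e-12)
  expect_equal(unname(apply(m, 2, sd)), rep(1, ncol(m)), tolerance = 1e-12)
  # duplicated molecule gives identical rows, and the result is reproducible
  m2 <- compute_descriptor_matrix(c(smi3, benzene2 = "c1ccccc1"),
                                  names = c(names(smi3), "benzene2"))
  expect_equal(unname(m2["benzene", ]), unname(m2["benzene2", ]))
  expect_identical(m, compute_descriptor_matrix(smi3, names = names(smi3)))
})

test_that("unparseable structures are reported by component name", {
  expect_error(compute_descriptor_matrix(c(a = "c1ccccc1", b = "xx$$yy",
                                           c = "CCO"),
                                         names = c("a", "b", "c")),
               "unparseable structure for component b")
  expect_error(cluster_mixture_moa(c(a = "CCO", b = NA_character_,
                                     c = "CC")),
               "missing")
})

test_that("PCA retention follows rank and the scores are sign-stable", {
  # rows on an exact line in descriptor space: one PC carries everything
  base <- rnorm(20)
  m <- rbind(base * 1, base * 2, base * 3.5, base * -1)
  m <- scale(m)
  s <- pca_reduce(m)
  expect_equal(attr(s, "n_pcs"), 1)
  # n - 1 bound for a general cloud
  set.seed(1)
  cloud <- scale(matrix(rnorm(3 * 10), nrow = 3))
  expect_lte(attr(pca_reduce(cloud), "n_pcs"), 2)
  # identical rows are degenerate
  same <- matrix(rep(c(1, 2, 3, 4), each = 3), nrow = 3)
  expect_error(pca_reduce(scale(same, scale = FALSE)), "identical")
  # deterministic, including sign
  expect_identical(pca_reduce(cloud), pca_reduce(cloud))
})

planted_blobs <- function(k, per = 6, sep = 12, seed = 4L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(rnorm(per, mean = sep * i, sd = 0.4),
          rnorm(per, mean = -sep * i, sd = 0.4))))
}

test_that("k-means recovers planted partitions under a fixed seed", {
  s2 <- planted_blobs(2)
  lab <- cluster_moa(s2, 2)
  expect_equal(lab, rep(1:2, each = 6))
  expect_identical(lab, cluster_moa(s2, 2))
  expect_error(cluster_moa(s2, nrow(s2)), "k must satisfy")
  expect_error(cluster_moa(s2, 1), "k must satisfy")
  # labels are invariant to row order up to relabeling
  ord <- c(7:12, 1:6)
  expect_equal(cluster_moa(s2[ord, ], 2), rep(1:2, each = 6))
})

test_that("silhouette selection finds the planted k and honors overrides", {
  expect_equal(as.integer(select_k(planted_blobs(2))), 2)
  expect_equal(as.integer(select_k(planted_blobs(3))), 3)
  expect_equal(as.integer(select_k(planted_blobs(3), k = 4)), 4)
})

test_that("ECFP6 Tanimoto is symmetric, bounded and cross-checked", {
  expect_equal(ecfp6_tanimoto("c1ccccc1", "c1ccccc1"), 1)
  s_ab <- ecfp6_tanimoto("c1ccccc1", "Cc1ccccc1")
  expect_equal(s_ab, ecfp6_tanimoto("Cc1ccccc1", "c1ccccc1"))
  expect_true(s_ab > 0 && s_ab < 1)
  # molecules sharing no atom environment
  expect_equal(ecfp6_tanimoto("CC", "OO"), 0)
  # frozen independent-implementation value for benzene vs toluene
  # (Morgan radius-3 fingerprints, RDKit 2024.09): 0.2142857
  expect_lt(abs(s_ab - 0.2142857), 0.05)
  expect_error(ecfp6_tanimoto("c1ccccc1", "not-a-smiles"), "unparseable")
})

test_that("the binary MoA rule is strict at 0.7", {
  expect_equal(binary_moa_rule(0.71), "CA")
  expect_equal(binary_moa_rule(0.70), "IA")
  expect_equal(binary_moa_rule(0), "IA")
  expect_equal(binary_moa_rule(1), "CA")
})

test_that("the clustering pipeline fills the MoA report fields", {
  cl <- cluster_mixture_moa(c(a = "c1ccccc1", b = "Cc1ccccc1",
                              c = "CCCCCC(=O)O", d = "CCCCCCC(=O)O"))
  expect_s3_class(cl, "moa_clustering")
  expect_equal(cl$n_components_in, 4)
  expect_length(cl$labels, 4)
  expect_true(cl$k >= 2 && cl$k <= 3)
  expect_null(cl$binary_similarity)
  # binary path
  cl2 <- cluster_mixture_moa(c(a = "c1ccccc1", b = "Cc1ccccc1"))
  expect_equal(cl2$n_components_in, 2)
  expect_equal(cl2$binary_choice, "IA")   # similarity ~0.21 <= 0.7
  expect_equal(cl2$labels, c(1L, 2L))
  expect_true(cl2$binary_similarity >= 0 && cl2$binary_similarity <= 1)
})

test_that("degenerate clusterings reduce TSP to CA and IA", {
  gen <- generate_synthetic_mixture(5, fraction_scheme = "dirichlet",
                                    seed = 21L)
  sp <- gen$spec
  grid <- seq(0.1, 0.9, by = 0.1)
  one <- structure(list(labels = rep(1L, 5)), class = "moa_clustering")
  sing <- structure(list(labels = 1:5), class = "moa_clustering")
  expect_rel_equal(tsp_effective_concentration(sp, one, grid),
                   ca_effective_concentration(sp, grid), 1e-6)
  expect_rel_equal(tsp_effective_concentration(sp, sing, grid),
                   ia_effective_concentration(sp, grid), 1e-6)
})

test_that("clusters of duplicated chemicals reduce to IA at doubled fractions", {
  da <- make_logit(1, 2); db <- make_weibull(6, 1.6)
  sp4 <- make_mixture(list(da, da, db, db), rep(0.25, 4))
  cl <- structure(list(labels = c(1L, 1L, 2L, 2L)), class = "moa_clustering")
  sp2 <- make_mixture(list(da, db), c(0.5, 0.5))
  for (cc in c(0.5, 2, 10))
    expect_equal(tsp_effect(sp4, cl, cc), ia_effect(sp2, cc),
                 tolerance = 1e-9)
})
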