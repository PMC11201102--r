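test_that("adjacency is the elementwise power with unit diagonal", {
  M <- random_unit_corr(6, 61)
  expect_equal(adjacency(M, 1), M)
  expect_equal(adjacency(vec_to_cormat(0.5, c("a", "b")), 3)["a", "b"], 0.125)
  # raising the power never increases an off-diagonal entry
  a2 <- adjacency(M, 2); a5 <- adjacency(M, 5)
  off <- !diag(6)
  expect_true(all(a5[off] <= a2[off] + 1e-15))
  expect_error(adjacency(M, 0), "power")
})

test_that("mean connectivity matches the brute-force double loop", {
  # uniform network: every gene connects at a to G-1 others
  G <- 7; a <- 0.4
  U <- matrix(a, G, G); diag(U) <- 1
  expect_equal(mean_connectivity(U), (G - 1) * a)
  expect_equal(mean_connectivity(diag(G)), 0)
  A <- random_unit_corr(6, 62)
  expect_equal(mean_connectivity(A), mean_connectivity_reference(A))
  # k(m) is nonincreasing in m for any unit-interval correlation matrix
  ks <- vapply(1:10, function(m) mean_connectivity(adjacency(A, m)),
               numeric(1))
  expect_true(all(diff(ks) <= 1e-12))
})

test_that("scale-free fit equals an independent least-squares fit and flags degenerate input", {
  A <- random_unit_corr(20, 63)
  got <- scale_free_fit(A, n_bins = 5)
  # independently coded binning + regression
  k <- rowSums(A) - 1
  breaks <- seq(min(k), max(k), length.out = 6)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- as.integer(table(bin))
  km <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(km) & km > 0
  fit <- lm(log10(freq[keep]) ~ log10(km[keep]))
  expect_equal(got, summary(fit)$adj.r.squared, tolerance = 1e-10)
  # constant connectivity: a single nonempty bin, not assessable
  U <- matrix(0.3, 20, 20); diag(U) <- 1
  expect_true(is.na(scale_free_fit(U)))
})

test_that("power selection: inflection picks a small power, traditional a large one", {
  # uniform correlation: k(m) is geometric, the change rate is constant,
  # so the inflection rule lands on the knee at the start of the grid
  U <- matrix(0.5, 30, 30); diag(U) <- 1
  dimnames(U) <- list(sprintf("g%d", 1:30), sprintf("g%d", 1:30))
  m_unif <- suppressWarnings(select_power(U, rule = "inflection"))
  expect_lte(as.integer(m_unif), 3)
  # traditional rule on the uniform matrix cannot assess scale-freeness
  expect_warning(select_power(U, rule = "traditional"), "falling back")
  # pooled Case-1 matrix (seeded): the proposed rule selects a strictly
  # smaller power than the traditional criterion
  cfg <- sim_config()
  studies <- simulate_meta(cfg, 42)
  pooled <- combine_diagonal(lapply(studies, function(ls)
    correlation_matrix(ls$study, "msoc")))
  corr <- finalize_for_clustering(pooled)
  m_inf <- select_power(corr, rule = "inflection")
  m_tra <- suppressWarnings(select_power(corr, rule = "traditional"))
  expect_lt(as.integer(m_inf), as.integer(m_tra))
  # the profile rides along and the grid must be long enough
  expect_s3_class(attr(m_inf, "profile"), "data.frame")
  expect_error(select_power(corr, grid = 1:4, rule = "inflection"),
               "5 grid points")
  expect_error(select_power(corr, grid = 1:2), "3 points")
})

test_that("TOM matches its closed forms and the triple-loop reference", {
  # G = 2, single edge a: empty neighbor sum, TOM = a
  for (a in c(0.2, 0.7)) {
    A <- matrix(c(1, a, a, 1), 2)
    expect_equal(tom_similarity(A)[1, 2], a)
  }
  # unweighted triangle: TOM = 1
  Tri <- matrix(1, 3, 3)
  expect_true(all(tom_similarity(Tri) == 1))
  # random 5 x 5 adjacency vs brute force
  set.seed(64)
  for (rep in 1:4) {
    A <- random_unit_corr(5, 640 + rep)
    expect_equal(tom_similarity(A), tom_reference(A), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # range and symmetry for arbitrary unit-interval adjacencies
  for (rep in 1:5) {
    A <- random_unit_corr(12, 650 + rep)
    tm <- tom_similarity(A)
    expect_true(all(tm >= 0 & tm <= 1))
    expect_equal(tm, t(tm))
    expect_equal(unname(diag(tm)), rep(1, 12))
  }
})

test_that("clustering recovers separable blocks and prunes small clusters", {
  # two perfect blocks: within-similarity 1, between 0
  B <- matrix(0, 6, 6)
  B[1:3, 1:3] <- 1; B[4:6, 4:6] <- 1
  dimnames(B) <- list(sprintf("g%d", 1:6), sprintf("g%d", 1:6))
  lab <- tom_cluster(B, min_cluster_size = 2)
  expect_equal(max(lab), 2)
  expect_equal(adjusted_rand_index(lab, c(1, 1, 1, 2, 2, 2)), 1)
  # labels renumbered by decreasing size
  B2 <- matrix(0, 7, 7); B2[1:3, 1:3] <- 1; B2[4:7, 4:7] <- 1
  dimnames(B2) <- list(sprintf("g%d", 1:7), sprintf("g%d", 1:7))
  lab2 <- tom_cluster(B2, min_cluster_size = 2)
  expect_equal(unname(lab2[4]), 1)  # the size-4 block gets label 1
  # nothing survives when the minimum size exceeds G
  expect_true(all(tom_cluster(B, min_cluster_size = 10) == 0))
  # dissolved genes are reassigned to the nearest surviving cluster
  C3 <- matrix(0, 7, 7)
  C3[1:3, 1:3] <- 1; C3[4:6, 4:6] <- 1
  C3[7, 1:3] <- C3[1:3, 7] <- 0.6   # lone gene closest to block 1
  diag(C3) <- 1
  dimnames(C3) <- list(sprintf("g%d", 1:7), sprintf("g%d", 1:7))
  lab3 <- tom_cluster(C3, min_cluster_size = 3)
  expect_equal(unname(lab3[7]), unname(lab3[1]))
})

test_that("clustering is deterministic and invariant to gene order", {
  cfg <- sim_config(G = 20, n_clusters = 4, V = 2, K = 2, Sk = 80,
                    tau = c(0.6, 0.5, 0.4, 0.05, 0.05), p = 0)
  ls <- simulate_study(cfg, 5)
  corr <- finalize_for_clustering(correlation_matrix(ls$study, "msoc"))
  tm <- tom_similarity(adjacency(corr, 3))
  lab <- tom_cluster(tm, 3)
  expect_identical(lab, tom_cluster(tm, 3))
  set.seed(66)
  perm <- sample(20)
  lab_p <- tom_cluster(tm[perm, perm], 3)
  # same partition up to label renaming
  expect_equal(adjusted_rand_index(lab[perm], lab_p), 1)
})
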