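test_that("correlation variance has the stated closed form and clipping floor", {
  expect_equal(correlation_variance(0, 100), 0.01)
  expect_equal(correlation_variance(0.6, 50), (1 - 0.36)^2 / 50)
  expect_equal(correlation_variance(0.6, 50), 0.008192)
  # at r = 1 the clip keeps the variance at its positive floor
  floor_var <- (1 - (1 - 1e-6)^2)^2 / 50
  expect_equal(correlation_variance(1, 50), floor_var)
  expect_gt(correlation_variance(1, 50), 0)
  expect_equal(correlation_variance(-1, 50), floor_var)
})

test_that("pair covariance reduces to the variance when the pairs coincide", {
  set.seed(31)
  for (rep in 1:5) {
    R <- cov2cor(crossprod(matrix(rnorm(64), 8)))
    for (idx in list(c(1, 2), c(3, 7), c(2, 8))) {
      a <- idx[1]; b <- idx[2]
      expect_equal(correlation_covariance(R, a, b, a, b, 40),
                   (1 - R[a, b]^2)^2 / 40, tolerance = 1e-12)
    }
  }
  # all off-diagonal correlations zero, four distinct genes: every term vanishes
  expect_equal(correlation_covariance(diag(5), 1, 2, 3, 4, 25), 0)
})

test_that("pair covariance matches a Monte-Carlo oracle within 3 MC standard errors", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.5; R[3, 4] <- R[4, 3] <- 0.3
  R[1, 3] <- R[3, 1] <- 0.2; R[1, 4] <- R[4, 1] <- 0.1
  R[2, 3] <- R[3, 2] <- 0.15; R[2, 4] <- R[4, 2] <- 0.25
  ch <- chol(R)
  Sk <- 30; n <- 200000
  set.seed(99)
  rab <- numeric(n); rcd <- numeric(n); done <- 0
  corcols <- function(x, y) {
    mx <- colMeans(x); my <- colMeans(y)
    (colSums(x * y) - Sk * mx * my) /
      sqrt((colSums(x * x) - Sk * mx^2) * (colSums(y * y) - Sk * my^2))
  }
  while (done < n) {
    m <- min(20000, n - done)
    Z <- matrix(rnorm(m * Sk * 4), m * Sk, 4) %*% ch
    rab[done + 1:m] <- corcols(matrix(Z[, 1], Sk), matrix(Z[, 2], Sk))
    rcd[done + 1:m] <- corcols(matrix(Z[, 3], Sk), matrix(Z[, 4], Sk))
    done <- done + m
  }
  emp <- cov(rab, rcd)
  se <- sd((rab - mean(rab)) * (rcd - mean(rcd))) / sqrt(n)
  theo <- correlation_covariance(R, 1, 2, 3, 4, Sk)
  expect_lt(abs(emp - theo), 3 * se)
})

test_that("diagonal pooling is the inverse-variance weighted mean", {
  M1 <- random_unit_corr(5, 41); M2 <- random_unit_corr(5, 42)
  r1 <- as_corr_vector(M1, Sk = 50); r2 <- as_corr_vector(M2, Sk = 80)
  # K = 1 is the identity
  expect_equal(combine_diagonal(list(r1))$values, r1$values)
  # constant across studies pools to the constant
  expect_equal(combine_diagonal(list(r1, r1))$values, r1$values)
  # hand-computed two-study value: r = 0.2 at S = 50 and 0.4 at S = 100
  A <- vec_to_cormat(0.2, c("a", "b")); B <- vec_to_cormat(0.4, c("a", "b"))
  pooled <- combine_diagonal(list(as_corr_vector(A, 50), as_corr_vector(B, 100)))
  expect_equal(pooled$values, 0.3446328, tolerance = 1e-6)
  # convexity: pooled entries lie within the per-study range
  p2 <- combine_diagonal(list(r1, r2))
  expect_true(all(p2$values >= pmin(r1$values, r2$values) - 1e-12))
  expect_true(all(p2$values <= pmax(r1$values, r2$values) + 1e-12))
  # pooled precision never decreases when a study is added
  expect_true(all(p2$weight_sum >= combine_diagonal(list(r1))$weight_sum))
  # mismatched gene sets refuse to pool
  r3 <- as_corr_vector(random_unit_corr(4, 43), 50)
  expect_error(combine_diagonal(list(r1, r3)), "same gene ids")
})

test_that("full GLS pooling matches a dense brute-force oracle", {
  mk <- function(seed, Sk) {
    set.seed(seed)
    M <- cov2cor(crossprod(matrix(rnorm(60), 12, 5)) / 12)
    dimnames(M) <- list(sprintf("g%d", 1:5), sprintf("g%d", 1:5))
    as_corr_vector(M, Sk)
  }
  rs <- list(mk(1, 60), mk(2, 90))
  full <- combine_full(rs)
  expect_equal(full$values, gls_reference(rs), tolerance = 1e-8)
  # K = 1 GLS is the identity map
  expect_equal(combine_full(rs[1])$values, rs[[1]]$values, tolerance = 1e-8)
  # zeroing the off-diagonal covariances recovers the diagonal variant:
  # brute-force GLS with diag(Tk) equals combine_diagonal up to clipping
  diag_ref <- local({
    p <- length(rs[[1]]$values)
    W <- numeric(p); bsum <- numeric(p)
    for (r in rs) {
      d <- diag(mmagc:::.build_tk(vec_to_cormat(r$values), r$sample_size))
      W <- W + 1 / d
      bsum <- bsum + r$values / d
    }
    bsum / W
  })
  expect_equal(combine_diagonal(rs)$values, diag_ref, tolerance = 1e-10)
  # the memory guard refuses large G unless forced
  big <- as_corr_vector(random_unit_corr(25, 77), 50)
  expect_error(combine_full(list(big), max_genes = 20), "max_genes")
})

test_that("finalize_for_clustering applies |.| to signed measures and clips", {
  M <- vec_to_cormat(c(-0.7, 0.5, 0.2), c("a", "b", "c"))
  meta <- structure(list(values = M[lower.tri(M)], method = "msoc",
                         variant = "diagonal", gene_ids = c("a", "b", "c")),
                    class = "meta_correlation")
  fin <- finalize_for_clustering(meta)
  expect_equal(fin["a", "b"], 0.7)
  expect_true(all(fin >= 0 & fin <= 1))
  expect_equal(unname(diag(fin)), rep(1, 3))
  # CC entries are only clipped, never folded
  meta$method <- "cc"
  meta$values <- c(1.02, 0.5, 0.2)
  fin2 <- finalize_for_clustering(meta)
  expect_equal(fin2["a", "b"], 1)
  expect_equal(fin2["a", "c"], 0.5)
})
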