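#' Asymptotic variance of a sample correlation
#'
#' The large-sample variance of a Pearson correlation estimate,
#' \eqn{(1 - r^2)^2 / S_k}. This is also the asymptotic variance of the
#' first canonical correlation, which is a Pearson correlation of the
#' canonical variates, so the same expression serves CC, MOC and MSOC.
#' `r` is clipped to |r| <= 1 - 1e-6 first so that inverse-variance
#' weights stay finite at r = +/-1.
#'
#' @param r correlation estimate(s)
#' @param Sk study sample size (>= 2)
#' @return variance estimate(s), same length as `r`
#' @export
correlation_variance <- function(r, Sk) {
  stopifnot(Sk >= 2)
  r <- pmax(pmin(r, 1 - 1e-6), -(1 - 1e-6))
  (1 - r^2)^2 / Sk
}

#' Olkin-Siotani covariance of two sample correlations
#'
#' Plug-in estimate of Cov(r_ab, r_cd) for correlations sharing the same
#' sample of size Sk:
#' \deqn{\frac{1}{S_k}\Big[\tfrac12 r_{ab} r_{cd}
#'   (r_{ac}^2 + r_{ad}^2 + r_{bc}^2 + r_{bd}^2)
#'   + r_{ac} r_{bd} + r_{ad} r_{bc}
#'   - r_{ab}(r_{ac} r_{ad} + r_{bc} r_{bd})
#'   - r_{cd}(r_{ac} r_{bc} + r_{ad} r_{bd})\Big]}
#' With (c,d) = (a,b) this collapses to \eqn{(1-r_{ab}^2)^2/S_k}, i.e.
#' [correlation_variance].
#'
#' @param r symmetric correlation matrix with unit diagonal
#' @param a,b,c,d gene indices (a != b, c != d)
#' @param Sk sample size
#' @return scalar covariance estimate
#' @export
correlation_covariance <- function(r, a, b, c, d, Sk) {
  stopifnot(is.matrix(r), a != b, c != d)
  rab <- r[a, b]; rcd <- r[c, d]
  rac <- r[a, c]; rad <- r[a, d]; rbc <- r[b, c]; rbd <- r[b, d]
  (0.5 * rab * rcd * (rac^2 + rad^2 + rbc^2 + rbd^2) +
     rac * rbd + rad * rbc -
     rab * (rac * rad + rbc * rbd) -
     rcd * (rac * rbc + rad * rbd)) / Sk
}

# Full p* x p* within-study covariance matrix of the correlation vector,
# assembled from the pairwise formula above (vectorized over all pair
# pairs).  Entries of the study correlation matrix are clipped to
# |r| <= 1 - 1e-6 for the same reason as in correlation_variance().
.build_tk <- function(R, Sk) {
  R <- pmax(pmin(R, 1 - 1e-6), -(1 - 1e-6))
  diag(R) <- 1
  G <- nrow(R)
  P <- pair_index(G)
  a <- P[, 1]; b <- P[, 2]
  rab <- R[P]
  Rac <- R[a, a]; Rad <- R[a, b]; Rbc <- R[b, a]; Rbd <- R[b, b]
  Tk <- 0.5 * outer(rab, rab) * (Rac^2 + Rad^2 + Rbc^2 + Rbd^2) +
    Rac * Rbd + Rad * Rbc -
    rab * (Rac * Rad + Rbc * Rbd) -
    sweep(Rac * Rbc + Rad * Rbd, 2, rab, `*`)
  Tk / Sk
}

# Cholesky with escalating ridge for matrices that should be PD but may be
# numerically indefinite (the covariance above is an asymptotic plug-in
# estimate, not guaranteed PD at finite samples).
.chol_pd <- function(M, start = 1e-8, cap = 1e2) {
  n <- nrow(M)
  scale <- mean(diag(M))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  lam <- 0
  repeat {
    ch <- tryCatch(chol(M + diag(lam, n)), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    lam <- if (lam == 0) start * scale else lam * 10
    if (lam > cap * scale)
      stop("covariance matrix could not be repaired to positive definite")
  }
}

.check_corr_vectors <- function(rs) {
  stopifnot(is.list(rs), length(rs) >= 1)
  if (!all(vapply(rs, inherits, logical(1), "corr_vector")))
    stop("'rs' must be a list of corr_vector objects")
  ref <- rs[[1]]
  for (r in rs[-1]) {
    if (!identical(r$gene_ids, ref$gene_ids))
      stop("all studies must share the same gene ids in the same order")
    if (!identical(r$method, ref$method))
      stop("all studies must use the same correlation method")
  }
  ref
}

#' Fixed-effects pooling of study correlation vectors (diagonal variant)
#'
#' Pools K per-study correlation vectors under the fixed-effects model
#' r_k = rho + e_k, taking each study's error covariance T_k as diagonal:
#' the pooled estimate is the entrywise inverse-variance weighted mean
#' with weights 1/Var(r_ab,k) from [correlation_variance]. This is the
#' computationally light variant; see [combine_full] for the full
#' generalized-least-squares estimator.
#'
#' @param rs list of K `corr_vector` objects sharing genes and method
#' @return object of class `meta_correlation`: `values` (pooled vector,
#'   signed), `weight_sum` (per-entry pooled precision), `method`,
#'   `variant`, `gene_ids`, `sample_sizes`
#' @export
combine_diagonal <- function(rs) {
  ref <- .check_corr_vectors(rs)
  vals <- vapply(rs, `[[`, numeric(length(ref$values)), "values")
  vals <- matrix(vals, ncol = length(rs))
  Sk <- vapply(rs, `[[`, numeric(1), "sample_size")
  w <- vapply(seq_along(rs),
              function(k) 1 / correlation_variance(vals[, k], Sk[k]),
              numeric(nrow(vals)))
  w <- matrix(w, ncol = length(rs))
  structure(
    list(values = rowSums(w * vals) / rowSums(w), weight_sum = rowSums(w),
         method = ref$method, variant = "diagonal", gene_ids = ref$gene_ids,
         sample_sizes = Sk),
    class = "meta_correlation")
}

#' Fixed-effects pooling of study correlation vectors (full GLS variant)
#'
#' The generalized least squares estimate
#' \deqn{\hat\rho = \Big(\sum_k T_k^{-1}\Big)^{-1} \sum_k T_k^{-1} r_k,}
#' with each T_k the full p* x p* Olkin-Siotani covariance of the study's
#' correlation vector. T_k is repaired to positive definite with an
#' escalating diagonal ridge when needed and all solves go through
#' Cholesky factorizations (no explicit inversion of the summed
#' precision). Memory is O(p*^2) per study, so the number of genes is
#' guarded by `max_genes` (override with `force = TRUE`).
#'
#' @inheritParams combine_diagonal
#' @param max_genes refuse larger problems unless `force`d (default 200)
#' @param force bypass the `max_genes` guard
#' @return a `meta_correlation` with `variant = "full"`
#' @export
combine_full <- function(rs, max_genes = 200, force = FALSE) {
  ref <- .check_corr_vectors(rs)
  G <- length(ref$gene_ids)
  if (G > max_genes && !force)
    stop("G = ", G, " exceeds max_genes = ", max_genes,
         "; the full variant needs O(G^4) memory (use force = TRUE to override)")
  p <- length(ref$values)
  W <- matrix(0, p, p)
  bsum <- numeric(p)
  Sk <- vapply(rs, `[[`, numeric(1), "sample_size")
  for (k in seq_along(rs)) {
    Tk <- .build_tk(vec_to_cormat(rs[[k]]$values), Sk[k])
    ch <- .chol_pd(Tk)
    Tinv <- chol2inv(ch)
    W <- W + Tinv
    bsum <- bsum + Tinv %*% rs[[k]]$values
  }
  chW <- .chol_pd(W)
  rho <- backsolve(chW, backsolve(chW, bsum, transpose = TRUE))
  structure(
    list(values = as.vector(rho), weight_sum = diag(W), method = ref$method,
         variant = "full", gene_ids = ref$gene_ids, sample_sizes = Sk),
    class = "meta_correlation")
}

#' @export
print.meta_correlation <- function(x, ...) {
  cat("Pooled gene-pair correlations (", toupper(x$method), ", ",
      x$variant, " T_k): G = ", length(x$gene_ids), ", K = ",
      length(x$sample_sizes), " studies, total n = ", sum(x$sample_sizes),
      "\n", sep = "")
  invisible(x)
}

#' Prepare a (pooled or single-study) correlation for clustering
#'
#' Because CC is nonnegative while MOC/MSOC are signed, the clustering
#' input takes the absolute value of MOC/MSOC entries; all entries are
#' then clipped to \[0, 1\] (full GLS pooling can overshoot slightly) and
#' reshaped to a symmetric G x G matrix with unit diagonal.
#'
#' @param meta a `meta_correlation` or a single-study `corr_vector`
#' @return symmetric G x G numeric matrix with entries in \[0, 1\]
#' @export
finalize_for_clustering <- function(meta) {
  if (!inherits(meta, c("meta_correlation", "corr_vector")))
    stop("'meta' must be a meta_correlation or corr_vector")
  v <- meta$values
  if (meta$method %in% c("moc", "msoc")) v <- abs(v)
  v <- pmax(pmin(v, 1), 0)
  vec_to_cormat(v, meta$gene_ids)
}
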