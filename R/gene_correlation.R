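#' Canonical correlation between two genes' multi-omics profiles
#'
#' The first canonical correlation between the column spaces of the two
#' Sk x V gene-specific matrices: the highest Pearson correlation
#' attainable between a linear combination of gene 1's omics and a linear
#' combination of gene 2's omics. Columns are centered internally. The
#' within-gene covariance matrices are given a small ridge
#' (`ridge * trace/V` on the diagonal) before whitening so that collinear
#' omics profiles do not break the computation; on well-conditioned inputs
#' the result is unaffected beyond ~1e-6.
#'
#' @param m1,m2 numeric Sk x V matrices (samples x omics), same Sk
#' @param ridge relative ridge added to each within-gene covariance
#' @return scalar in \[0, 1\]
#' @export
canonical_correlation <- function(m1, m2, ridge = 1e-8) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  Sk <- nrow(m1)
  if (nrow(m2) != Sk) stop("m1 and m2 must have the same number of samples")
  if (Sk < max(ncol(m1), ncol(m2)) + 2)
    stop("sample size too small for canonical correlation (need Sk >= V + 2)")
  q1 <- .whiten(m1, ridge)
  q2 <- .whiten(m2, ridge)
  d <- svd(crossprod(q1, q2), nu = 0, nv = 0)$d[1] / (Sk - 1)
  min(max(d, 0), 1)
}

# center and whiten an Sk x V matrix so that crossprod(q1, q2)/(Sk-1) is the
# whitened cross-covariance whose singular values are canonical correlations
.whiten <- function(m, ridge) {
  x <- scale(m, center = TRUE, scale = FALSE)
  S <- crossprod(x) / (nrow(x) - 1)
  eps <- ridge * sum(diag(S)) / ncol(S)
  if (eps <= 0) eps <- ridge
  R <- chol(S + diag(eps, ncol(S)))
  t(backsolve(R, t(x), transpose = TRUE))
}

#' Maximum omics correlation (MOC) between two genes
#'
#' Among all V1 x V2 Pearson correlations between a column of `m1` and a
#' column of `m2`, returns the one of largest magnitude, keeping its sign.
#' Correlations involving a zero-variance column are treated as 0 (with a
#' warning).
#'
#' @inheritParams canonical_correlation
#' @return signed scalar in \[-1, 1\]
#' @export
max_omics_correlation <- function(m1, m2) {
  cors <- .safe_cor(as.matrix(m1), as.matrix(m2))
  cors[which.max(abs(cors))]
}

#' Maximum same-omics correlation (MSOC) between two genes
#'
#' As [max_omics_correlation] but restricted to matching omics types:
#' column j of `m1` against column j of `m2` (RNA with RNA, protein with
#' protein, ...). Both genes must carry the same ordered omics types.
#'
#' @inheritParams canonical_correlation
#' @return signed scalar in \[-1, 1\]
#' @export
max_same_omics_correlation <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (ncol(m1) != ncol(m2))
    stop("MSOC requires the same ordered omics types for both genes")
  cors <- diag(.safe_cor(m1, m2))
  cors[which.max(abs(cors))]
}

.safe_cor <- function(x, y) {
  cors <- suppressWarnings(stats::cor(x, y))
  if (anyNA(cors)) {
    warning("zero-variance omics column: its correlations are treated as 0")
    cors[is.na(cors)] <- 0
  }
  cors
}

#' Per-study gene-to-gene correlation vector
#'
#' Computes the chosen correlation measure for all \eqn{p^* = G(G-1)/2}
#' gene pairs of one study and returns them as a `corr_vector` in canonical
#' pair order (see [pair_index]). CC values lie in \[0,1\]; MOC/MSOC values
#' are signed — the absolute value is only applied when the pooled matrix
#' is finalized for clustering (see [finalize_for_clustering]).
#'
#' @param study an [omics_study]
#' @param method one of `"msoc"`, `"moc"`, `"cc"`
#' @param ridge ridge passed to [canonical_correlation] (CC only)
#' @return object of class `corr_vector`: list with `values` (length p*),
#'   `method`, `sample_size`, `gene_ids`, `study_id`
#' @export
correlation_matrix <- function(study, method = c("msoc", "moc", "cc"),
                               ridge = 1e-8) {
  stopifnot(inherits(study, "omics_study"))
  method <- match.arg(method)
  G <- length(study$gene_ids)
  if (G < 2) stop("need at least two genes")
  if (study$sample_size < 3)
    stop("need at least 3 samples to estimate correlations")
  M <- switch(method,
    msoc = .pairwise_msoc(study),
    moc  = .pairwise_moc(study),
    cc   = .pairwise_cc(study, ridge))
  structure(
    list(values = M[lower.tri(M)], method = method,
         sample_size = study$sample_size, gene_ids = study$gene_ids,
         study_id = study$study_id),
    class = "corr_vector")
}

#' @export
print.corr_vector <- function(x, ...) {
  cat("Gene-pair correlation vector (", toupper(x$method), "), study '",
      x$study_id, "': G = ", length(x$gene_ids), ", p* = ",
      length(x$values), ", Sk = ", x$sample_size, "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.corr_vector <- function(x, ...) {
  vec_to_cormat(x$values, x$gene_ids)
}

# MSOC, all pairs at once: per omics type a G x G correlation matrix,
# then the signed entry of maximum magnitude across types.
.pairwise_msoc <- function(study) {
  best <- NULL; besta <- NULL
  for (v in seq_len(study$n_omics)) {
    Cv <- .safe_cor(t(study$omics[[v]]), t(study$omics[[v]]))
    if (is.null(best)) { best <- Cv; besta <- abs(Cv) } else {
      upd <- abs(Cv) > besta
      best[upd] <- Cv[upd]; besta[upd] <- abs(Cv)[upd]
    }
  }
  diag(best) <- 1
  best
}

# MOC: correlations between every omics column of every gene; per gene
# pair the signed max-magnitude entry of its V x V block.
.pairwise_moc <- function(study) {
  V <- study$n_omics
  best <- NULL; besta <- NULL
  for (v1 in seq_len(V)) for (v2 in seq_len(V)) {
    Cv <- .safe_cor(t(study$omics[[v1]]), t(study$omics[[v2]]))
    if (is.null(best)) { best <- Cv; besta <- abs(Cv) } else {
      upd <- abs(Cv) > besta
      best[upd] <- Cv[upd]; besta[upd] <- abs(Cv)[upd]
    }
  }
  # symmetrize: block (v1,v2) of pair (a,b) equals block (v2,v1) of (b,a),
  # but strict '>' tie-breaking can differ across the diagonal at equal
  # magnitude; enforce symmetry from the upper triangle
  best[lower.tri(best)] <- t(best)[lower.tri(best)]
  diag(best) <- 1
  best
}

.pairwise_cc <- function(study, ridge) {
  G <- length(study$gene_ids)
  Sk <- study$sample_size
  if (Sk < study$n_omics + 2)
    stop("sample size too small for canonical correlation (need Sk >= V + 2)")
  qs <- lapply(study$gene_ids,
               function(g) .whiten(gene_matrix(study, g), ridge))
  M <- diag(1, G)
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    d <- svd(crossprod(qs[[i]], qs[[j]]), nu = 0, nv = 0)$d[1] / (Sk - 1)
    M[i, j] <- M[j, i] <- min(max(d, 0), 1)
  }
  dimnames(M) <- list(study$gene_ids, study$gene_ids)
  M
}
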