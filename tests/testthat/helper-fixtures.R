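# small random study builders and independent reference implementations
# used as oracles across the test files

make_study <- function(G = 6, Sk = 40, V = 2, seed = 1, study_id = "study1",
                       gene_ids = sprintf("g%02d", seq_len(G))) {
  set.seed(seed)
  omics <- lapply(seq_len(V), function(v) {
    m <- matrix(rnorm(G * Sk), G, Sk,
                dimnames = list(gene_ids, sprintf("s%02d", seq_len(Sk))))
    m
  })
  names(omics) <- paste0("om", seq_len(V))
  omics_study(omics, study_id = study_id)
}

write_study_files <- function(study, dir, format = "tsv") {
  sep <- if (format == "tsv") "\t" else ","
  vapply(names(study$omics), function(nm) {
    path <- file.path(dir, paste0(nm, ".", format))
    m <- study$omics[[nm]]
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    path
  }, character(1))
}

# first canonical correlation via the generalized eigenproblem
# Sxx^{-1} Sxy Syy^{-1} Syx (independent of the SVD/whitening route)
cc_eigen_oracle <- function(m1, m2) {
  x <- scale(m1, scale = FALSE); y <- scale(m2, scale = FALSE)
  n <- nrow(x) - 1
  Sxx <- crossprod(x) / n; Syy <- crossprod(y) / n; Sxy <- crossprod(x, y) / n
  ev <- eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy),
              only.values = TRUE)$values
  sqrt(max(pmax(Re(ev), 0)))
}

# triple-loop TOM reference
tom_reference <- function(A) {
  G <- nrow(A)
  out <- diag(1, G)
  k <- rowSums(A) - diag(A)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i == j) next
    l <- 0
    for (g in seq_len(G)) if (g != i && g != j) l <- l + A[i, g] * A[g, j]
    out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  out
}

# dense brute-force GLS pooling with explicit matrix inversion
gls_reference <- function(rs) {
  p <- length(rs[[1]]$values)
  W <- matrix(0, p, p); bsum <- numeric(p)
  for (r in rs) {
    Tk <- mmagc:::.build_tk(vec_to_cormat(r$values), r$sample_size)
    Tinv <- solve(Tk)
    W <- W + Tinv
    bsum <- bsum + Tinv %*% r$values
  }
  as.vector(solve(W) %*% bsum)
}

# brute-force double-loop mean connectivity
mean_connectivity_reference <- function(A) {
  G <- nrow(A)
  tot <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) if (i != j) tot <- tot + A[i, j]
  tot / G
}

# a corr_vector built directly from a matrix (bypasses correlation_matrix)
as_corr_vector <- function(M, Sk, method = "msoc", study_id = "s") {
  structure(list(values = M[lower.tri(M)], method = method, sample_size = Sk,
                 gene_ids = rownames(M), study_id = study_id),
            class = "corr_vector")
}

# random symmetric matrix with entries in [0,1] and unit diagonal
random_unit_corr <- function(G, seed) {
  set.seed(seed)
  M <- matrix(runif(G * G), G)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(sprintf("g%02d", 1:G), sprintf("g%02d", 1:G))
  M
}
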