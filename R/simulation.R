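#' Simulation configuration
#'
#' Describes one synthetic multi-omics study: G genes partitioned into
#' `n_clusters` planted clusters of equal size, V omics types per gene,
#' and multivariate normal data whose (G*V) x (G*V) correlation matrix is
#' built from five correlation parameters:
#' \describe{
#'   \item{tau1}{between omics of the same gene}
#'   \item{tau2}{same omics type, different genes, same cluster}
#'   \item{tau3}{different omics types, different genes, same cluster}
#'   \item{tau4}{between genes of different clusters (any omics)}
#'   \item{tau5}{background correlation used to rewire perturbed genes}
#' }
#' In a proportion `p` of the clusters the first `n_perturbed_genes` genes
#' have their omics-1 correlations with omics 1 of every other gene set to
#' tau5, emulating one omics type telling a different story than the rest.
#'
#' The defaults are the reference study conditions used throughout the
#' package's benchmarks: 50 genes in 10 clusters of 5, three omics, five
#' studies of 100 samples, tau = (0.6, 0.4, 0.3, 0.1, 0.1), p = 0.3.
#'
#' @param G number of genes (must equal n_clusters * cluster size)
#' @param n_clusters number of planted clusters
#' @param V omics types per gene
#' @param K number of studies (used by [simulate_meta] when a single
#'   config is replicated)
#' @param Sk samples per study
#' @param tau numeric length-5 vector (tau1..tau5), each in \[0, 1)
#' @param p proportion of clusters perturbed, in \[0, 1\]
#' @param n_perturbed_genes genes rewired per perturbed cluster (default 3,
#'   capped at the cluster size)
#' @return object of class `sim_config`
#' @export
sim_config <- function(G = 50, n_clusters = 10, V = 3, K = 5, Sk = 100,
                       tau = c(0.6, 0.4, 0.3, 0.1, 0.1), p = 0.3,
                       n_perturbed_genes = min(3, G %/% n_clusters)) {
  stopifnot(length(tau) == 5, all(tau >= 0), all(tau < 1),
            p >= 0, p <= 1, G >= 2, V >= 1, K >= 1, Sk >= 1,
            n_clusters >= 1, G %% n_clusters == 0,
            n_perturbed_genes >= 1, n_perturbed_genes <= G / n_clusters)
  structure(
    list(G = as.integer(G), n_clusters = as.integer(n_clusters),
         cluster_size = as.integer(G / n_clusters), V = as.integer(V),
         K = as.integer(K), Sk = as.integer(Sk), tau = as.numeric(tau),
         p = p, n_perturbed_genes = as.integer(n_perturbed_genes)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: G =", x$G, "genes in", x$n_clusters,
      "clusters of", x$cluster_size, "| V =", x$V, "| K =", x$K,
      "| Sk =", x$Sk, "\n  tau =", paste(x$tau, collapse = ", "),
      "| p =", x$p, "(", x$n_perturbed_genes, "genes rewired per",
      "perturbed cluster )\n")
  invisible(x)
}

# variable ordering in the big matrix is gene-major, omics-minor:
# gene 1 omics 1..V, gene 2 omics 1..V, ...
.sim_gene_ids <- function(cfg) {
  sprintf(paste0("gene_%0", nchar(cfg$G), "d"), seq_len(cfg$G))
}

#' Block correlation matrix of the simulation model
#'
#' Builds the (G*V) x (G*V) correlation matrix implied by a
#' [sim_config] (before perturbation): unit diagonal, tau1 within gene,
#' tau2/tau3 within cluster (same/different omics type), tau4 between
#' clusters. Fails if the result is not positive definite.
#'
#' @param cfg a [sim_config]
#' @return symmetric positive-definite correlation matrix
#' @export
build_correlation_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gg <- rep(seq_len(cfg$G), each = cfg$V)
  vv <- rep(seq_len(cfg$V), cfg$G)
  cl <- (gg - 1L) %/% cfg$cluster_size + 1L
  same_gene <- outer(gg, gg, `==`)
  same_omics <- outer(vv, vv, `==`)
  same_cl <- outer(cl, cl, `==`)
  S <- matrix(cfg$tau[4], cfg$G * cfg$V, cfg$G * cfg$V)
  S[same_cl & !same_gene & !same_omics] <- cfg$tau[3]
  S[same_cl & !same_gene & same_omics] <- cfg$tau[2]
  S[same_gene & !same_omics] <- cfg$tau[1]
  diag(S) <- 1
  .assert_pd(S, "the simulation correlation matrix")
  S
}

#' Perturb the simulation correlation matrix
#'
#' For each of the first `ceiling(p * n_clusters)` clusters, the first
#' `n_perturbed_genes` genes of the cluster have the correlation between
#' their omics type 1 and omics type 1 of the other genes of their
#' cluster set to tau5 (symmetrically), so that omics type 1 stops
#' carrying that cluster's signal for those genes. All other entries are
#' untouched and the perturbed matrix must remain positive definite.
#'
#' Rewiring is confined to the gene's own cluster: the cross-cluster
#' omics-1 correlations already sit at the between-cluster level tau4,
#' and forcing them to tau5 as well would make the matrix indefinite
#' whenever tau5 < tau4 (the weak-signal settings). When tau4 = tau5 the
#' two formulations coincide.
#'
#' @param S matrix from [build_correlation_matrix]
#' @param cfg the same [sim_config]
#' @return perturbed correlation matrix
#' @export
apply_perturbation <- function(S, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_pert <- ceiling(cfg$p * cfg$n_clusters)
  if (n_pert == 0) return(S)
  for (clu in seq_len(n_pert)) {
    genes_cl <- (clu - 1L) * cfg$cluster_size + seq_len(cfg$cluster_size)
    omics1_cl <- (genes_cl - 1L) * cfg$V + 1L
    for (g in genes_cl[seq_len(cfg$n_perturbed_genes)]) {
      j <- (g - 1L) * cfg$V + 1L
      others <- setdiff(omics1_cl, j)
      S[j, others] <- cfg$tau[5]
      S[others, j] <- cfg$tau[5]
    }
  }
  .assert_pd(S, "the perturbed correlation matrix")
  S
}

.assert_pd <- function(S, what, tol = 1e-10) {
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= tol)
    stop(what, " is not positive definite (smallest eigenvalue ",
         signif(ev, 4), ")")
  invisible(ev)
}

#' Simulate one labeled study
#'
#' Draws Sk iid samples from the (G*V)-variate normal with mean 0 and the
#' perturbed block correlation matrix as covariance, then reshapes them to
#' V genes-by-samples matrices. The planted cluster labels ride along for
#' ARI evaluation.
#'
#' @param cfg a [sim_config]
#' @param seed integer seed (the draw is reproducible bit-for-bit)
#' @param study_id study identifier
#' @param .chol optional precomputed Cholesky factor of the perturbed
#'   correlation matrix (upper triangular), to avoid rebuilding it across
#'   replicates
#' @return object of class `labeled_study`: list with `study` (an
#'   [omics_study]) and `labels` (named integer vector of true clusters)
#' @export
simulate_study <- function(cfg, seed, study_id = "study1", .chol = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(.chol))
    .chol <- chol(apply_perturbation(build_correlation_matrix(cfg), cfg))
  set.seed(seed)
  D <- cfg$G * cfg$V
  X <- matrix(stats::rnorm(cfg$Sk * D), cfg$Sk, D) %*% .chol
  ids <- .sim_gene_ids(cfg)
  samples <- sprintf("s%03d", seq_len(cfg$Sk))
  omics <- lapply(seq_len(cfg$V), function(v) {
    M <- t(X[, (seq_len(cfg$G) - 1L) * cfg$V + v, drop = FALSE])
    dimnames(M) <- list(ids, samples)
    M
  })
  names(omics) <- paste0("omics", seq_len(cfg$V))
  labels <- stats::setNames(rep(seq_len(cfg$n_clusters),
                                each = cfg$cluster_size), ids)
  structure(list(study = omics_study(omics, study_id), labels = labels),
            class = "labeled_study")
}

#' @export
print.labeled_study <- function(x, ...) {
  print(x$study)
  cat("  planted clusters:", max(x$labels), "\n")
  invisible(x)
}

#' Simulate a multi-study collection
#'
#' Generates K independent studies. `cfgs` is either a single
#' [sim_config] (replicated `cfg$K` times: the iid case) or a list of K
#' configs sharing G, `n_clusters` and V (studies differing in p or in the
#' tau vector). Per-study seeds are drawn deterministically from
#' `master_seed`, so studies are mutually independent yet the whole
#' collection is reproducible.
#'
#' @param cfgs a [sim_config] or list of them
#' @param master_seed integer seed
#' @return list of `labeled_study` objects
#' @export
simulate_meta <- function(cfgs, master_seed) {
  if (inherits(cfgs, "sim_config")) cfgs <- rep(list(cfgs), cfgs$K)
  stopifnot(is.list(cfgs), length(cfgs) >= 1,
            all(vapply(cfgs, inherits, logical(1), "sim_config")))
  ref <- cfgs[[1]]
  for (cfg in cfgs[-1])
    if (cfg$G != ref$G || cfg$n_clusters != ref$n_clusters || cfg$V != ref$V)
      stop("all configs must share G, n_clusters and V")
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, length(cfgs))
  # cache the Cholesky factor per distinct parameter set
  keys <- vapply(cfgs, function(cfg)
    paste(c(cfg$tau, cfg$p, cfg$n_perturbed_genes), collapse = "|"),
    character(1))
  chols <- new.env(parent = emptyenv())
  lapply(seq_along(cfgs), function(k) {
    key <- keys[k]
    if (is.null(chols[[key]]))
      chols[[key]] <- chol(apply_perturbation(
        build_correlation_matrix(cfgs[[k]]), cfgs[[k]]))
    simulate_study(cfgs[[k]], seeds[k], study_id = paste0("study", k),
                   .chol = chols[[key]])
  })
}
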