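#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions,
#' computed from the contingency table. Equals 1 iff the partitions are
#' identical up to relabeling; has expectation 0 under random labeling.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type)
#' @return scalar <= 1
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(labels_a), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)   # degenerate: both partitions trivially agree
  (sij - expected) / denom
}

# one clustering pass: finalized correlation matrix -> labels
.cluster_corr <- function(corr_final, power_rule = "inflection",
                          grid = 1:20, min_cluster_size = 3, cut = "gap") {
  m <- suppressWarnings(select_power(corr_final, grid, rule = power_rule))
  tom <- tom_similarity(adjacency(corr_final, as.integer(m)))
  tom_cluster(tom, min_cluster_size = min_cluster_size, cut = cut)
}

# parse a method name from the benchmarking roster
.parse_method <- function(name) {
  if (grepl("^Meta_(CC|MOC|MSOC)(_Diag)?(_[0-9]+)?$", name)) {
    parts <- strsplit(name, "_")[[1]]
    list(kind = "meta", measure = tolower(parts[2]),
         variant = if ("Diag" %in% parts) "diagonal" else "full",
         n_studies = if (grepl("[0-9]+$", parts[length(parts)]))
           as.integer(parts[length(parts)]) else NA_integer_)
  } else if (grepl("^(CC|MOC|MSOC)-[0-9]+$", name)) {
    parts <- strsplit(name, "-")[[1]]
    list(kind = "single", measure = tolower(parts[1]),
         study = as.integer(parts[2]))
  } else if (name %in% c("WGCNA1", "WGCNA2")) {
    list(kind = "wgcna",
         rule = if (name == "WGCNA1") "inflection" else "traditional")
  } else if (name %in% c("KM1", "KM2")) {
    list(kind = "kmeans", gap = name == "KM2")
  } else stop("unknown method name: ", name)
}

#' Replicate a simulation scenario and score methods by ARI
#'
#' For each replicate, simulates K studies from `cfgs` (see
#' [simulate_meta]), runs each requested method end-to-end — per-study
#' correlation, optional fixed-effects pooling, absolute
#' value/finalization, power selection, TOM, hierarchical clustering —
#' and records the adjusted Rand index against the planted clusters.
#'
#' Method names follow the benchmarking roster:
#' \itemize{
#'   \item `Meta_MSOC_Diag`, `Meta_MOC`, `Meta_CC_Diag_3`, ... —
#'     multi-study methods; the optional trailing integer pools only the
#'     first so-many studies (default: all), `_Diag` selects the diagonal
#'     error covariance, otherwise the full GLS is used.
#'   \item `MSOC-2`, `CC-1`, ... — the measure applied to a single study.
#'   \item `WGCNA1` / `WGCNA2` — single-omics clustering of omics type 1
#'     of study 1 with the inflection / traditional power rule.
#'   \item `KM1` / `KM2` — K-means comparators on the same single-omics
#'     data; `KM1` uses the true number of clusters, `KM2` chooses it by
#'     the gap statistic. Comparators only, not part of the method.
#' }
#' Multi-omics methods use `power_rule` (default inflection).
#'
#' @param cfgs a [sim_config] or list of them (one per study)
#' @param methods character vector of method names
#' @param n_reps number of replicates
#' @param master_seed integer seed; the whole run is reproducible
#' @param power_rule power-selection rule for the multi-omics methods
#' @param grid power grid
#' @param min_cluster_size minimum cluster size for pruning
#' @return data.frame with columns `method`, `mean_ari`, `sd_ari`,
#'   `n_reps`; the per-replicate ARI matrix is attached as attribute
#'   `"ari"`
#' @export
run_scenario <- function(cfgs, methods = c("Meta_MSOC_Diag", "MSOC-1"),
                         n_reps = 100, master_seed = 1,
                         power_rule = c("inflection", "traditional"),
                         grid = 1:20, min_cluster_size = 3) {
  power_rule <- match.arg(power_rule)
  stopifnot(n_reps >= 1)
  specs <- lapply(methods, .parse_method)
  names(specs) <- methods
  set.seed(master_seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  measures_needed <- unique(unlist(lapply(specs, function(s)
    if (s$kind %in% c("meta", "single")) s$measure else NULL)))
  ari <- matrix(NA_real_, n_reps, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    studies <- simulate_meta(cfgs, rep_seeds[r])
    truth <- studies[[1]]$labels
    cvs <- lapply(measures_needed, function(me)
      lapply(studies, function(ls) correlation_matrix(ls$study, me)))
    names(cvs) <- measures_needed
    for (mi in seq_along(methods)) {
      s <- specs[[mi]]
      labels <- switch(s$kind,
        meta = {
          nk <- if (is.na(s$n_studies)) length(studies) else s$n_studies
          rs <- cvs[[s$measure]][seq_len(nk)]
          pooled <- if (s$variant == "diagonal") combine_diagonal(rs)
                    else combine_full(rs)
          .cluster_corr(finalize_for_clustering(pooled), power_rule,
                        grid, min_cluster_size)
        },
        single = .cluster_corr(
          finalize_for_clustering(cvs[[s$measure]][[s$study]]),
          power_rule, grid, min_cluster_size),
        wgcna = {
          X <- studies[[1]]$study$omics[[1]]
          C <- abs(.safe_cor(t(X), t(X)))
          diag(C) <- 1
          .cluster_corr(C, s$rule, grid, min_cluster_size)
        },
        kmeans = .kmeans_labels(studies[[1]]$study$omics[[1]],
                                max(truth), s$gap))
      ari[r, mi] <- adjusted_rand_index(truth, labels)
    }
  }
  out <- data.frame(method = methods,
                    mean_ari = colMeans(ari),
                    sd_ari = apply(ari, 2, stats::sd),
                    n_reps = n_reps, row.names = NULL)
  attr(out, "ari") <- ari
  out
}

# K-means comparators on single-omics genes-by-samples data
.kmeans_labels <- function(X, c_true, use_gap) {
  centers <- c_true
  if (use_gap) {
    if (!requireNamespace("cluster", quietly = TRUE))
      stop("the gap-statistic comparator needs the 'cluster' package")
    gap <- cluster::clusGap(X, FUN = function(x, k)
      stats::kmeans(x, k, nstart = 25), K.max = c_true + 10, B = 25,
      verbose = FALSE)
    centers <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                              method = "Tibs2001SEmax")
  }
  stats::kmeans(X, centers, nstart = 25)$cluster
}
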