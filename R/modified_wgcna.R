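#' Soft-threshold adjacency
#'
#' Raises every entry of a nonnegative gene-to-gene correlation matrix to
#' the integer power m (the soft threshold), suppressing weak
#' correlations; the diagonal is set to 1.
#'
#' @param corr symmetric matrix with entries in \[0, 1\]
#'   (see [finalize_for_clustering])
#' @param power integer m >= 1
#' @return adjacency matrix, entries in \[0, 1\], unit diagonal
#' @export
adjacency <- function(corr, power) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (power < 1) stop("power must be >= 1")
  if (min(corr) < -1e-12 || max(corr) > 1 + 1e-12)
    stop("correlation entries must lie in [0, 1]; run finalize_for_clustering first")
  A <- pmax(pmin(corr, 1), 0)^power
  diag(A) <- 1
  A
}

#' Mean connectivity of a weighted network
#'
#' Average over genes of the sum of adjacency weights to all other genes
#' (self excluded).
#'
#' @param adj adjacency matrix
#' @return nonnegative scalar
#' @export
mean_connectivity <- function(adj) {
  mean(rowSums(adj) - diag(adj))
}

#' Scale-free topology fit
#'
#' Bins the per-gene connectivities into `n_bins` equal-width bins and
#' regresses log10(frequency) on log10(mean connectivity) over the
#' nonempty bins; returns the adjusted R-squared of that simple linear
#' fit. With fewer than three usable bins the fit is not assessable and
#' `NA` is returned.
#'
#' @param adj adjacency matrix
#' @param n_bins number of equal-width connectivity bins (default 10)
#' @return adjusted R-squared in (-Inf, 1\], or `NA_real_` when not
#'   assessable
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  k <- rowSums(adj) - diag(adj)
  if (length(k) < 2 * n_bins)
    warning("fewer than 2 genes per bin; the scale-free fit is unstable")
  rng <- range(k)
  if (rng[2] - rng[1] <= 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  km <- vapply(seq_len(n_bins), function(i) mean(k[as.integer(bin) == i]),
               numeric(1))
  keep <- freq > 0 & km > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(km[keep]))
  summary(fit)$adj.r.squared
}

#' Connectivity profile over a power grid
#'
#' Evaluates, for each candidate power m, the mean connectivity k(m), the
#' scale-free adjusted R-squared, and the relative connectivity change
#' rate (k(m-1) - k(m)) / k(m-1) (with the convention k(0) = G - 1, the
#' connectivity of the untransformed complete network).
#'
#' @param corr finalized correlation matrix (entries in \[0, 1\])
#' @param grid ascending integer powers (default 1:20)
#' @param n_bins bins for [scale_free_fit]
#' @return data.frame with columns `power`, `k`, `r2`, `rate`
#' @export
connectivity_profile <- function(corr, grid = 1:20, n_bins = 10) {
  stopifnot(all(diff(grid) > 0), all(grid >= 1))
  if (nrow(corr) < 2 * n_bins)
    warning("fewer than 2 genes per bin; the scale-free fit is unstable")
  k <- vapply(grid, function(m) mean_connectivity(adjacency(corr, m)),
              numeric(1))
  r2 <- vapply(grid, function(m)
    suppressWarnings(scale_free_fit(adjacency(corr, m), n_bins)),
    numeric(1))
  kprev <- vapply(grid, function(m) {
    if (m - 1 >= 1) mean_connectivity(adjacency(corr, m - 1))
    else nrow(corr) - 1
  }, numeric(1))
  rate <- ifelse(kprev > 0, (kprev - k) / kprev, 0)
  data.frame(power = grid, k = k, r2 = r2, rate = rate)
}

#' Soft-threshold power selection
#'
#' Two selection rules operate on the connectivity profile:
#' \describe{
#'   \item{traditional}{the smallest grid power with scale-free adjusted
#'     R-squared >= `r2_cutoff` (default 0.60) and relative connectivity
#'     change rate <= `rate_cutoff` (default 1/3). If no power qualifies,
#'     the R-squared-maximizing power is returned with a warning.}
#'   \item{inflection}{the proposed rule. The mean-connectivity change
#'     rate rho(m) = (k(m) - k(m+1)) / k(m) always decreases with m, but
#'     its own rate of change s(m) = rho(m+1) - rho(m) need not be
#'     monotone; the rule returns the first grid power at which s attains
#'     a local extremum — the first inflection point of the change rate.
#'     (Rules phrased on the raw differences of k(m) cannot work: k(m)
#'     is a moment sequence of the adjacency entries and therefore
#'     completely monotone, so every finite difference of k has a fixed
#'     sign.) When s is monotone over the whole grid — typical for noisy
#'     single-study matrices whose connectivity decays smoothly — the
#'     power at the steepest change of the change rate (the grid
#'     maximizer of |s|, the knee of the decay) is used instead.}
#' }
#' The traditional rule tends to select large powers, driving the mean
#' connectivity toward zero; the inflection rule stops at the first power
#' where the connectivity decay changes character, typically a much
#' smaller value.
#'
#' @inheritParams connectivity_profile
#' @param rule `"inflection"` (default) or `"traditional"`
#' @param r2_cutoff,rate_cutoff thresholds of the traditional rule
#' @return the selected power (integer from `grid`), with the profile
#'   attached as attribute `"profile"`
#' @export
select_power <- function(corr, grid = 1:20,
                         rule = c("inflection", "traditional"),
                         r2_cutoff = 0.6, rate_cutoff = 1/3, n_bins = 10) {
  rule <- match.arg(rule)
  if (length(grid) < 3) stop("the power grid needs at least 3 points")
  if (rule == "inflection" && length(grid) < 5)
    stop("the inflection rule needs at least 5 grid points")
  prof <- connectivity_profile(corr, grid, n_bins)
  m <- if (rule == "traditional") .power_traditional(prof, r2_cutoff, rate_cutoff)
       else .power_inflection(prof, r2_cutoff, rate_cutoff)
  structure(m, profile = prof)
}

.power_traditional <- function(prof, r2_cutoff, rate_cutoff) {
  ok <- !is.na(prof$r2) & prof$r2 >= r2_cutoff & prof$rate <= rate_cutoff
  if (any(ok)) return(prof$power[which(ok)[1]])
  warning("no power satisfies the scale-free criterion; ",
          "falling back to the R-squared-maximizing power")
  r2 <- ifelse(is.na(prof$r2), -Inf, prof$r2)
  prof$power[which.max(r2)]
}

.power_inflection <- function(prof, r2_cutoff, rate_cutoff) {
  k <- prof$k
  n <- length(k)
  # change rate of the mean connectivity: rho[i] spans powers i..i+1
  rho <- (k[-n] - k[-1]) / k[-n]
  # its rate of change: s[i] spans powers i..i+2, centered on power i+1
  s <- diff(rho)
  ds <- diff(s)
  # local extremum of s at position i+1: slope sign change across it
  ext <- which(ds[-length(ds)] * ds[-1] < 0) + 1L
  i <- if (length(ext)) ext[1] else which.max(abs(s))
  prof$power[i + 1L]
}

#' Topological overlap similarity
#'
#' For genes g1 != g2 with adjacency a = a_{g1,g2}, shared-neighbor weight
#' l = sum over g of a_{g1,g} a_{g,g2} (g excluding g1, g2) and
#' connectivities k_{g} = sum of a_{g,.} excluding self:
#' \deqn{TOM_{g_1,g_2} = \frac{l + a}{\min(k_{g_1}, k_{g_2}) + 1 - a}}
#' with diagonal 1. When the adjacency entries lie in \[0, 1\] so do all
#' TOM entries.
#'
#' @param adj adjacency matrix with entries in \[0, 1\], unit diagonal
#' @return symmetric TOM matrix in \[0, 1\] with unit diagonal
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  A <- adj
  diag(A) <- 1
  L <- A %*% A - 2 * A             # off-diagonal: sum_g a_ig a_gj, g != i,j
  k <- rowSums(A) - 1
  mins <- outer(k, k, pmin)
  tom <- (L + A) / (mins + 1 - A)
  tom <- pmax(pmin(tom, 1), 0)     # guard floating-point spill only
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Cluster genes from a TOM similarity matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering on the dissimilarity
#' D = 1 - TOM. The dendrogram is cut either at a user-supplied height, at
#' a quantile of the merge heights, or (default) where the merge
#' similarity 1 - h drops by the largest factor between consecutive
#' merges, cutting at the geometric midpoint of that drop. Working on the
#' similarity scale makes the rule invariant to the overall compression
#' of the dendrogram at high soft-threshold powers (where all heights
#' approach 1 but their ratios still separate within-cluster from
#' between-cluster merges); it is deterministic and recovers separable
#' block structure exactly.
#' Clusters smaller than `min_cluster_size` are dissolved and their genes
#' reassigned to the surviving cluster at smallest average dissimilarity
#' (or labeled 0 when no cluster survives); labels are renumbered 1..C by
#' decreasing final cluster size.
#'
#' @param tom TOM (or any similarity) matrix, entries in \[0, 1\]
#' @param min_cluster_size clusters below this size are dissolved
#'   (default 3)
#' @param cut `"gap"` (default), `"quantile"`, or a numeric height in
#'   \[0, 1\]
#' @param q quantile of merge heights used when `cut = "quantile"`
#' @return named integer vector of cluster labels (0 = unassigned), with
#'   attributes `hclust` (the tree), `cut_height` and `min_cluster_size`
#' @export
tom_cluster <- function(tom, min_cluster_size = 3, cut = "gap", q = 0.99) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom), min_cluster_size >= 1)
  G <- nrow(tom)
  ids <- rownames(tom)
  if (is.null(ids)) ids <- paste0("g", seq_len(G))
  D <- 1 - tom
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  h <- sort(hc$height)
  cut_height <- if (is.numeric(cut)) {
    cut
  } else if (identical(cut, "quantile")) {
    stats::quantile(hc$height, q, names = FALSE)
  } else if (identical(cut, "gap")) {
    if (length(h) > 1) {
      sim <- pmax(1 - h, 1e-15)          # merge similarity, descending
      i <- which.max(sim[-length(sim)] / sim[-1])
      1 - sqrt(sim[i] * sim[i + 1])      # geometric midpoint of the drop
    } else max(h)              # single merge: one cluster
  } else stop("'cut' must be \"gap\", \"quantile\" or a numeric height")
  raw <- stats::cutree(hc, h = cut_height)
  labels <- .prune_clusters(raw, D, min_cluster_size)
  names(labels) <- ids
  structure(labels, hclust = hc, cut_height = cut_height,
            min_cluster_size = min_cluster_size)
}

# dissolve clusters below the minimum size and reassign their genes to the
# nearest surviving cluster by average dissimilarity
.prune_clusters <- function(raw, D, min_cluster_size) {
  sizes <- table(raw)
  survivors <- as.integer(names(sizes)[sizes >= min_cluster_size])
  out <- integer(length(raw))
  if (length(survivors) == 0) return(out)
  core <- lapply(survivors, function(cl) which(raw == cl))
  for (g in seq_along(raw)) {
    if (raw[g] %in% survivors) {
      out[g] <- raw[g]
    } else {
      avg <- vapply(core, function(members) mean(D[g, members]), numeric(1))
      out[g] <- survivors[which.min(avg)]
    }
  }
  # renumber 1..C by decreasing final size (ties: smaller original label)
  fs <- table(out)
  ord <- order(-as.integer(fs), as.integer(names(fs)))
  relabel <- stats::setNames(seq_along(ord), names(fs)[ord])
  as.integer(relabel[as.character(out)])
}
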