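#' Meta-analytic multi-omics gene clustering
#'
#' Fits the full three-step procedure to a collection of multi-omics
#' studies: (I) a per-study gene-to-gene correlation under the chosen
#' measure (MSOC, MOC or CC); (II) fixed-effects pooling of the study
#' correlation vectors (diagonal or full generalized-least-squares error
#' covariance); (III) modified weighted-correlation-network clustering of
#' the pooled matrix — soft-threshold power selection, topological
#' overlap, average-linkage hierarchical clustering and
#' minimum-cluster-size pruning. With a single study, step II is the
#' identity and the result is single-study clustering.
#'
#' Studies are first restricted to their common gene list (sorted), so
#' studies with unequal gene universes can be combined.
#'
#' @param studies an [omics_study], a `labeled_study`, or a list of them
#' @param method correlation measure: `"msoc"` (default), `"moc"`, `"cc"`
#' @param pool error-covariance variant for pooling: `"diagonal"`
#'   (default) or `"full"`
#' @param power `"inflection"` (default), `"traditional"`, or an integer
#'   soft-threshold power to fix it manually
#' @param grid integer power grid searched by the automatic rules
#' @param min_cluster_size clusters below this size are dissolved
#'   (default 3)
#' @param cut dendrogram cut policy, see [tom_cluster]
#' @param max_genes_full guard for the full-GLS workspace, see
#'   [combine_full]
#' @param ridge ridge for the canonical-correlation whitening (CC only)
#' @return an object of class `mmagc` with components `labels` (named
#'   integer cluster assignment, 0 = unassigned), `correlation` (pooled,
#'   finalized G x G matrix), `tom`, `power` (selected power),
#'   `profile` (connectivity profile data.frame), `tree` (the hclust
#'   object), `cut_height`, and the fitting metadata (`method`, `pool`,
#'   `K`, `G`, `V`, `sample_sizes`, `gene_ids`, `call`).
#' @seealso [simulate_meta] to generate synthetic studies,
#'   [run_scenario] for replicated benchmarking.
#' @examples
#' cfg <- sim_config(G = 20, n_clusters = 4, V = 2, K = 3, Sk = 60)
#' studies <- simulate_meta(cfg, master_seed = 7)
#' fit <- mmagc(studies, method = "msoc", pool = "diagonal")
#' fit
#' table(labels(fit), studies[[1]]$labels)
#' @export
mmagc <- function(studies, method = c("msoc", "moc", "cc"),
                  pool = c("diagonal", "full"),
                  power = "inflection", grid = 1:20,
                  min_cluster_size = 3, cut = "gap",
                  max_genes_full = 200, ridge = 1e-8) {
  cl <- match.call()
  method <- match.arg(method)
  pool <- match.arg(pool)
  studies <- .as_study_list(studies)
  genes <- intersect_genes(studies)
  studies <- lapply(studies, function(s)
    if (identical(s$gene_ids, genes)) s else subset_genes(s, genes))
  rs <- lapply(studies, correlation_matrix, method = method, ridge = ridge)
  pooled <- if (length(rs) == 1) combine_diagonal(rs)
            else if (pool == "diagonal") combine_diagonal(rs)
            else combine_full(rs, max_genes = max_genes_full)
  corr <- finalize_for_clustering(pooled)
  if (is.numeric(power)) {
    m <- as.integer(power)
    prof <- connectivity_profile(corr, grid)
    rule <- "fixed"
  } else {
    rule <- match.arg(power, c("inflection", "traditional"))
    m <- select_power(corr, grid, rule = rule)
    prof <- attr(m, "profile")
    m <- as.integer(m)
  }
  tom <- tom_similarity(adjacency(corr, m))
  labels <- tom_cluster(tom, min_cluster_size = min_cluster_size, cut = cut)
  structure(
    list(labels = labels, correlation = corr, tom = tom, power = m,
         power_rule = rule, profile = prof,
         tree = attr(labels, "hclust"),
         cut_height = attr(labels, "cut_height"),
         min_cluster_size = min_cluster_size,
         method = method, pool = if (length(rs) == 1) "diagonal" else pool,
         K = length(rs), G = length(genes),
         V = studies[[1]]$n_omics,
         sample_sizes = vapply(studies, `[[`, numeric(1), "sample_size"),
         gene_ids = genes, call = cl),
    class = "mmagc")
}

.as_study_list <- function(studies) {
  unwrap <- function(s) {
    if (inherits(s, "labeled_study")) s$study
    else if (inherits(s, "omics_study")) s
    else stop("'studies' must be omics_study or labeled_study objects")
  }
  if (inherits(studies, c("omics_study", "labeled_study")))
    return(list(unwrap(studies)))
  stopifnot(is.list(studies), length(studies) >= 1)
  lapply(studies, unwrap)
}

#' @export
print.mmagc <- function(x, ...) {
  n_cl <- max(x$labels)
  cat("Meta-analytic multi-omics gene clustering\n")
  cat("  measure: ", toupper(x$method), ", pooling: ", x$pool,
      " T_k, K = ", x$K, " studies (n = ",
      paste(x$sample_sizes, collapse = ", "), ")\n", sep = "")
  cat("  G = ", x$G, " genes, V = ", x$V, " omics; power m = ", x$power,
      " (", x$power_rule, " rule)\n", sep = "")
  cat("  ", n_cl, " clusters (min size ", x$min_cluster_size, "), ",
      sum(x$labels == 0), " unassigned gene(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.mmagc <- function(object, ...) {
  sizes <- table(factor(object$labels[object$labels > 0]))
  structure(list(fit = object, sizes = sizes), class = "summary.mmagc")
}

#' @export
print.summary.mmagc <- function(x, ...) {
  print(x$fit)
  cat("\nCluster sizes:\n")
  print(x$sizes)
  prof <- x$fit$profile
  sel <- prof[prof$power == x$fit$power, , drop = FALSE]
  cat("\nAt the selected power: mean connectivity k = ",
      signif(sel$k, 4), ", scale-free adj. R^2 = ",
      signif(sel$r2, 3), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname mmagc
#' @param object,x a fitted `mmagc` object
#' @param ... unused
coef.mmagc <- function(object, ...) object$correlation

#' @export
#' @rdname mmagc
labels.mmagc <- function(object, ...) {
  out <- as.integer(object$labels)
  names(out) <- names(object$labels)
  out
}

#' Diagnostic plots for a fitted clustering
#'
#' Left: mean connectivity (log scale) against candidate power, with the
#' selected power marked. Right: the gene dendrogram with the cut height.
#'
#' @param x a fitted `mmagc` object
#' @param ... passed to `plot.hclust`
#' @export
plot.mmagc <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  prof <- x$profile
  plot(prof$power, prof$k, log = "y", type = "b", pch = 19,
       xlab = "soft-threshold power m", ylab = "mean connectivity k(m)",
       main = "Connectivity profile")
  graphics::abline(v = x$power, lty = 2)
  plot(x$tree, labels = FALSE, hang = -1, xlab = "", sub = "",
       main = paste0("TOM dendrogram (", max(x$labels), " clusters)"), ...)
  graphics::abline(h = x$cut_height, lty = 2, col = "red3")
  invisible(x)
}
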