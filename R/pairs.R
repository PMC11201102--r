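#' Canonical gene-pair indexing
#'
#' All per-study and pooled correlation vectors in this package store the
#' \eqn{p^* = G(G-1)/2} distinct gene pairs in row-major upper-triangle
#' order: (1,2), (1,3), ..., (1,G), (2,3), ..., (G-1,G).  This is the order
#' in which R's \code{lower.tri()} enumerates a matrix column-by-column, so
#' \code{M[lower.tri(M)]} extracts a vector in canonical pair order.
#'
#' @param G number of genes (>= 2)
#' @return `pair_index()`: a two-column integer matrix with columns `a`, `b`
#'   (`a < b`), one row per pair in canonical order. `n_pairs()`: the number
#'   of distinct pairs.
#' @examples
#' pair_index(4)
#' n_pairs(50)  # 1225
#' @export
pair_index <- function(G) {
  stopifnot(is.numeric(G), length(G) == 1, G >= 2)
  G <- as.integer(G)
  a <- rep.int(seq_len(G - 1L), times = (G - 1L):1L)
  b <- sequence((G - 1L):1L, from = 2:G)
  cbind(a = a, b = b)
}

#' @rdname pair_index
#' @export
n_pairs <- function(G) as.integer(G * (G - 1) / 2)

#' Convert between a pair-ordered vector and a symmetric correlation matrix
#'
#' @param v numeric vector of length \eqn{G(G-1)/2} in canonical pair order
#' @param gene_ids optional character vector of gene identifiers
#' @return a symmetric G x G matrix with unit diagonal
#' @export
vec_to_cormat <- function(v, gene_ids = NULL) {
  G <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(G - round(G)) > 1e-8)
    stop("length of 'v' is not G(G-1)/2 for any integer G")
  G <- as.integer(round(G))
  M <- matrix(0, G, G)
  M[lower.tri(M)] <- v
  M <- M + t(M)
  diag(M) <- 1
  if (!is.null(gene_ids)) dimnames(M) <- list(gene_ids, gene_ids)
  M
}

#' @rdname vec_to_cormat
#' @param M symmetric matrix
#' @export
cormat_to_vec <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  M[lower.tri(M)]
}
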