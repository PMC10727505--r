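#' Exact full correlation matrix via a single matrix product
#'
#' Projects every feature onto its correlation vector and computes the Gram
#' matrix of the projections, so the whole n-by-n correlation matrix is a
#' single BLAS-backed crossproduct.  Entries are clipped into \[-1, 1\] to
#' absorb floating-point rounding.
#'
#' @inheritParams project_correlation
#' @return A `correlation_matrix` with `values` (n x n), `feature_names`
#'   and `method`.
#' @examples
#' C <- full_correlation_matrix(feature_matrix(matrix(rnorm(40), 10, 4)))
#' range(diag(C$values))
#' @export
full_correlation_matrix <- function(X, method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  P <- project_correlation(X, method)
  R <- clip_range(crossprod(P$values), -1, 1)
  dimnames(R) <- list(X$feature_names, X$feature_names)
  structure(list(values = R, feature_names = X$feature_names, method = method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d (%s)\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

# Upper-triangle pairs of a square matrix as a data.frame(i, j, value).
upper_pairs <- function(R) {
  n <- nrow(R)
  ut <- which(upper.tri(R))
  loc <- arrayInd(ut, dim(R))
  data.frame(i = loc[, 1L], j = loc[, 2L], value = R[ut])
}

#' Exact top-k correlations from the full matrix (matrix backend)
#'
#' Computes the complete correlation matrix and extracts the `k` strongest
#' unordered feature pairs.  This is the exact reference ("matrix") backend
#' and the oracle against which the index backend is validated; it needs
#' O(n^2) memory.
#'
#' @inheritParams project_correlation
#' @param k Number of pairs, between 1 and n (n - 1) / 2.
#' @param ranking `"abs"` (default; strongest correlations of either sign)
#'   or `"signed"` (largest positive correlations).
#' @return An `edge_list` of exactly `k` rows, ordered by descending
#'   ranking key with ties broken by ascending pair index.
#' @export
topk_from_matrix <- function(X, k, ranking = c("abs", "signed"),
                             method = c("pearson", "spearman", "phi")) {
  ranking <- match.arg(ranking)
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  npairs <- count_pairs(ncol(X$values))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > npairs)
    stop_(sprintf("k must be in [1, %d]", npairs))
  k <- as.integer(round(k))
  C <- full_correlation_matrix(X, method)
  df <- sort_edges(upper_pairs(C$values), ranking)
  new_edge_list(df[seq_len(k), , drop = FALSE], X$feature_names,
                ranking, "correlation")
}

#' Exact thresholded correlations from the full matrix
#'
#' All unordered pairs with correlation at or above threshold `t`
#' (absolute value under `ranking = "abs"`), extracted from the full
#' correlation matrix.
#'
#' @inheritParams topk_from_matrix
#' @param t Correlation threshold in (0, 1].
#' @return An `edge_list` (possibly empty), deterministically ordered.
#' @export
threshold_from_matrix <- function(X, t, ranking = c("abs", "signed"),
                                  method = c("pearson", "spearman", "phi")) {
  ranking <- match.arg(ranking)
  method <- match.arg(method)
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 1)
    stop_("threshold t must lie in (0, 1]")
  X <- as_feature_matrix(X)
  C <- full_correlation_matrix(X, method)
  df <- upper_pairs(C$values)
  df <- df[ranking_key(df$value, ranking) >= t, , drop = FALSE]
  new_edge_list(sort_edges(df, ranking), X$feature_names, ranking,
                "correlation")
}

#' Number of unordered feature pairs
#'
#' @param n Feature count (non-negative).
#' @return n (n - 1) / 2.
#' @examples
#' count_pairs(1000)
#' @export
count_pairs <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop_("n must be a single non-negative number")
  n * (n - 1) / 2
}

#' Memory footprint of a dense full correlation matrix
#'
#' Rough estimate assuming 64-bit floats: 64 n^2 / (8 x 10^9) gigabytes
#' (decimal GB, not GiB).  Useful for deciding when to switch from the
#' matrix backend to index-based top-k search.
#'
#' @param n Feature count.
#' @return Estimated size in GB.
#' @examples
#' estimate_full_matrix_memory_gb(32000)
#' @export
estimate_full_matrix_memory_gb <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop_("n must be a single non-negative number")
  64 * n^2 / (8e9)
}
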