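#' Correlation-preserving feature coordinates for Euclidean embedders
#'
#' Returns the projected feature vectors as m-dimensional coordinates (one
#' row per feature).  Pairwise Euclidean distances between coordinates
#' equal sqrt(2 (1 - r)), so any distance-based embedding method (t-SNE,
#' UMAP, MDS) applied to them reflects correlation structure directly: no
#' custom metric support is needed.  Note that negatively correlated
#' features map to LARGE distances by design.
#'
#' @inheritParams project_correlation
#' @return Numeric matrix, n features x m coordinates, rownames set to
#'   feature names.
#' @export
correlation_embedding_coordinates <- function(X,
                                              method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  P <- project_correlation(X, method)
  coords <- t(P$values)
  rownames(coords) <- X$feature_names
  coords
}

#' Precomputed correlation-distance matrix
#'
#' Materializes the n-by-n matrix of distances sqrt(2 (1 - r_ij)) for
#' embedders that accept precomputed distances.  It is a true Euclidean
#' distance (triangle inequality holds), bounded in \[0, 2\], zero on the
#' diagonal.  Guarded by a memory cap since it is quadratic in n.
#'
#' @inheritParams project_correlation
#' @param max_gb Refuse to allocate if the estimated dense-matrix size
#'   exceeds this many GB.
#' @return Symmetric numeric n x n matrix.
#' @export
correlation_distance_matrix <- function(X,
                                        method = c("pearson", "spearman", "phi"),
                                        max_gb = 2) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  est <- estimate_full_matrix_memory_gb(ncol(X$values))
  if (est > max_gb)
    stop_(sprintf(
      "distance matrix would need ~%.1f GB (> max_gb = %g); use the index backend",
      est, max_gb))
  C <- full_correlation_matrix(X, method)
  D <- sqrt(2 * (1 - C$values))
  diag(D) <- 0
  D
}
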