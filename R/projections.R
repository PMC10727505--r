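#' Project features onto correlation-preserving unit vectors
#'
#' Each feature column x is transformed to (x - mean(x)) / ||x - mean(x)||.
#' The scalar product of two projected columns then equals their Pearson
#' correlation, and the Euclidean distance between them is order-equivalent
#' to correlation via d = sqrt(2 (1 - r)).  Spearman correlations are
#' obtained by ranking each column first; the Phi coefficient for binary
#' variables is the Pearson formula applied to 0/1 columns.
#'
#' @param X A [feature_matrix()] (or coercible matrix) with at least 2
#'   samples.
#' @param method Coefficient class: `"pearson"`, `"spearman"` (ranks are
#'   taken internally), or `"phi"` (columns must contain only 0/1 values).
#' @return A `projected_matrix` with unit-norm, zero-mean columns.
#' @examples
#' P <- project_correlation(feature_matrix(matrix(rnorm(30), 10, 3)))
#' colSums(P$values^2)  # all 1
#' @export
project_correlation <- function(X, method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  check_min_samples(X)
  V <- X$values
  if (method == "spearman") {
    V <- rank_transform(X)$values
  } else if (method == "phi") {
    ok <- apply(V, 2L, function(col) all(col %in% c(0, 1)))
    if (!all(ok))
      stop_("method = \"phi\" requires 0/1 encoded columns; offending: ",
            paste(head(X$feature_names[!ok], 5L), collapse = ", "))
  }
  centered <- sweep(V, 2L, colMeans(V), "-")
  norms <- sqrt(colSums(centered^2))
  zero <- norms == 0
  if (any(zero))
    stop_("constant feature(s): ",
          paste(head(X$feature_names[zero], 5L), collapse = ", "),
          "; remove them first, e.g. with preprocess_features()")
  projected <- sweep(centered, 2L, norms, "/")
  structure(
    list(values = projected, method = method,
         feature_names = X$feature_names),
    class = "projected_matrix")
}

#' @export
print.projected_matrix <- function(x, ...) {
  cat(sprintf("<projected_matrix> %d x %d (%s)\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Convert between correlations and Euclidean distances of projections
#'
#' For projected (unit-norm, mean-centered) feature vectors the mapping
#' d = sqrt(2 (1 - r)) is an exact, order-reversing bijection between
#' correlations r in \[-1, 1\] and distances d in \[0, 2\];
#' `distance_to_corr()` is its inverse r = 1 - d^2 / 2.
#'
#' @param r Correlations in \[-1, 1\].
#' @param d Distances in \[0, 2\].
#' @return The converted vector.
#' @examples
#' corr_to_distance(c(-1, 0, 1))
#' distance_to_corr(corr_to_distance(0.8))
#' @export
corr_to_distance <- function(r) {
  check_range(r, -1, 1, "correlation")
  sqrt(2 * (1 - clip_range(r, -1, 1)))
}

#' @rdname corr_to_distance
#' @export
distance_to_corr <- function(d) {
  check_range(d, 0, 2, "distance")
  clip_range(1 - d^2 / 2, -1, 1)
}

#' Convert between correlation differences and differential-space distances
#'
#' In differential space the scalar product of the paired representations
#' equals the correlation difference g = cor1 - cor2 in \[-2, 2\], and
#' distances obey g = 2 - d^2 / 2 with d in \[0, 2 sqrt(2)\].
#'
#' @param g Correlation differences in \[-2, 2\].
#' @param d Distances in \[0, 2 sqrt(2)\].
#' @return The converted vector.
#' @examples
#' diff_to_distance(c(-2, 0, 2))
#' @export
diff_to_distance <- function(g) {
  check_range(g, -2, 2, "correlation difference")
  sqrt(2 * (2 - clip_range(g, -2, 2)))
}

#' @rdname diff_to_distance
#' @export
distance_to_diff <- function(d) {
  check_range(d, 0, 2 * sqrt(2), "distance")
  clip_range(2 - d^2 / 2, -2, 2)
}

check_range <- function(x, lo, hi, what, tol = 1e-9) {
  if (!is.numeric(x)) stop_(what, " must be numeric")
  if (any(x < lo - tol | x > hi + tol, na.rm = TRUE))
    stop_(sprintf("%s out of range [%g, %g]", what, lo, hi))
  invisible(x)
}

#' Paired differential-space representation of two conditions
#'
#' Builds, for every feature, the pair of vectors delta = (x1_hat, x2_hat)
#' and kappa = (y1_hat, -y2_hat) of length m1 + m2 such that the scalar
#' product `<delta(x), kappa(y)>` equals cor(x1, y1) - cor(x2, y2): one dot
#' product per feature pair recovers the correlation difference across the
#' two conditions.
#'
#' @param X1,X2 Two [feature_matrix()] objects over the same features in
#'   the same order (sample counts may differ).
#' @inheritParams project_correlation
#' @return A `differential_representation` with matrices `delta` and
#'   `kappa` (columns have norm sqrt(2)), plus `m1`, `m2`.
#' @examples
#' X1 <- feature_matrix(matrix(rnorm(24), 6, 4))
#' X2 <- feature_matrix(matrix(rnorm(20), 5, 4))
#' D <- project_differential(X1, X2)
#' colSums(D$delta^2)  # all 2
#' @export
project_differential <- function(X1, X2,
                                 method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  X1 <- as_feature_matrix(X1)
  X2 <- as_feature_matrix(X2)
  if (!identical(X1$feature_names, X2$feature_names))
    stop_("the two conditions must share identical feature names in order")
  P1 <- project_correlation(X1, method)
  P2 <- project_correlation(X2, method)
  structure(
    list(delta = rbind(P1$values, P2$values),
         kappa = rbind(P1$values, -P2$values),
         m1 = nrow(P1$values), m2 = nrow(P2$values),
         method = method, feature_names = X1$feature_names),
    class = "differential_representation")
}

#' @export
print.differential_representation <- function(x, ...) {
  cat(sprintf(
    "<differential_representation> %d features, m1 = %d, m2 = %d (%s)\n",
    length(x$feature_names), x$m1, x$m2, x$method))
  invisible(x)
}
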