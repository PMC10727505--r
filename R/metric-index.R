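#' Build a joint ball-tree index over positive and negative projections
#'
#' Indexes the 2n points \{x_hat, -x_hat\} for all n projected features in a
#' single exact ball tree.  Because cor(-x, y) = -cor(x, y), a nearest
#' neighbor among the joined points captures the strongest correlation of
#' either sign: a match on a negated point at distance d corresponds to a
#' correlation of -(1 - d^2 / 2).  k-NN and radius queries against the
#' index are exact; any approximation happens only in how many candidates
#' are requested per query.
#'
#' @param P A `projected_matrix` from [project_correlation()].
#' @param leaf_size Ball-tree leaf size (performance knob only).
#' @return A `metric_index` holding the compiled tree, the point matrix,
#'   and per-point `(feature_id, sign)` origins.
#' @export
build_joint_index <- function(P, leaf_size = 40L) {
  stopifnot(inherits(P, "projected_matrix"))
  build_index_points(P$values, P$feature_names, P$method, leaf_size)
}

# Shared by correlation search (points = projections) and differential
# search (points = delta vectors).
build_index_points <- function(V, feature_names, method, leaf_size = 40L) {
  n <- ncol(V)
  if (n == 0L) stop_("cannot build an index over zero features")
  pts <- t(cbind(V, -V))  # 2n x m, rows are points
  structure(
    list(ptr = bt_build(pts, as.integer(leaf_size)),
         points = pts,
         feature_id = rep.int(seq_len(n), 2L),
         sign = rep(c(1, -1), each = n),
         n_features = n, dim = ncol(pts),
         feature_names = feature_names, method = method),
    class = "metric_index")
}

#' @export
print.metric_index <- function(x, ...) {
  cat(sprintf("<metric_index> %d points (2 x %d features), dim %d\n",
              2L * x$n_features, x$n_features, x$dim))
  invisible(x)
}

# The external pointer does not survive serialization; rebuild lazily.
index_ptr <- function(index) {
  p <- index$ptr
  if (!is.null(p) && !is_null_xptr(p)) return(p)
  bt_build(index$points, 40L)
}

is_null_xptr <- function(p) {
  tryCatch(bt_size(p) < 1L, error = function(e) TRUE)
}

#' Query the k nearest indexed points for each query vector
#'
#' @param index A `metric_index`.
#' @param queries Matrix with queries in rows (dimension must match the
#'   index).
#' @param k Neighbors per query (1..2n).
#' @return List with integer matrix `idx` (point ids) and numeric matrix
#'   `dist`, both `nrow(queries) x k`, each row ascending by
#'   (distance, point id).
#' @export
index_knn <- function(index, queries, k) {
  stopifnot(inherits(index, "metric_index"))
  queries <- as.matrix(queries)
  bt_knn(index_ptr(index), queries, as.integer(k))
}

#' Query all indexed points within a Euclidean radius of each query
#'
#' @inheritParams index_knn
#' @param r Non-negative radius (inclusive).
#' @return List with `lengths` (results per query) and flat vectors `idx`,
#'   `dist` concatenated over queries.
#' @export
index_radius <- function(index, queries, r) {
  stopifnot(inherits(index, "metric_index"))
  queries <- as.matrix(queries)
  bt_radius(index_ptr(index), queries, r)
}
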