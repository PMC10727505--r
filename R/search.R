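#' Search configuration for index-backed correlation discovery
#'
#' @param approximation_factor Approximation factor `a >= 1`.  Each query
#'   feature retrieves `k' = ceiling(a k / n)` candidate neighbors (capped
#'   at 2n); larger values trade runtime for sensitivity, and any `a` with
#'   `k' >= 2n` makes the search exhaustive (exact).  Default 10, a
#'   conservative setting: in practice observed sensitivity is far above
#'   worst-case bounds.
#' @param batch_size Query features per batch; affects memory and
#'   parallel granularity only, never results.
#' @param n_workers Parallel workers (forked; >1 requires a Unix-alike,
#'   otherwise falls back to serial).  Results are worker-count invariant.
#' @param ranking `"abs"` or `"signed"` ranking key.
#' @param symmetrize Emit both orientations of each edge.
#' @param seed Optional integer recorded for provenance (the search itself
#'   is deterministic).
#' @param low_memory Spill per-batch results to temporary files and merge
#'   from disk; identical results.
#' @param dual_tree Accepted performance hint for dual-tree traversal; the
#'   current implementation uses the same exact single-tree search path
#'   either way, so results are identical by construction.
#' @return A `search_config` list.
#' @export
search_config <- function(approximation_factor = 10, batch_size = 512L,
                          n_workers = 1L,
                          ranking = c("abs", "signed"),
                          symmetrize = FALSE, seed = NULL,
                          low_memory = FALSE, dual_tree = FALSE) {
  ranking <- match.arg(ranking)
  if (!is.numeric(approximation_factor) || approximation_factor < 1)
    stop_("approximation_factor must be >= 1")
  if (batch_size < 1L) stop_("batch_size must be positive")
  if (n_workers < 1L) stop_("n_workers must be positive")
  structure(list(approximation_factor = approximation_factor,
                 batch_size = as.integer(batch_size),
                 n_workers = as.integer(n_workers), ranking = ranking,
                 symmetrize = isTRUE(symmetrize), seed = seed,
                 low_memory = isTRUE(low_memory),
                 dual_tree = isTRUE(dual_tree)),
            class = "search_config")
}

resolve_kprime <- function(a, k, n) {
  min(2L * n, as.integer(ceiling(a * k / n)))
}

# Run `fun` over query batches, serially or via forked workers, optionally
# spilling batch results to disk; batch order (hence output) is preserved.
run_batches <- function(batch_list, fun, config) {
  runner <- function(b) fun(b)
  if (config$low_memory) {
    dir <- tempfile("topcorr-batches-")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    spill <- function(b) {
      f <- tempfile(tmpdir = dir, fileext = ".rds")
      saveRDS(fun(b), f)
      f
    }
    files <- if (config$n_workers > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(batch_list, spill, mc.cores = config$n_workers)
    } else {
      lapply(batch_list, spill)
    }
    return(lapply(files, readRDS))
  }
  if (config$n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(batch_list, runner, mc.cores = config$n_workers)
  } else {
    lapply(batch_list, runner)
  }
}

split_batches <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

# Assemble canonical candidate edges from a k-NN result against a joint
# +/- index.  `queries` are feature ids, `scale` is 1 for correlations and
# 2 for correlation differences (value = sign * (scale - d^2 / 2)).
knn_to_edges <- function(res, queries, index, kprime, scale = 1) {
  nq <- length(queries)
  kret <- ncol(res$idx)
  q <- rep.int(queries, kret)               # column-major: rank-major blocks
  fid <- index$feature_id[as.vector(res$idx)]
  sgn <- index$sign[as.vector(res$idx)]
  d <- as.vector(res$dist)
  keep <- fid != q
  dt <- data.table::data.table(q = q[keep], fid = fid[keep],
                               sgn = sgn[keep], d = d[keep])
  # rows arrive rank-major but rowid counts occurrences per query in rank
  # order, so this keeps each query's kprime nearest non-self candidates
  dt <- dt[data.table::rowidv(dt, "q") <= kprime]
  lim <- c(-scale, scale)
  dt[, `:=`(i = pmin(q, fid), j = pmax(q, fid),
            value = clip_range(sgn * (scale - d^2 / 2), lim[1L], lim[2L]))]
  dt[, c("i", "j", "value"), with = FALSE]
}

radius_to_edges <- function(res, queries, index, scale = 1, signs = c(1, -1)) {
  q <- rep.int(queries, res$lengths)
  fid <- index$feature_id[res$idx]
  sgn <- index$sign[res$idx]
  d <- res$dist
  keep <- fid != q & sgn %in% signs
  dt <- data.table::data.table(q = q[keep], fid = fid[keep], sgn = sgn[keep],
                               d = d[keep])
  lim <- c(-scale, scale)
  dt[, `:=`(i = pmin(q, fid), j = pmax(q, fid),
            value = clip_range(sgn * (scale - d^2 / 2), lim[1L], lim[2L]))]
  dt[, c("i", "j", "value"), with = FALSE]
}

#' Approximate global top-k correlation search (index backend)
#'
#' Projects the features, builds the joint +/- ball-tree index and, for
#' every feature as a query, retrieves its `k' = ceiling(a k / n)` nearest
#' candidates; self-matches are discarded, pairs canonicalized and
#' deduplicated, and all batches merged into the global top-k by the
#' ranking key.  Never materializes the n-by-n correlation matrix: peak
#' additional storage is O(n k' + k) edge records.  With `a` large enough
#' that `k' >= 2n` the result is exact and identical to
#' [topk_from_matrix()].
#'
#' @inheritParams topk_from_matrix
#' @param config A [search_config()].
#' @return An `edge_list` of `k` rows (fewer, with a warning and the
#'   `incomplete` attribute, if the candidate pool is smaller than `k`).
#' @examples
#' X <- generate_block_correlated(20, 30, block_sizes = 4, rho = 0.9,
#'                                seed = 1)$matrix
#' topk_correlation_search(X, k = 6)
#' @export
topk_correlation_search <- function(X, k, config = search_config(),
                                    method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  n <- ncol(X$values)
  npairs <- count_pairs(n)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > npairs)
    stop_(sprintf("k must be in [1, %d]", npairs))
  k <- as.integer(round(k))
  P <- project_correlation(X, method)
  index <- build_joint_index(P)
  kprime <- resolve_kprime(config$approximation_factor, k, n)
  # request two extra neighbors so a query's own +/- points (always present
  # at distances 0 and 2) do not eat into its kprime candidates
  kret <- min(2L * n, kprime + 2L)
  queries_mat <- t(P$values)
  batches <- split_batches(n, config$batch_size)
  partials <- run_batches(batches, function(b) {
    res <- index_knn(index, queries_mat[b, , drop = FALSE], kret)
    knn_to_edges(res, b, index, kprime, scale = 1)
  }, config)
  edges <- merge_batch_results(partials, k, config$ranking,
                               X$feature_names, "correlation")
  log_search("topk", X, method, config,
             k = k, kprime = kprime, n_batches = length(batches))
  if (config$symmetrize) symmetrize(edges) else edges
}

#' Exact thresholded correlation search via radius queries
#'
#' Converts the correlation threshold `t` into the Euclidean radius
#' sqrt(2 (1 - t)) and issues one radius query per feature against the
#' joint index.  Radius queries are exact, so (unlike top-k search) the
#' result involves no approximation: it equals [threshold_from_matrix()]
#' while never allocating the full correlation matrix.  Under
#' `ranking = "signed"` only positive-sign matches (correlations >= t) are
#' kept.
#'
#' @inheritParams topk_correlation_search
#' @param t Correlation threshold in (0, 1].
#' @return An `edge_list`, deterministically ordered.
#' @export
threshold_correlation_search <- function(X, t, config = search_config(),
                                         method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 1)
    stop_("threshold t must lie in (0, 1]")
  X <- as_feature_matrix(X)
  n <- ncol(X$values)
  P <- project_correlation(X, method)
  index <- build_joint_index(P)
  radius <- corr_to_distance(t)
  signs <- if (config$ranking == "signed") 1 else c(1, -1)
  queries_mat <- t(P$values)
  batches <- split_batches(n, config$batch_size)
  partials <- run_batches(batches, function(b) {
    res <- index_radius(index, queries_mat[b, , drop = FALSE], radius)
    radius_to_edges(res, b, index, scale = 1, signs = signs)
  }, config)
  combined <- data.table::rbindlist(partials)
  if (nrow(combined)) combined <- combined[!duplicated(combined, by = c("i", "j"))]
  df <- sort_edges(as.data.frame(combined), config$ranking)
  edges <- new_edge_list(df, X$feature_names, config$ranking, "correlation")
  log_search("threshold", X, method, config, threshold = t,
             n_batches = length(batches))
  if (config$symmetrize) symmetrize(edges) else edges
}

#' Measure search sensitivity across approximation factors
#'
#' Empirical stand-in for a closed-form sensitivity/approximation-factor
#' relation: for each factor in `a_grid`, runs the index-backed top-k
#' search and reports the fraction of the exact top-k (from the matrix
#' oracle) that it recovers.  Sensitivity is non-decreasing in `a` and
#' reaches 1 once `k' >= 2n`.
#'
#' @inheritParams topk_correlation_search
#' @param a_grid Numeric vector of approximation factors (each >= 1).
#' @return A data frame with columns `a`, `kprime`, `sensitivity`.
#' @export
empirical_sensitivity <- function(X, k, a_grid = c(1, 2, 5, 10, 20),
                                  config = search_config(),
                                  method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  n <- ncol(X$values)
  exact <- topk_from_matrix(X, k, config$ranking, method)
  exact_keys <- paste(exact$i, exact$j)
  rows <- lapply(a_grid, function(a) {
    cfg <- config
    cfg$approximation_factor <- a
    approx <- suppressWarnings(topk_correlation_search(X, k, cfg, method))
    data.frame(a = a, kprime = resolve_kprime(a, k, n),
               sensitivity = length(intersect(paste(approx$i, approx$j),
                                              exact_keys)) / k)
  })
  do.call(rbind, rows)
}

log_search <- function(task, X, method, config, ...) {
  extras <- list(...)
  msg <- sprintf(
    "[topcorr] %s: n = %d, m = %d, method = %s, ranking = %s, a = %g, workers = %d%s",
    task, ncol(X$values), nrow(X$values), method, config$ranking,
    config$approximation_factor, config$n_workers,
    if (length(extras))
      paste0(", ", paste(names(extras), unlist(extras), sep = " = ",
                         collapse = ", "))
    else "")
  if (isTRUE(getOption("topcorr.verbose", FALSE))) message(msg)
  invisible(msg)
}
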