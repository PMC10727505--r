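#' Exact full differential-correlation matrix
#'
#' Computes the two per-condition correlation matrices and subtracts them:
#' entry (i, j) is cor(X1_i, X1_j) - cor(X2_i, X2_j), the change in
#' correlation from condition 1 to condition 2.  Equals the Gram-style
#' product of the differential-space representations delta and kappa.
#'
#' @inheritParams project_differential
#' @return A `correlation_matrix`-shaped object with values in \[-2, 2\],
#'   symmetric with a zero diagonal, `method` tagged `"difference"`.
#' @export
full_differential_matrix <- function(X1, X2,
                                     method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  C1 <- full_correlation_matrix(X1, method)
  C2 <- full_correlation_matrix(X2, method)
  if (!identical(C1$feature_names, C2$feature_names))
    stop_("the two conditions must share identical feature names in order")
  structure(list(values = C1$values - C2$values,
                 feature_names = C1$feature_names,
                 method = paste0(method, "-difference")),
            class = "correlation_matrix")
}

#' Approximate top-k differential correlation search
#'
#' Builds the joint ball tree over the delta representations and their
#' negations and queries it with the kappa representations, so each query
#' distance d encodes a correlation difference g = sign (2 - d^2 / 2).
#' All other contracts (approximation factor, self-match removal,
#' canonicalization, batch merge, deterministic ordering) are identical to
#' [topk_correlation_search()]; ranking is by absolute difference by
#' default.
#'
#' @inheritParams project_differential
#' @inheritParams topk_correlation_search
#' @return An `edge_list` whose `value` column holds correlation
#'   differences in \[-2, 2\].
#' @export
topk_differential_search <- function(X1, X2, k, config = search_config(),
                                     method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  X1 <- as_feature_matrix(X1)
  X2 <- as_feature_matrix(X2)
  D <- project_differential(X1, X2, method)
  n <- length(D$feature_names)
  npairs <- count_pairs(n)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > npairs)
    stop_(sprintf("k must be in [1, %d]", npairs))
  k <- as.integer(round(k))
  index <- build_index_points(D$delta, D$feature_names, method)
  kprime <- resolve_kprime(config$approximation_factor, k, n)
  kret <- min(2L * n, kprime + 2L)
  queries_mat <- t(D$kappa)
  batches <- split_batches(n, config$batch_size)
  partials <- run_batches(batches, function(b) {
    res <- index_knn(index, queries_mat[b, , drop = FALSE], kret)
    # norm contract: ||delta|| = ||kappa|| = sqrt(2) bounds d by 2 sqrt(2)
    stopifnot(all(res$dist <= 2 * sqrt(2) + 1e-8))
    knn_to_edges(res, b, index, kprime, scale = 2)
  }, config)
  edges <- merge_batch_results(partials, k, config$ranking,
                               D$feature_names, "difference")
  log_search("diff-topk", X1, method, config,
             k = k, kprime = kprime, n_batches = length(batches))
  if (config$symmetrize) symmetrize(edges) else edges
}

#' Bootstrap selection frequencies for differential edges
#'
#' Thin robustness wrapper: repeats [topk_differential_search()] over `b`
#' bootstrap resamples of the samples within each condition and reports,
#' for every edge selected in any replicate, the fraction of replicates in
#' which it appeared.  With `b = 0` (the default) resampling is off and
#' the plain search result is returned.
#'
#' @inheritParams topk_differential_search
#' @param b Number of bootstrap replicates (0 disables resampling).
#' @param seed Integer seed governing the resampling.
#' @return For `b = 0` an `edge_list`; otherwise a data frame with
#'   columns `feature_i`, `feature_j`, `frequency`, sorted by descending
#'   frequency.
#' @export
differential_bootstrap <- function(X1, X2, k, b = 0L,
                                   config = search_config(), seed = 1L,
                                   method = c("pearson", "spearman", "phi")) {
  method <- match.arg(method)
  if (b == 0L) return(topk_differential_search(X1, X2, k, config, method))
  X1 <- as_feature_matrix(X1)
  X2 <- as_feature_matrix(X2)
  tallies <- with_seed(seed, {
    lapply(seq_len(b), function(rep) {
      idx1 <- sample.int(nrow(X1$values), replace = TRUE)
      idx2 <- sample.int(nrow(X2$values), replace = TRUE)
      B1 <- feature_matrix(X1$values[idx1, , drop = FALSE], X1$feature_names)
      B2 <- feature_matrix(X2$values[idx2, , drop = FALSE], X2$feature_names)
      e <- suppressWarnings(
        topk_differential_search(B1, B2, k, config, method))
      paste(e$feature_i, e$feature_j, sep = "\t")
    })
  })
  tab <- sort(table(unlist(tallies)), decreasing = TRUE) / b
  parts <- do.call(rbind, strsplit(names(tab), "\t", fixed = TRUE))
  data.frame(feature_i = parts[, 1L], feature_j = parts[, 2L],
             frequency = as.numeric(tab), row.names = NULL)
}
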