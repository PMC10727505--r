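# Edge lists: canonical (i < j) feature-pair records carrying correlations
# or correlation differences, with a fully deterministic ordering so that
# results are byte-identical across backends, batch sizes and worker counts.

ranking_key <- function(value, ranking) {
  switch(ranking, abs = abs(value), signed = value,
         stop_("unknown ranking: ", ranking))
}

new_edge_list <- function(df, feature_names, ranking = "abs",
                          kind = "correlation", incomplete = FALSE) {
  df <- as.data.frame(df)[, intersect(c("i", "j", "value", "p", "p_adj"),
                                      names(df)), drop = FALSE]
  df$feature_i <- feature_names[df$i]
  df$feature_j <- feature_names[df$j]
  front <- c("feature_i", "feature_j", "value")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("edge_list", "data.frame"),
            ranking = ranking, kind = kind, incomplete = incomplete)
}

# Deterministic order: descending ranking key, ties broken by ascending
# (i, j).  Shared by all backends.
sort_edges <- function(df, ranking) {
  df[order(-ranking_key(df$value, ranking), df$i, df$j), , drop = FALSE]
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("<edge_list> %d edges (%s, ranking = %s)%s\n",
              nrow(x), attr(x, "kind"), attr(x, "ranking"),
              if (isTRUE(attr(x, "incomplete"))) " [incomplete]" else ""))
  print(as.data.frame(head(x, 10L)))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Merge per-batch candidate edges into the global top-k
#'
#' Reduction step of the project/batch/reduce pipeline: concatenates batch
#' results, drops duplicate pairs (keeping the first occurrence; values of
#' duplicates are identical by symmetry of the search), partitions to the
#' top `k` by the ranking key and applies the deterministic ordering.  The
#' output is invariant to how queries were split into batches.
#'
#' @param partials List of data frames with columns `i`, `j`, `value`
#'   (canonical `i < j`), all produced under the same ranking key.
#' @param k Number of edges to retain.  If fewer unique pairs are
#'   available, all are returned and the result is flagged via
#'   `attr(, "incomplete")` with a warning.
#' @param ranking `"abs"` (rank by absolute value) or `"signed"`.
#' @param feature_names Feature names used to label the pairs.
#' @param kind Value semantics, `"correlation"` or `"difference"`.
#' @return An `edge_list` data frame.
#' @export
merge_batch_results <- function(partials, k, ranking = "abs",
                                feature_names = NULL, kind = "correlation") {
  stopifnot(is.list(partials))
  combined <- data.table::rbindlist(partials, use.names = TRUE)
  if (nrow(combined)) {
    combined <- combined[!duplicated(combined, by = c("i", "j"))]
  }
  df <- as.data.frame(combined)
  df <- sort_edges(df, ranking)
  incomplete <- FALSE
  if (nrow(df) > k) {
    df <- df[seq_len(k), , drop = FALSE]
  } else if (nrow(df) < k) {
    incomplete <- TRUE
    warning(sprintf("only %d unique pairs available for k = %d",
                    nrow(df), k), call. = FALSE)
  }
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(max(df$j, 0)))
  new_edge_list(df, feature_names, ranking, kind, incomplete)
}

#' Emit both orientations of every edge
#'
#' Top-k search returns each unordered pair once, in canonical `i < j`
#' orientation; some downstream tools expect a symmetric adjacency-style
#' list.  This duplicates every record with its endpoints swapped and
#' re-applies the deterministic ordering (now over both orientations).
#'
#' @param edges An `edge_list`.
#' @return An `edge_list` with twice the records.
#' @export
symmetrize <- function(edges) {
  stopifnot(inherits(edges, "edge_list"))
  if (!nrow(edges)) return(edges)
  swapped <- edges
  swapped$i <- edges$j
  swapped$j <- edges$i
  swapped$feature_i <- edges$feature_j
  swapped$feature_j <- edges$feature_i
  out <- rbind(as.data.frame(edges), as.data.frame(swapped))
  out <- sort_edges(out, attr(edges, "ranking"))
  rownames(out) <- NULL
  structure(out, class = c("edge_list", "data.frame"),
            ranking = attr(edges, "ranking"), kind = attr(edges, "kind"),
            incomplete = attr(edges, "incomplete"), symmetrized = TRUE)
}
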