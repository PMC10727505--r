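# Single-cell functional coordination recipe: equalize cell-type sizes by
# dual bootstrapping, count which cell-type pairs carry the top-k
# cell-to-cell Spearman correlations over functional markers, and screen
# condition differences in those counts with Cliff's delta.

#' Dual bootstrap sampling of grouped cells
#'
#' Two-stage with-replacement resampling that equalizes group sizes while
#' preserving within-group variation: stage 1 draws n_g cells with
#' replacement from group g (n_g = cells available in g); stage 2 draws
#' `target_per_group` cells with replacement from that intermediate
#' sample.  Every group contributes exactly `target_per_group` rows.
#'
#' @param cells Cells-by-markers matrix or [feature_matrix()].
#' @param labels Group (cell-type) label per row.
#' @param target_per_group Cells to draw per group.
#' @param seed Integer seed.
#' @return List with `matrix` (resampled cells) and `labels`.
#' @export
dual_bootstrap_sample <- function(cells, labels, target_per_group, seed = 1L) {
  cells <- as_feature_matrix(cells)
  if (length(labels) != nrow(cells$values))
    stop_("labels must match the number of cells (rows)")
  groups <- split(seq_along(labels), labels)
  if (any(lengths(groups) == 0L)) stop_("empty group")
  with_seed(seed, {
    rows <- unlist(lapply(groups, function(idx) {
      stage1 <- idx[sample.int(length(idx), length(idx), replace = TRUE)]
      stage1[sample.int(length(stage1), target_per_group, replace = TRUE)]
    }), use.names = FALSE)
    list(matrix = feature_matrix(cells$values[rows, , drop = FALSE],
                                 cells$feature_names),
         labels = rep(names(groups), each = target_per_group))
  })
}

#' Count top-k cell-to-cell correlations per cell-type pair
#'
#' Treats each cell as a feature and its functional-marker values as the
#' samples, computes the top `k = round(k_fraction * pairs(n_cells))`
#' cell-to-cell correlations (Spearman by default), and tallies every
#' returned edge into the unordered pair of cell-type labels of its two
#' endpoints.  Counts over all label pairs (including within-type pairs)
#' sum to k.
#'
#' @param cells Cells-by-markers matrix or [feature_matrix()] (>= 3
#'   markers).
#' @param labels Cell-type label per row.
#' @param k_fraction Fraction of all cell pairs to keep, in (0, 1].
#' @param method Correlation coefficient class (default `"spearman"`).
#' @param config A [search_config()]; use a large approximation factor
#'   (or small data) when exact counts are required.
#' @return Data frame with columns `group_a`, `group_b` (`group_a <=
#'   group_b` lexicographically) and `count`, covering every unordered
#'   label pair.
#' @export
count_topk_group_pairs <- function(cells, labels, k_fraction = 1e-4,
                                   method = "spearman",
                                   config = search_config()) {
  cells <- as_feature_matrix(cells)
  if (ncol(cells$values) < 3L)
    stop_("at least 3 markers are required for rank correlations")
  if (k_fraction <= 0 || k_fraction > 1)
    stop_("k_fraction must lie in (0, 1]")
  n_cells <- nrow(cells$values)
  if (length(labels) != n_cells)
    stop_("labels must match the number of cells (rows)")
  # transpose: cells become the features being correlated, markers the
  # samples they are correlated over
  Xt <- feature_matrix(t(cells$values),
                       feature_names = paste0("cell", seq_len(n_cells)))
  k <- max(1L, as.integer(round(k_fraction * count_pairs(n_cells))))
  edges <- suppressWarnings(topk_correlation_search(Xt, k, config, method))
  ulabels <- sort(unique(labels))
  pair_grid <- expand.grid(a = seq_along(ulabels), b = seq_along(ulabels))
  pair_grid <- pair_grid[pair_grid$a <= pair_grid$b, ]
  la <- pmin(labels[edges$i], labels[edges$j])
  lb <- pmax(labels[edges$i], labels[edges$j])
  tallied <- table(factor(paste(la, lb, sep = "\r"),
                          levels = paste(ulabels[pair_grid$a],
                                         ulabels[pair_grid$b], sep = "\r")))
  out <- data.frame(group_a = ulabels[pair_grid$a],
                    group_b = ulabels[pair_grid$b],
                    count = as.integer(tallied), row.names = NULL)
  attr(out, "k") <- nrow(edges)
  out
}

#' Screen cell-type pairs for large count shifts between conditions
#'
#' For every cell-type pair, computes Cliff's delta of the condition-2
#' counts versus the condition-1 counts across replicates and keeps pairs
#' whose |delta| exceeds `threshold` (default 0.622, the conventional
#' "very large" effect-size cutoff).  Positive delta is labelled
#' `"increase"` (more top-k correlations in condition 2), negative
#' `"decrease"`.
#'
#' @param counts_condition1,counts_condition2 Replicate-by-pair count
#'   matrices with identical column names (one column per cell-type
#'   pair), e.g. stacked rows of [count_topk_group_pairs()] counts; at
#'   least 2 replicates each.
#' @param threshold Effect-size cutoff in (0, 1].
#' @return Data frame with `group_a`, `group_b`, `delta`, `direction` for
#'   the retained pairs, sorted by descending |delta|.
#' @export
effect_size_screen <- function(counts_condition1, counts_condition2,
                               threshold = 0.622) {
  c1 <- as.matrix(counts_condition1)
  c2 <- as.matrix(counts_condition2)
  if (nrow(c1) < 2L || nrow(c2) < 2L)
    stop_("at least 2 replicates per condition are required")
  if (!identical(colnames(c1), colnames(c2)))
    stop_("conditions must cover identical cell-type pairs")
  deltas <- vapply(seq_len(ncol(c1)),
                   function(p) cliffs_delta(c2[, p], c1[, p]), numeric(1))
  keep <- abs(deltas) > threshold
  pairs <- do.call(rbind, strsplit(colnames(c1)[keep], "\r", fixed = TRUE))
  if (!any(keep))
    return(data.frame(group_a = character(0), group_b = character(0),
                      delta = numeric(0), direction = character(0)))
  out <- data.frame(group_a = pairs[, 1L], group_b = pairs[, 2L],
                    delta = deltas[keep],
                    direction = ifelse(deltas[keep] > 0, "increase",
                                       "decrease"))
  out[order(-abs(out$delta)), , drop = FALSE]
}

#' Run the full coordination analysis across two conditions
#'
#' Convenience orchestration: for each of `n_replicates` replicates, draws
#' a dual-bootstrap sample from each condition, counts top-k cell-type
#' pair correlations, and finally screens the replicate count tables with
#' Cliff's delta.
#'
#' @param cells1,labels1 Condition-1 cells and labels.
#' @param cells2,labels2 Condition-2 cells and labels.
#' @param n_replicates Bootstrap replicates (the reference analysis uses
#'   1000; tests use far fewer).
#' @param target_per_group Cells drawn per type and replicate.
#' @param k_fraction Top fraction of cell pairs to count.
#' @param threshold Cliff's delta cutoff.
#' @param seed Integer seed.
#' @param config A [search_config()].
#' @return List with matrices `counts1`, `counts2` (replicate x pair) and
#'   the `screened` pair table.
#' @export
run_coordination <- function(cells1, labels1, cells2, labels2,
                             n_replicates = 50L, target_per_group = 100L,
                             k_fraction = 1e-4, threshold = 0.622,
                             seed = 1L, config = search_config()) {
  one_condition <- function(cells, labels, seed0) {
    reps <- lapply(seq_len(n_replicates), function(r) {
      s <- dual_bootstrap_sample(cells, labels, target_per_group,
                                 seed = seed0 + r)
      tab <- count_topk_group_pairs(s$matrix, s$labels, k_fraction,
                                    config = config)
      stats::setNames(tab$count, paste(tab$group_a, tab$group_b, sep = "\r"))
    })
    do.call(rbind, reps)
  }
  counts1 <- one_condition(cells1, labels1, seed)
  counts2 <- one_condition(cells2, labels2, seed + n_replicates)
  list(counts1 = counts1, counts2 = counts2,
       screened = effect_size_screen(counts1, counts2, threshold))
}
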