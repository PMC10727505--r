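#' P-value of a correlation coefficient via the t-distribution
#'
#' Under the null of no association, t = r sqrt(m - 2) / sqrt(1 - r^2)
#' follows a t-distribution with m - 2 degrees of freedom; the two-sided
#' p-value is 2 P(T > |t|).  |r| = 1 yields p = 0.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @param m Sample count used to compute `r` (>= 3).
#' @return Two-sided p-value(s) in \[0, 1\].
#' @examples
#' correlation_pvalue(0.5, 12)
#' @export
correlation_pvalue <- function(r, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 3)
    stop_("m must be a single sample count >= 3")
  check_range(r, -1, 1, "correlation")
  r <- clip_range(r, -1, 1)
  p <- numeric(length(r))
  degenerate <- abs(r) >= 1
  t_stat <- r[!degenerate] * sqrt(m - 2) / sqrt(1 - r[!degenerate]^2)
  p[!degenerate] <- 2 * pt(abs(t_stat), df = m - 2, lower.tail = FALSE)
  p[degenerate] <- 0
  pmin(p, 1)
}

#' Bonferroni adjustment over all feature pairs
#'
#' Controls the family-wise error rate by multiplying each p-value by the
#' number of compared correlation coefficients, (n^2 - n) / 2 for n
#' features, capped at 1.
#'
#' @param p P-value(s).
#' @param n_features Number of features whose pairwise correlations were
#'   tested (>= 2).
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, n_features) {
  if (!is.numeric(n_features) || length(n_features) != 1L || n_features < 2)
    stop_("n_features must be a single count >= 2")
  check_range(p, 0, 1, "p-value")
  pmin(1, p * count_pairs(n_features))
}

#' Truncated Benjamini-Hochberg adjustment for top-k p-values
#'
#' Standard BH step-up adjustment applied to only the `k` smallest
#' p-values out of `m_total` tests, computed as if the unobserved
#' p-values at ranks k+1..m_total were 1 but without materializing them:
#' `p_adj(i) = min(min_{i <= j <= k} m_total p_j / j, 1)`.  This is a
#' conservative upper bound on the full-distribution BH adjustment and
#' equals textbook BH exactly when `k = m_total`.
#'
#' The optional `u_replacement` step replaces adjusted values tied with
#' the k-th one by the bound `u = m_total / (k + 1)` when they exceed it;
#' it is off by default because its exact intent is interpretation
#' dependent (see the methods vignette).
#'
#' @param p_topk Ascending vector of the k smallest p-values.
#' @param m_total Total number of tests (>= k), e.g. (n^2 - n) / 2.
#' @param u_replacement Apply the tie-replacement micro-correction.
#' @return Adjusted p-values, same length/order as `p_topk`, monotone
#'   non-decreasing.
#' @examples
#' bh_truncated_adjust(c(0.01, 0.02, 0.03), 3)
#' @export
bh_truncated_adjust <- function(p_topk, m_total, u_replacement = FALSE) {
  check_range(p_topk, 0, 1, "p-value")
  k <- length(p_topk)
  if (k == 0L) return(numeric(0))
  if (is.unsorted(p_topk)) stop_("p_topk must be sorted ascending")
  if (!is.numeric(m_total) || length(m_total) != 1L || m_total < k)
    stop_("m_total must be a single count >= length(p_topk)")
  adj <- pmin(rev(cummin(rev(m_total * p_topk / seq_len(k)))), 1)
  if (u_replacement) {
    u <- m_total / (k + 1)
    if (adj[k] > u) adj[adj == adj[k]] <- u
  }
  adj
}

#' Cliff's delta effect size
#'
#' Nonparametric effect size: the difference between the probabilities
#' that a value drawn from `sample_a` exceeds, versus falls below, one
#' drawn from `sample_b`, i.e. (#\{a > b\} - #\{a < b\}) / (n_a n_b) over
#' all cross-pairs.  Ranges over \[-1, 1\]; 0 for identical distributions.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A single value in \[-1, 1\].
#' @examples
#' cliffs_delta(c(3, 4), c(1, 2))
#' @export
cliffs_delta <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop_("both samples must be non-empty")
  gt <- sum(vapply(sample_a, function(a) sum(a > sample_b), numeric(1)))
  lt <- sum(vapply(sample_a, function(a) sum(a < sample_b), numeric(1)))
  (gt - lt) / (length(sample_a) * length(sample_b))
}

#' Attach p-values and multiple-testing adjustment to an edge list
#'
#' Post-processing for correlation edge lists: computes the t-based
#' p-value for every edge and, optionally, a multiplicity adjustment over
#' all (n^2 - n)/2 implicit tests — Bonferroni, or the truncated BH
#' procedure treating the edge list as the top-k smallest p-values.
#'
#' @param edges An `edge_list` of correlations.
#' @param m Sample count the correlations were computed from.
#' @param n_features Total number of features searched over.
#' @param adjust `"none"`, `"bonferroni"`, or `"bh"` (truncated BH).
#' @return The edge list with columns `p` and (if adjusted) `p_adj`.
#' @export
add_edge_pvalues <- function(edges, m, n_features,
                             adjust = c("none", "bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(edges, "edge_list"))
  edges$p <- correlation_pvalue(edges$value, m)
  if (adjust == "bonferroni") {
    edges$p_adj <- bonferroni_adjust(edges$p, n_features)
  } else if (adjust == "bh") {
    m_total <- count_pairs(n_features)
    ord <- order(edges$p)
    adj <- bh_truncated_adjust(edges$p[ord], m_total)
    edges$p_adj <- adj[order(ord)]
  }
  edges
}
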