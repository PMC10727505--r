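# Independent oracles and fixture builders used across tests.  All oracles
# are deliberately naive (per-pair loops, exhaustive scans) and never share
# code with the package's computation paths.

random_fm <- function(m, n, seed) {
  set.seed(seed)
  feature_matrix(matrix(rnorm(m * n), m, n))
}

# Textbook per-pair Pearson correlation matrix via stats::cor on columns.
oracle_cor_matrix <- function(X, method = "pearson") {
  stats::cor(X$values, method = method)
}

# Exhaustive top-k over all pairs: full sort of the oracle matrix with the
# deterministic (-key, i, j) tie-break.
oracle_topk <- function(X, k, ranking = "abs", method = "pearson") {
  R <- oracle_cor_matrix(X, method)
  ut <- which(upper.tri(R))
  loc <- arrayInd(ut, dim(R))
  df <- data.frame(i = loc[, 1], j = loc[, 2], value = R[ut])
  key <- if (ranking == "abs") abs(df$value) else df$value
  df <- df[order(-key, df$i, df$j), ]
  rownames(df) <- NULL
  df[seq_len(k), , drop = FALSE]
}

oracle_threshold <- function(X, t, ranking = "abs", method = "pearson") {
  R <- oracle_cor_matrix(X, method)
  ut <- which(upper.tri(R))
  loc <- arrayInd(ut, dim(R))
  df <- data.frame(i = loc[, 1], j = loc[, 2], value = R[ut])
  key <- if (ranking == "abs") abs(df$value) else df$value
  df <- df[key >= t, , drop = FALSE]
  df <- df[order(-(if (ranking == "abs") abs(df$value) else df$value),
                 df$i, df$j), ]
  rownames(df) <- NULL
  df
}

# Brute-force Euclidean nearest neighbors over a point matrix (rows =
# points), tie-broken by ascending index.
oracle_knn <- function(points, query, k) {
  d <- sqrt(colSums((t(points) - as.numeric(query))^2))
  ord <- order(d, seq_along(d))[seq_len(k)]
  list(idx = ord, dist = d[ord])
}

edge_keys <- function(edges) paste(edges$i, edges$j)

expect_same_edges <- function(a, b, tol = 1e-10) {
  expect_identical(as.integer(a$i), as.integer(b$i))
  expect_identical(as.integer(a$j), as.integer(b$j))
  expect_lt(max(abs(a$value - b$value), 0), tol)
}
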