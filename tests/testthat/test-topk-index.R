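test_that("joint index contains 2n points and self-matches at distance 0", {
  X <- random_fm(8, 10, 41)
  P <- project_correlation(X)
  idx <- build_joint_index(P)
  expect_identical(nrow(idx$points), 20L)
  expect_identical(idx$feature_id, rep(1:10, 2))
  res <- index_knn(idx, t(P$values), 1)
  expect_identical(as.integer(res$idx[, 1]), 1:10)   # own +1 point first
  expect_lt(max(res$dist[, 1]), 1e-12)
})

test_that("ball-tree k-NN and radius queries equal brute-force scans", {
  X <- random_fm(8, 10, 42)
  P <- project_correlation(X)
  idx <- build_joint_index(P)
  queries <- t(P$values)
  for (k in c(1, 3, 20)) {
    res <- index_knn(idx, queries, k)
    for (q in 1:10) {
      bf <- oracle_knn(idx$points, queries[q, ], k)
      expect_identical(as.integer(res$idx[q, ]), as.integer(bf$idx))
      expect_lt(max(abs(res$dist[q, ] - bf$dist)), 1e-12)
    }
  }
  for (r in c(0.5, 1.2, 2.5)) {
    res <- index_radius(idx, queries, r)
    off <- c(0, cumsum(res$lengths))
    for (q in 1:10) {
      d <- sqrt(colSums((t(idx$points) - queries[q, ])^2))
      want <- order(d, seq_along(d))[sort(d) <= r]
      got <- res$idx[(off[q] + 1):off[q + 1]]
      if (length(want) == 0) expect_identical(res$lengths[q], 0L)
      else expect_identical(as.integer(got), as.integer(want))
    }
  }
})

test_that("exhaustive approximation factor reproduces the matrix backend", {
  for (seed in 1:8) {
    set.seed(seed + 100)
    n <- sample(5:40, 1); m <- sample(3:25, 1)
    X <- random_fm(m, n, seed + 200)
    k <- sample(count_pairs(n), 1)
    exact <- topk_from_matrix(X, k)
    approx <- topk_correlation_search(
      X, k, search_config(approximation_factor = 2 * n^2))
    expect_same_edges(exact, approx)
  }
})

test_that("planted block edges are recovered at moderate factors", {
  sim <- generate_block_correlated(20, 100, block_sizes = 5, rho = 0.95,
                                   noise_sd = 0.2, seed = 77)
  k <- nrow(sim$truth)  # the 10 within-block pairs; k' = ceil(10k/n) = 5
  got <- topk_correlation_search(sim$matrix, k,
                                 search_config(approximation_factor = 10))
  expect_setequal(edge_keys(got), paste(sim$truth$i, sim$truth$j))
})

test_that("threshold search is exact at every tested threshold", {
  X <- random_fm(6, 12, 43)
  for (t in c(0.3, 0.5, 0.8)) {
    expect_same_edges(threshold_correlation_search(X, t),
                      threshold_from_matrix(X, t))
  }
  expect_identical(nrow(threshold_correlation_search(X, 1)), 0L)
  # exact negation is found with value -1 at any threshold
  set.seed(44)
  v <- rnorm(9)
  Xn <- feature_matrix(cbind(matrix(rnorm(27), 9, 3), v, -v),
                       c(paste0("r", 1:3), "pos", "neg"))
  got <- threshold_correlation_search(Xn, 0.99)
  expect_identical(c(got$feature_i, got$feature_j), c("pos", "neg"))
  expect_equal(got$value, -1, tolerance = 1e-12)
  # signed ranking only returns the positive side
  expect_identical(nrow(threshold_correlation_search(
    Xn, 0.99, search_config(ranking = "signed"))), 0L)
})

test_that("merging is invariant to query partitioning and deduplicates", {
  X <- random_fm(9, 14, 45)
  cfgs <- lapply(c(1, 3, 14), function(b)
    search_config(batch_size = b, approximation_factor = 5))
  res <- lapply(cfgs, function(cfg) topk_correlation_search(X, 12, cfg))
  expect_identical(res[[1]], res[[2]])
  expect_identical(res[[2]], res[[3]])
  # explicit merge contract
  part <- data.frame(i = c(1L, 2L), j = c(2L, 3L), value = c(0.9, -0.5))
  merged <- merge_batch_results(list(part, part[1, ]), 2,
                                feature_names = paste0("f", 1:3))
  expect_identical(nrow(merged), 2L)
  expect_identical(anyDuplicated(edge_keys(merged)), 0L)
  expect_warning(
    short <- merge_batch_results(list(part), 5,
                                 feature_names = paste0("f", 1:3)),
    "unique pairs")
  expect_true(attr(short, "incomplete"))
  expect_identical(nrow(short), 2L)
})

test_that("worker count and low-memory spilling do not change results", {
  X <- random_fm(10, 30, 46)
  base <- topk_correlation_search(X, 25, search_config(batch_size = 7))
  for (cfg in list(search_config(batch_size = 7, n_workers = 4),
                   search_config(batch_size = 7, low_memory = TRUE))) {
    alt <- topk_correlation_search(X, 25, cfg)
    expect_identical(as.data.frame(base), as.data.frame(alt))
  }
})

test_that("symmetrize doubles records and preserves backend agreement", {
  empty <- threshold_correlation_search(random_fm(6, 5, 47), 1)
  expect_identical(nrow(symmetrize(empty)), 0L)
  X <- random_fm(8, 9, 48)
  one <- topk_from_matrix(X, 1)
  expect_identical(nrow(symmetrize(one)), 2L)
  sym_matrix <- symmetrize(topk_from_matrix(X, 6))
  sym_index <- symmetrize(topk_correlation_search(
    X, 6, search_config(approximation_factor = 1e6)))
  expect_identical(sym_matrix$i, sym_index$i)
  expect_identical(sym_matrix$j, sym_index$j)
  expect_lt(max(abs(sym_matrix$value - sym_index$value)), 1e-10)
})

test_that("empirical sensitivity is monotone and saturates", {
  sim <- generate_block_correlated(40, 30, c(5, 5), rho = 0.95,
                                   noise_sd = 0.2, seed = 7)
  tab <- empirical_sensitivity(sim$matrix, 20, c(1, 2, 5, 1e6))
  expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 1))
  expect_false(is.unsorted(tab$sensitivity))
  expect_equal(tab$sensitivity[nrow(tab)], 1)
  expect_identical(tab$kprime[nrow(tab)], 80L)  # capped at 2n
})

test_that("search validates its inputs", {
  X <- random_fm(6, 5, 49)
  expect_error(topk_correlation_search(X, 0), "k must be")
  expect_error(topk_correlation_search(X, 11), "k must be")
  expect_error(search_config(approximation_factor = 0.5),
               "approximation_factor")
  expect_error(topk_correlation_search(
    feature_matrix(cbind(a = rep(1, 5), b = rnorm(5))), 1),
    "constant")
})
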