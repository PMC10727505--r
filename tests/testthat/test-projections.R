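test_that("correlation projection matches the closed form", {
  P <- project_correlation(feature_matrix(cbind(a = c(1, 2, 3))))
  expect_equal(P$values[, 1], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("projected columns are unit-norm and mean-zero; Gram = Pearson", {
  for (seed in 1:5) {
    X <- random_fm(m = sample(3:40, 1), n = sample(2:50, 1), seed)
    P <- project_correlation(X)
    expect_lt(max(abs(colSums(P$values^2) - 1)), 1e-10)
    expect_lt(max(abs(colMeans(P$values))), 1e-10)
    expect_lt(max(abs(crossprod(P$values) - oracle_cor_matrix(X))), 1e-10)
  }
})

test_that("constant features are rejected with a useful message", {
  X <- feature_matrix(cbind(flat = c(5, 5, 5), ok = c(1, 2, 3)))
  expect_error(project_correlation(X), "constant feature")
  expect_error(project_correlation(X), "flat")
  expect_error(project_correlation(X), "preprocess_features")
})

test_that("rank transform uses average ranks and drives Spearman", {
  expect_equal(rank_transform(cbind(x = c(10, 20, 30)))$values[, 1],
               c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(rank_transform(cbind(x = c(1, 1, 2)))$values[, 1],
               c(1.5, 1.5, 3), ignore_attr = TRUE)
  # monotone invariance: spearman(x, x^3) = 1 for strictly increasing x
  X <- feature_matrix(cbind(a = 1:8, b = (1:8)^3))
  P <- project_correlation(X, "spearman")
  expect_equal(sum(P$values[, 1] * P$values[, 2]), 1, tolerance = 1e-12)
})

test_that("Spearman via ranks matches the rank-correlation oracle under ties", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- sample(5:30, 1)
    X <- feature_matrix(matrix(sample(1:4, m * 6, TRUE) + rnorm(m * 6, 0, 0.1),
                               m, 6))
    Xt <- feature_matrix(matrix(sample(1:3, m * 6, TRUE), m, 6))  # heavy ties
    for (M in list(X, Xt)) {
      skip_constant <- any(apply(M$values, 2, function(c) length(unique(c))) < 2)
      if (skip_constant) next
      P <- project_correlation(M, "spearman")
      expect_lt(max(abs(crossprod(P$values) -
                          oracle_cor_matrix(M, "spearman"))), 1e-10)
    }
  }
})

test_that("Phi on 0/1 columns equals the contingency-table formula", {
  set.seed(11)
  X <- feature_matrix(matrix(rbinom(40 * 4, 1, 0.5), 40, 4))
  P <- project_correlation(X, "phi")
  G <- crossprod(P$values)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- X$values[, i]; b <- X$values[, j]
    n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
    n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
    phi <- (n11 * n00 - n10 * n01) /
      sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
    expect_equal(G[i, j], phi, tolerance = 1e-10)
  }
  expect_error(project_correlation(feature_matrix(cbind(x = c(0, 1, 2))),
                                   "phi"), "0/1")
})

test_that("correlation/distance conversions are exact mutual inverses", {
  expect_equal(corr_to_distance(1), 0)
  expect_equal(corr_to_distance(-1), 2)
  expect_equal(corr_to_distance(0.8), sqrt(0.4), tolerance = 1e-12)
  r <- seq(-1, 1, by = 0.01)
  expect_equal(distance_to_corr(corr_to_distance(r)), r, tolerance = 1e-12)
  expect_error(corr_to_distance(1.5), "out of range")
  expect_error(distance_to_corr(2.5), "out of range")
})

test_that("difference/distance conversions are exact mutual inverses", {
  expect_equal(diff_to_distance(2), 0)
  expect_equal(diff_to_distance(0), 2)
  expect_equal(diff_to_distance(-2), 2 * sqrt(2), tolerance = 1e-12)
  g <- seq(-2, 2, by = 0.05)
  expect_equal(distance_to_diff(diff_to_distance(g)), g, tolerance = 1e-12)
  expect_error(diff_to_distance(2.1), "out of range")
  expect_error(distance_to_diff(3), "out of range")
})

test_that("differential representation encodes correlation differences", {
  set.seed(3)
  X1 <- random_fm(6, 4, 31)
  X2 <- random_fm(5, 4, 32)
  D <- project_differential(X1, X2)
  expect_lt(max(abs(colSums(D$delta^2) - 2)), 1e-10)
  expect_lt(max(abs(colSums(D$kappa^2) - 2)), 1e-10)
  expect_identical(D$delta[1:6, ], D$kappa[1:6, ])
  # brute-force oracle over all pairs
  R1 <- oracle_cor_matrix(X1); R2 <- oracle_cor_matrix(X2)
  expect_lt(max(abs(crossprod(D$delta, D$kappa) - (R1 - R2))), 1e-10)
  # identical conditions cancel
  Dz <- project_differential(X1, X1)
  expect_lt(max(abs(crossprod(Dz$delta, Dz$kappa))), 1e-10)
  expect_error(project_differential(
    X1, feature_matrix(X2$values, paste0("g", 1:4))), "feature names")
})

test_that("order equivalence and sign symmetry hold", {
  for (seed in 6:8) {
    X <- random_fm(10, 12, seed)
    P <- project_correlation(X)
    R <- crossprod(P$values)
    # random triples: higher correlation <=> smaller distance
    set.seed(seed)
    for (rep in 1:20) {
      tri <- sample(12, 3)
      d_xy <- sqrt(sum((P$values[, tri[1]] - P$values[, tri[2]])^2))
      d_xz <- sqrt(sum((P$values[, tri[1]] - P$values[, tri[3]])^2))
      expect_identical(R[tri[1], tri[2]] > R[tri[1], tri[3]], d_xy < d_xz)
    }
    expect_identical(crossprod(-P$values[, 1], P$values[, 2]),
                     -crossprod(P$values[, 1], P$values[, 2]))
  }
})
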