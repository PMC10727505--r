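test_that("dual bootstrap equalizes group sizes with replacement", {
  sim <- generate_celllike(3, 40, 8, seed = 101)
  s <- dual_bootstrap_sample(sim$matrix, sim$labels, 25, seed = 5)
  expect_identical(nrow(s$matrix$values), 75L)
  expect_identical(as.vector(table(s$labels)), rep(25L, 3))
  expect_identical(s, dual_bootstrap_sample(sim$matrix, sim$labels, 25,
                                            seed = 5))
  # a tiny group is upsampled to the target
  small <- dual_bootstrap_sample(sim$matrix[["values"]][1:45, ],
                                 rep(c("a", "b"), c(40, 5)), 30, seed = 6)
  expect_identical(as.vector(table(small$labels)), rep(30L, 2))
  expect_error(dual_bootstrap_sample(sim$matrix, sim$labels[-1], 10),
               "labels")
})

test_that("top-k group-pair counts are conserved and match brute force", {
  sim <- generate_celllike(3, 20, 10, group_effect = 1.5, seed = 102)
  cfg <- search_config(approximation_factor = 1e6)
  tab <- count_topk_group_pairs(sim$matrix, sim$labels, k_fraction = 0.02,
                                config = cfg)
  n_cells <- 60
  k <- round(0.02 * count_pairs(n_cells))
  expect_identical(sum(tab$count), as.integer(k))
  expect_identical(nrow(tab), 6L)  # 3 within + 3 between pairs
  # brute-force oracle: full cell-cell Spearman matrix
  R <- cor(t(sim$matrix$values), method = "spearman")
  ut <- which(upper.tri(R))
  loc <- arrayInd(ut, dim(R))
  df <- data.frame(i = loc[, 1], j = loc[, 2], value = R[ut])
  df <- df[order(-abs(df$value), df$i, df$j), ][seq_len(k), ]
  la <- pmin(sim$labels[df$i], sim$labels[df$j])
  lb <- pmax(sim$labels[df$i], sim$labels[df$j])
  want <- table(paste(la, lb))
  got <- setNames(tab$count, paste(tab$group_a, tab$group_b))
  for (nm in names(want)) expect_identical(got[[nm]], as.integer(want[[nm]]))
  expect_error(count_topk_group_pairs(sim$matrix[["values"]][, 1:2],
                                      sim$labels), "markers")
})

test_that("identical cells within groups concentrate counts within groups", {
  # two groups of internally identical cells (plus jitter-free structure):
  # every top pair is within-group once k covers exactly those pairs
  set.seed(105)
  markers <- 6
  proto <- matrix(rnorm(2 * markers), 2, markers)
  cells <- proto[rep(1:2, each = 10), ]
  cells <- cells + matrix(rnorm(length(cells), sd = 1e-6), nrow(cells))
  labels <- rep(c("g1", "g2"), each = 10)
  k_within <- 2 * count_pairs(10)
  tab <- count_topk_group_pairs(
    cells, labels, k_fraction = k_within / count_pairs(20),
    config = search_config(approximation_factor = 1e6))
  counts <- setNames(tab$count, paste(tab$group_a, tab$group_b))
  expect_identical(counts[["g1 g1"]], as.integer(count_pairs(10)))
  expect_identical(counts[["g2 g2"]], as.integer(count_pairs(10)))
  expect_identical(counts[["g1 g2"]], 0L)
})

test_that("effect-size screening thresholds and labels directions", {
  counts1 <- cbind("a\rb" = c(1, 2, 1, 2), "a\rc" = c(5, 6, 5, 6),
                   "b\rc" = c(3, 3, 4, 4))
  counts2 <- cbind("a\rb" = c(5, 6, 7, 8), "a\rc" = c(5, 6, 5, 7),
                   "b\rc" = c(0, 0, 1, 1))
  scr <- effect_size_screen(counts1, counts2)
  expect_setequal(scr$group_a, c("a", "b"))
  ab <- scr[scr$group_a == "a" & scr$group_b == "b", ]
  expect_identical(ab$direction, "increase")
  expect_equal(ab$delta, 1)  # all condition-2 counts strictly greater
  bc <- scr[scr$group_a == "b" & scr$group_b == "c", ]
  expect_identical(bc$direction, "decrease")
  # |delta| at or below the threshold is dropped ("a c" has small delta)
  expect_false(any(scr$group_a == "a" & scr$group_b == "c"))
  # antisymmetry: swapping conditions flips labels and negates delta
  swapped <- effect_size_screen(counts2, counts1)
  expect_equal(sort(-swapped$delta), sort(scr$delta))
  expect_identical(sort(unique(swapped$direction)),
                   sort(unique(ifelse(scr$delta > 0, "decrease",
                                      "increase"))))
  expect_error(effect_size_screen(counts1[1, , drop = FALSE], counts2[1, ,
                                  drop = FALSE]), "replicates")
})

test_that("null data rarely passes the very-large-effect screen", {
  sim1 <- generate_celllike(6, 30, 10, group_effect = 0, seed = 103)
  sim2 <- generate_celllike(6, 30, 10, group_effect = 0, seed = 104)
  res <- run_coordination(sim1$matrix, sim1$labels, sim2$matrix,
                          sim2$labels, n_replicates = 100,
                          target_per_group = 20, k_fraction = 0.01,
                          seed = 7,
                          config = search_config(approximation_factor = 20))
  n_pairs <- ncol(res$counts1)
  expect_identical(n_pairs, 21L)
  expect_lt(nrow(res$screened) / n_pairs, 0.05)
  # per-replicate conservation
  k <- round(0.01 * count_pairs(120))
  expect_true(all(rowSums(res$counts1) == k))
  expect_true(all(rowSums(res$counts2) == k))
})
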