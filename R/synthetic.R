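# Seeded generators with planted ground truth.  All are pure functions of
# their arguments (including the seed): the caller's RNG state is left
# untouched.
#
# Correlated blocks use a latent-factor construction: each feature in a
# block is s * z + noise_sd * eps with shared latent z and independent eps,
# giving expected within-block correlation rho = v / (v + noise_sd^2) for
# signal variance v = s^2; s is solved from the requested rho.

#' Generate a matrix with planted correlated feature blocks
#'
#' Features inside each block share a latent signal plus independent
#' Gaussian noise so their expected pairwise correlation is `rho`;
#' all remaining features are independent standard normals.  With
#' `noise_sd = 0` block members are exact (scaled) copies, r = 1.
#'
#' @param n_features Total number of features.
#' @param m_samples Number of samples.
#' @param block_sizes Integer vector of block sizes (sum <= n_features).
#' @param rho Target within-block correlation in (0, 1).
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `matrix` (a [feature_matrix()]), `truth` (data frame
#'   of all within-block pairs `i < j` with `expected` correlation), and
#'   `blocks` (feature-to-block assignment).
#' @export
generate_block_correlated <- function(n_features, m_samples, block_sizes,
                                      rho = 0.9, noise_sd = 0.3, seed = 1L) {
  if (sum(block_sizes) > n_features)
    stop_("block sizes exceed the number of features")
  if (rho <= 0 || rho >= 1) stop_("rho must lie in (0, 1)")
  if (noise_sd < 0) stop_("noise_sd must be non-negative")
  with_seed(seed, {
    V <- matrix(rnorm(m_samples * n_features), m_samples, n_features)
    block <- integer(n_features)
    expected <- if (noise_sd == 0) 1 else rho
    s <- if (noise_sd == 0) 1 else noise_sd * sqrt(rho / (1 - rho))
    pos <- 1L
    truth <- list()
    for (b in seq_along(block_sizes)) {
      size <- block_sizes[b]
      members <- seq.int(pos, pos + size - 1L)
      z <- rnorm(m_samples)
      for (f in members) V[, f] <- s * z + noise_sd * rnorm(m_samples)
      block[members] <- b
      if (size >= 2L) {
        combs <- utils::combn(members, 2L)
        truth[[b]] <- data.frame(i = combs[1L, ], j = combs[2L, ],
                                 expected = expected)
      }
      pos <- pos + size
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(i = integer(0), j = integer(0),
                             expected = numeric(0))
    list(matrix = feature_matrix(V), truth = truth, blocks = block)
  })
}

#' Generate two-condition data with planted differential correlations
#'
#' Plants, for each requested pair, correlation `rho1` in condition 1 and
#' `rho2` in condition 2 (a pair is built as x_j = rho x_i +
#' sqrt(1 - rho^2) eps, so the expected correlation equals rho).  Pairs
#' must be feature-disjoint; all unplanted features are independent noise
#' in both conditions.
#'
#' @param n_features Number of features (same in both conditions).
#' @param m1,m2 Sample counts of the two conditions.
#' @param planted_pairs Data frame with columns `i`, `j`, `rho1`, `rho2`.
#' @param seed Integer seed.
#' @return List with feature matrices `X1`, `X2` and `truth` (planted
#'   pairs with `expected` difference rho1 - rho2).
#' @export
generate_two_condition <- function(n_features, m1, m2,
                                   planted_pairs = NULL, seed = 1L) {
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(i = integer(0), j = integer(0),
                                rho1 = numeric(0), rho2 = numeric(0))
  ids <- c(planted_pairs$i, planted_pairs$j)
  if (anyDuplicated(ids)) stop_("planted pairs must be feature-disjoint")
  if (length(ids) && max(ids) > n_features) stop_("pair index out of range")
  with_seed(seed, {
    plant <- function(m, rhos) {
      V <- matrix(rnorm(m * n_features), m, n_features)
      for (r in seq_len(nrow(planted_pairs))) {
        i <- planted_pairs$i[r]; j <- planted_pairs$j[r]
        rho <- rhos[r]
        V[, j] <- rho * V[, i] + sqrt(1 - rho^2) * rnorm(m)
      }
      feature_matrix(V)
    }
    X1 <- plant(m1, planted_pairs$rho1)
    X2 <- plant(m2, planted_pairs$rho2)
    truth <- data.frame(i = pmin(planted_pairs$i, planted_pairs$j),
                        j = pmax(planted_pairs$i, planted_pairs$j),
                        expected = planted_pairs$rho1 - planted_pairs$rho2)
    list(X1 = X1, X2 = X2, truth = truth)
  })
}

#' Generate grouped cell-like data (cells x markers)
#'
#' Emulates a mass-cytometry-style benchmark: `n_groups` cell types, each
#' with `cells_per_group` cells measured on `n_markers` functional
#' markers.  Cells of a group scatter (unit-variance Gaussian noise)
#' around a group centroid whose coordinates are drawn with standard
#' deviation `group_effect`; `group_effect = 0` makes groups
#' indistinguishable (null data).
#'
#' @param n_groups Number of cell types.
#' @param cells_per_group Cells per type.
#' @param n_markers Functional markers per cell.
#' @param group_effect Centroid spread (0 = no group structure).
#' @param seed Integer seed.
#' @return List with `matrix` (a cells-by-markers [feature_matrix()];
#'   rows are cells) and `labels` (cell-type label per row).
#' @export
generate_celllike <- function(n_groups, cells_per_group, n_markers,
                              group_effect = 1, seed = 1L) {
  if (n_groups < 1 || cells_per_group < 1 || n_markers < 1)
    stop_("all counts must be positive")
  with_seed(seed, {
    n_cells <- n_groups * cells_per_group
    centroids <- matrix(rnorm(n_groups * n_markers, sd = group_effect),
                        n_groups, n_markers)
    V <- matrix(rnorm(n_cells * n_markers), n_cells, n_markers)
    labels <- rep(sprintf("type%02d", seq_len(n_groups)),
                  each = cells_per_group)
    V <- V + centroids[rep(seq_len(n_groups), each = cells_per_group), ,
                       drop = FALSE]
    colnames(V) <- paste0("marker", seq_len(n_markers))
    list(matrix = feature_matrix(V, colnames(V)), labels = labels)
  })
}
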