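#' Construct a validated sample-by-feature matrix
#'
#' The universal input container: rows are samples (observations), columns
#' are named features.  Validation rejects non-finite values and duplicate
#' feature names, which would silently corrupt downstream correlation
#' computations.
#'
#' @param values Numeric matrix (or object coercible to one), samples in
#'   rows, features in columns.
#' @param feature_names Character vector of unique feature names; defaults
#'   to `colnames(values)` or `f1..fn`.
#' @param sample_ids Optional character vector of sample identifiers.
#' @return An object of class `feature_matrix` with elements `values`,
#'   `feature_names`, and `sample_ids`.
#' @examples
#' X <- feature_matrix(matrix(rnorm(20), 5, 4))
#' dim(X$values)
#' @export
feature_matrix <- function(values, feature_names = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_("`values` must be a numeric matrix")
  storage.mode(values) <- "double"
  bad <- which(!is.finite(values))
  if (length(bad)) {
    loc <- arrayInd(bad[1L], dim(values))
    stop_(sprintf(
      "non-finite value at row %d, column %d (%d non-finite values total)",
      loc[1L], loc[2L], length(bad)))
  }
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(values))
    stop_("`feature_names` length must equal the number of columns")
  if (anyDuplicated(feature_names)) {
    dup <- unique(feature_names[duplicated(feature_names)])
    stop_("duplicate feature names: ", paste(head(dup, 5L), collapse = ", "))
  }
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (!is.null(sample_ids) && length(sample_ids) != nrow(values))
    stop_("`sample_ids` length must equal the number of rows")
  colnames(values) <- feature_names
  structure(
    list(values = values, feature_names = feature_names,
         sample_ids = sample_ids),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x else feature_matrix(x)
}

# Correlations need at least 2 (really 3 for inference) samples.
check_min_samples <- function(X, min = 2L) {
  if (nrow(X$values) < min)
    stop_(sprintf("at least %d samples are required, got %d",
                  min, nrow(X$values)))
  invisible(X)
}

#' Replace feature values by within-feature ranks
#'
#' Each column is replaced by its ranks across samples; tied values receive
#' the average of the tied rank positions (the standard Spearman
#' convention).  Applying Pearson machinery to the ranked matrix yields
#' Spearman rank correlations.
#'
#' @param X A [feature_matrix()] (or coercible matrix).
#' @return A `feature_matrix` of the same shape holding ranks.
#' @examples
#' rank_transform(feature_matrix(cbind(a = c(1, 1, 2))))$values
#' @export
rank_transform <- function(X) {
  X <- as_feature_matrix(X)
  ranked <- apply(X$values, 2L, rank, ties.method = "average")
  if (nrow(X$values) == 1L) ranked <- matrix(ranked, nrow = 1L)
  feature_matrix(ranked, X$feature_names, X$sample_ids)
}
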