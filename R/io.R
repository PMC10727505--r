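#' Read a sample-by-feature matrix from CSV, TSV or MatrixMarket files
#'
#' Dense CSV/TSV files must carry a header row of feature names, samples
#' in rows; a leading non-numeric column is taken as sample identifiers.
#' Sparse MatrixMarket (`.mtx`) coordinate files are densified and need a
#' sidecar file with one feature name per line (default
#' `<path>.names`).  Non-finite values are rejected with their location.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"mtx"`.
#' @param names_path Sidecar feature-name file for MTX input.
#' @param transpose Set when the file stores features in rows.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                                names_path = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx",
                     stop_("cannot infer format from extension: ", ext))
  }
  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    names_path <- names_path %||% paste0(path, ".names")
    if (!file.exists(names_path))
      stop_("feature-name sidecar not found: ", names_path)
    fnames <- readLines(names_path)
    if (transpose) M <- t(M)
    if (length(fnames) != ncol(M))
      stop_("sidecar has ", length(fnames), " names but matrix has ",
            ncol(M), " feature columns")
    return(feature_matrix(M, fnames))
  }
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, fill = FALSE)
  sample_ids <- NULL
  if (ncol(dt) && !is.numeric(dt[[1L]])) {
    sample_ids <- as.character(dt[[1L]])
    dt <- dt[, -1L, drop = FALSE]
  }
  non_num <- !vapply(dt, is.numeric, logical(1))
  if (any(non_num))
    stop_("non-numeric feature column(s): ",
          paste(head(names(dt)[non_num], 5L), collapse = ", "))
  M <- as.matrix(dt)
  if (transpose) {
    fnames <- sample_ids %||% paste0("f", seq_len(nrow(M)))
    M <- t(M)
    return(feature_matrix(M, fnames))
  }
  feature_matrix(M, colnames(M), sample_ids)
}

#' Write a feature matrix as CSV or TSV
#'
#' @param X A [feature_matrix()].
#' @param path Output file.
#' @param format `"csv"` or `"tsv"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  X <- as_feature_matrix(X)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  # print with 17 significant digits for a lossless read-back round trip
  chr <- matrix(sprintf("%.17g", X$values), nrow(X$values),
                dimnames = dimnames(X$values))
  df <- as.data.frame(chr)
  if (!is.null(X$sample_ids)) df <- cbind(sample_id = X$sample_ids, df)
  data.table::fwrite(df, path, sep = if (format == "csv") "," else "\t",
                     quote = FALSE)
  invisible(path)
}

#' Preprocess a feature matrix: clamp, drop constants, drop duplicates
#'
#' Applies, in this fixed order: (1) negative values are set to 0, (2)
#' features left with only a single distinct value are removed, (3) exact
#' duplicate features (identical on every sample) are removed keeping the
#' first occurrence.  Clamping runs first because it can create new
#' constant or duplicate features.  The removals are recorded in a report
#' attached as `attr(, "removal_report")`.  Idempotent.
#'
#' @param X A [feature_matrix()].
#' @return The filtered `feature_matrix`; errors if nothing survives.
#' @export
preprocess_features <- function(X) {
  X <- as_feature_matrix(X)
  V <- pmax(X$values, 0)
  report <- data.frame(feature = character(0), reason = character(0))
  n_distinct <- apply(V, 2L, function(col) length(unique(col)))
  constant <- n_distinct <= 1L
  if (any(constant))
    report <- rbind(report, data.frame(feature = X$feature_names[constant],
                                       reason = "constant"))
  V2 <- V[, !constant, drop = FALSE]
  keep_names <- X$feature_names[!constant]
  dup <- duplicated(t(V2))
  if (any(dup))
    report <- rbind(report, data.frame(feature = keep_names[dup],
                                       reason = "duplicate"))
  V3 <- V2[, !dup, drop = FALSE]
  if (ncol(V3) == 0L) stop_("preprocessing removed every feature")
  out <- feature_matrix(V3, keep_names[!dup], X$sample_ids)
  attr(out, "removal_report") <- report
  out
}

#' Write an edge list as TSV
#'
#' Columns `feature_i`, `feature_j`, `value` and, when present, `p`,
#' `p_adj`; rows in the edge list's deterministic order; numeric values
#' printed with 17 significant digits so a read-back round trip is
#' lossless.
#'
#' @param edges An `edge_list`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(inherits(edges, "edge_list"))
  cols <- intersect(c("feature_i", "feature_j", "value", "p", "p_adj"),
                    names(edges))
  df <- as.data.frame(edges)[, cols, drop = FALSE]
  for (cl in intersect(c("value", "p", "p_adj"), cols))
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path TSV file.
#' @return A data frame with the stored columns, numerics parsed back.
#' @export
read_edge_list <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write feature coordinates as TSV
#'
#' @param coords Matrix from [correlation_embedding_coordinates()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(coords, path) {
  df <- data.frame(feature = rownames(coords) %||%
                     paste0("f", seq_len(nrow(coords))),
                   as.data.frame(unname(coords)))
  names(df)[-1L] <- paste0("dim", seq_len(ncol(coords)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
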