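#' Read a binary regulatory matrix from a file
#'
#' Two on-disk formats are supported. Dense delimited files (TSV/CSV)
#' store target genes as rows and samples as columns — the layout produced
#' by GRN-inference pipelines — with feature ids in the first column and
#' sample ids in the header; the matrix is transposed once at this
#' boundary to the internal samples-as-rows convention. Matrix Market
#' files (\code{.mtx}) store the same features-by-samples sparse matrix
#' with two sidecar id files (one id per line): \code{<stem>.features.txt}
#' and \code{<stem>.samples.txt} by default.
#'
#' @param path file to read; format inferred from the extension
#'   (\code{.mtx} = Matrix Market, anything else dense delimited).
#' @param sep field delimiter for dense files; inferred from the extension
#'   (\code{","} for \code{.csv}, tab otherwise) when \code{NULL}.
#' @param feature_file,sample_file sidecar id files for Matrix Market
#'   input; defaults derived from \code{path}.
#' @return A \code{\link{binary_matrix}} (samples as rows).
#' @export
read_binary_matrix <- function(path, sep = NULL,
                               feature_file = NULL, sample_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(feature_file)) feature_file <- sidecar(path, "features")
    if (is.null(sample_file)) sample_file <- sidecar(path, "samples")
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "integer"  # pattern/logical Matrix Market variants
    features <- readLines(feature_file)
    samples <- readLines(sample_file)
    if (nrow(m) != length(features) || ncol(m) != length(samples)) {
      stop("sidecar id files do not match the matrix dimensions")
    }
    return(binary_matrix(t(m), sample_ids = samples, feature_ids = features))
  }
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "#")
  binary_matrix(t(as.matrix(df)),
                sample_ids = colnames(df), feature_ids = rownames(df))
}

sidecar <- function(path, what) {
  sub("\\.mtx$", paste0(".", what, ".txt"), path)
}

#' Write a binary regulatory matrix to a file
#'
#' Inverse of \code{\link{read_binary_matrix}}: dense delimited output has
#' features as rows and samples as columns; Matrix Market output writes
#' the sparse features-by-samples matrix plus the two sidecar id files.
#' Reading a written file reproduces the matrix exactly.
#'
#' @param m a \code{\link{binary_matrix}}.
#' @inheritParams read_binary_matrix
#' @return \code{path}, invisibly.
#' @export
write_binary_matrix <- function(m, path, sep = NULL,
                                feature_file = NULL, sample_file = NULL) {
  m <- as_binary_matrix(m)
  if (grepl("\\.mtx$", path)) {
    if (is.null(feature_file)) feature_file <- sidecar(path, "features")
    if (is.null(sample_file)) sample_file <- sidecar(path, "samples")
    Matrix::writeMM(Matrix::Matrix(t(unclass(m)) * 1, sparse = TRUE), path)
    writeLines(colnames(m), feature_file)
    writeLines(rownames(m), sample_file)
    return(invisible(path))
  }
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  fm <- t(unclass(m))  # features as rows on disk
  df <- data.frame(feature_id = rownames(fm), fm, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read two-group sample labels from a file
#'
#' Expects a delimited file with two columns, sample id and group, and
#' exactly two distinct groups. When a matrix is supplied the labels are
#' aligned to its samples by id (order in the file is irrelevant) and
#' every sample must be labeled.
#'
#' @param path label file.
#' @param m optional \code{\link{binary_matrix}} to align against.
#' @param sep field delimiter; inferred as in
#'   \code{\link{read_binary_matrix}} when \code{NULL}.
#' @param case group value to treat as the case group (level A); defaults
#'   to the first in sort order.
#' @return A named \code{\link{group_labels}} vector.
#' @export
read_group_labels <- function(path, m = NULL, sep = NULL, case = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("label file needs two columns: sample_id, group")
  if (anyDuplicated(df[[1L]])) stop("duplicate sample ids in label file")
  labels <- group_labels(stats::setNames(df[[2L]], df[[1L]]), case = case)
  if (!is.null(m)) {
    m <- as_binary_matrix(m)
    unknown <- setdiff(names(labels), rownames(m))
    if (length(unknown)) {
      stop("labels for unknown samples: ", paste(unknown, collapse = ", "))
    }
    labels <- align_labels(m, labels)
  }
  labels
}

#' Write two-group sample labels
#'
#' @param labels a \code{\link{group_labels}} vector with sample names.
#' @param path output file.
#' @param sep field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
write_group_labels <- function(labels, path, sep = "\t") {
  if (is.null(names(labels))) stop("'labels' must be named by sample id")
  df <- data.frame(sample_id = names(labels), group = as.character(labels))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table with a provenance header
#'
#' Writes any of the package's result data frames as TSV, preceded by
#' comment-prefixed header lines recording the effective seed and
#' permutation count so a result file is self-describing.
#'
#' @param x a data frame (e.g. from \code{\link{run_tf_suite}} or
#'   \code{\link{power_study}}).
#' @param path output file.
#' @param seed,n_perm provenance values recorded in the header; taken from
#'   matching columns of \code{x} when present and \code{NULL}.
#' @return \code{path}, invisibly.
#' @export
write_results_tsv <- function(x, path, seed = NULL, n_perm = NULL) {
  if (is.null(seed) && "seed" %in% names(x)) seed <- x$seed[1L]
  if (is.null(n_perm) && "n_perm" %in% names(x)) n_perm <- x$n_perm[1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grndiff results | seed=%s | n_perm=%s | written=%s",
                     ifelse(is.null(seed), "NA", seed),
                     ifelse(is.null(n_perm), "NA", n_perm),
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
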