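#' Construct a binary regulatory matrix
#'
#' A binary regulatory matrix records, for one transcription factor (TF),
#' which of its target genes are actively regulated in each sample: entry
#' \code{(i, g)} is 1 if target \code{g} is active in sample \code{i} and 0
#' otherwise. The internal convention throughout the package is
#' samples-as-rows (\code{N x G}); file formats that store targets as rows
#' are transposed once at the I/O boundary (see
#' \code{\link{read_binary_matrix}}).
#'
#' @param values integer or numeric matrix with entries in \{0, 1\};
#'   samples as rows, features (target genes) as columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames or \code{"S1"..."SN"}.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to existing colnames or \code{"g1"..."gG"}.
#' @return An integer matrix of class \code{"binary_matrix"} with sample ids
#'   as rownames and feature ids as colnames.
#' @examples
#' m <- binary_matrix(rbind(c(1, 0, 1), c(0, 0, 1)))
#' dim(m)
#' @export
binary_matrix <- function(values, sample_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(values)) {
    values <- as.matrix(values)
  }
  if (is.logical(values)) storage.mode(values) <- "integer"
  if (!is.numeric(values)) {
    stop("'values' must be a numeric matrix with entries in {0, 1}")
  }
  if (anyNA(values) || !all(values == 0L | values == 1L)) {
    bad <- which(is.na(values) | (values != 0L & values != 1L), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary entry at row %d, column %d", bad[1L], bad[2L]))
  }
  storage.mode(values) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("g", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids)) {
    stop("'sample_ids' must be unique and match the number of rows")
  }
  if (length(feature_ids) != ncol(values) || anyDuplicated(feature_ids)) {
    stop("'feature_ids' must be unique and match the number of columns")
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_ids))
  class(values) <- c("binary_matrix", class(values))
  values
}

#' Test for a binary regulatory matrix
#' @param x object to test.
#' @return \code{TRUE} if \code{x} is a \code{binary_matrix}.
#' @export
is.binary_matrix <- function(x) inherits(x, "binary_matrix")

as_binary_matrix <- function(x) {
  if (is.binary_matrix(x)) x else binary_matrix(x)
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("Binary regulatory matrix: %d samples x %d features (%.1f%% active)\n",
              nrow(x), ncol(x), 100 * mean(x)))
  invisible(x)
}

#' Construct two-group sample labels
#'
#' Assigns each sample to one of two groups, conventionally A = case and
#' B = control. The first level of the resulting factor is the case group.
#'
#' @param assignment character or factor vector of group memberships with
#'   exactly two distinct values, or a named vector whose names are sample
#'   ids.
#' @param case value of \code{assignment} identifying the case group;
#'   defaults to the first level in sort order.
#' @return A factor of class \code{"group_labels"} with two levels, the
#'   case group first.
#' @examples
#' group_labels(c("oud", "oud", "ctl", "ctl"), case = "oud")
#' @export
group_labels <- function(assignment, case = NULL) {
  if (is.factor(assignment)) assignment <- as.character(assignment)
  lev <- sort(unique(assignment))
  if (length(lev) != 2L) {
    stop(sprintf("expected exactly 2 groups, found %d", length(lev)))
  }
  if (is.null(case)) {
    case <- lev[1L]
  } else if (!case %in% lev) {
    stop(sprintf("case group '%s' not present in assignment", case))
  }
  out <- factor(assignment, levels = c(case, setdiff(lev, case)))
  names(out) <- names(assignment)
  class(out) <- c("group_labels", "factor")
  out
}

#' @export
print.group_labels <- function(x, ...) {
  n <- table(unclass(x))
  cat(sprintf("Group labels: %s (case) n=%d, %s (control) n=%d\n",
              levels(x)[1L], n[1L], levels(x)[2L], n[2L]))
  invisible(x)
}

# Index sets of case (A) and control (B) samples; optionally require
# at least `min_per_group` samples per group.
group_split <- function(labels, min_per_group = 2L) {
  if (!inherits(labels, "group_labels")) labels <- group_labels(labels)
  idx_a <- which(unclass(labels) == 1L)
  idx_b <- which(unclass(labels) == 2L)
  if (length(idx_a) < min_per_group || length(idx_b) < min_per_group) {
    stop(sprintf("each group needs at least %d samples (found %d and %d)",
                 min_per_group, length(idx_a), length(idx_b)))
  }
  list(a = idx_a, b = idx_b)
}

# Align labels to a matrix: labels may be named (joined by sample id) or
# positional. Returns a group_labels vector in matrix row order.
align_labels <- function(m, labels) {
  if (!inherits(labels, "group_labels")) labels <- group_labels(labels)
  if (!is.null(names(labels)) && !is.null(rownames(m))) {
    miss <- setdiff(rownames(m), names(labels))
    if (length(miss)) {
      stop("samples missing a group label: ", paste(miss, collapse = ", "))
    }
    labels <- labels[rownames(m)]
  } else if (length(labels) != nrow(m)) {
    stop("labels length does not match the number of samples")
  }
  labels
}
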