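#' Hamming distance between two binary vectors
#'
#' Counts the positions at which two binary profiles differ. This is the
#' kernel of the global U-statistic test: it weighs every edge-wise
#' mismatch equally, whether the change is an activation or a loss.
#'
#' @param x,y binary vectors (entries in \{0, 1\}) of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming_distance(c(1, 0, 1, 1), c(0, 0, 1, 0))  # 2
#' @export
hamming_distance <- function(x, y) {
  check_binary_pair(x, y)
  sum(x != y)
}

#' Jaccard distance between two binary vectors
#'
#' One minus the ratio of jointly active positions to positions active in
#' either profile. Unlike the Hamming count it ignores shared inactivity,
#' which makes it sensitive to changes among the (typically few) active
#' edges of a sparse regulatory profile. Two all-zero profiles are treated
#' as identical (distance 0) rather than undefined, so fully inactive
#' samples do not propagate NaN.
#'
#' @inheritParams hamming_distance
#' @return Real dissimilarity in [0, 1].
#' @examples
#' jaccard_distance(c(1, 1, 0), c(1, 0, 1))  # 1 - 1/3
#' @export
jaccard_distance <- function(x, y) {
  check_binary_pair(x, y)
  union <- sum(x | y)
  if (union == 0L) return(0)
  1 - sum(x & y) / union
}

check_binary_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("vectors differ in length (%d vs %d)", length(x), length(y)))
  }
  if (anyNA(x) || anyNA(y) || !all(x == 0L | x == 1L) || !all(y == 0L | y == 1L)) {
    stop("entries must all be 0 or 1")
  }
  invisible(TRUE)
}

#' All pairwise sample dissimilarities of a binary matrix
#'
#' Computes the full \code{N x N} matrix of pairwise distances between
#' sample profiles (rows). Group labels never change the distances, so the
#' permutation tests compute this matrix once and merely re-partition it
#' across label permutations.
#'
#' @param m a \code{\link{binary_matrix}} (or coercible matrix), samples as
#'   rows.
#' @param metric \code{"hamming"} (integer mismatch count) or
#'   \code{"jaccard"}.
#' @return A symmetric numeric matrix of class \code{"dist_matrix"} with
#'   zero diagonal, sample ids as dimnames and the metric stored in
#'   \code{attr(, "metric")}.
#' @examples
#' m <- binary_matrix(rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1)))
#' pairwise_distances(m, "hamming")
#' @export
pairwise_distances <- function(m, metric = c("hamming", "jaccard")) {
  metric <- match.arg(metric)
  m <- as_binary_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  d <- if (metric == "hamming") {
    stats::dist(m, method = "manhattan")  # |x-y| == mismatch count on 0/1
  } else {
    stats::dist(m, method = "binary")     # Jaccard; NaN when both rows all-zero
  }
  d <- as.matrix(d)
  d[is.nan(d)] <- 0  # empty-union convention: two inactive profiles are identical
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "metric") <- metric
  class(d) <- c("dist_matrix", class(d))
  d
}

is_dist_matrix <- function(x) inherits(x, "dist_matrix")
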