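#' Components of the global U-statistic
#'
#' Decomposes a Hamming distance matrix into average pairwise distances
#' within each group (\code{U_AA}, \code{U_BB}) and between groups
#' (\code{U_AB}), and forms the dissimilarity ratio \code{T_d = B / W}
#' where \code{B = U_AB} and \code{W} is the pair-count-weighted pooled
#' within-group mean. \code{T_d} near 1 indicates that cross-group pairs
#' are no more dissimilar than same-group pairs; values above 1 indicate
#' group separation.
#'
#' Degenerate matrices are handled without epsilons: \code{W = 0} with
#' \code{B > 0} yields \code{T_d = Inf} (maximal separation), and
#' \code{W = 0} with \code{B = 0} yields \code{T_d = 1} (no evidence).
#'
#' @param d a Hamming distance matrix from \code{\link{pairwise_distances}}
#'   (any symmetric dissimilarity matrix is accepted).
#' @param labels a \code{\link{group_labels}} vector (or coercible), both
#'   groups with at least 2 samples.
#' @return A list of class \code{"global_u_components"} with elements
#'   \code{U_AA}, \code{U_BB}, \code{U_AB}, \code{B}, \code{W}, \code{T_d}.
#' @examples
#' m <- binary_matrix(rbind(c(1,1,0), c(1,0,0), c(0,0,1), c(0,1,1)))
#' d <- pairwise_distances(m, "hamming")
#' global_u_statistic(d, group_labels(c("A","A","B","B")))
#' @export
global_u_statistic <- function(d, labels) {
  labels <- align_labels(d, labels)
  g <- group_split(labels)
  comp <- dissimilarity_components(d, g$a, g$b)
  structure(comp, class = "global_u_components")
}

#' @export
print.global_u_components <- function(x, ...) {
  cat(sprintf("U_AA = %.4f  U_BB = %.4f  U_AB = %.4f\n", x$U_AA, x$U_BB, x$U_AB))
  cat(sprintf("T_d = B/W = %.4f / %.4f = %.4f\n", x$B, x$W, x$T_d))
  invisible(x)
}

# Shared between/within decomposition of a cached distance matrix.
# Returns means, the B and W contributions and their ratio, with the
# degenerate conventions W=0,B>0 -> Inf and W=0,B=0 -> 1.
dissimilarity_components <- function(d, idx_a, idx_b) {
  n_a <- length(idx_a)
  n_b <- length(idx_b)
  s_aa <- sum(d[idx_a, idx_a]) / 2
  s_bb <- sum(d[idx_b, idx_b]) / 2
  s_ab <- sum(d[idx_a, idx_b])
  p_aa <- n_a * (n_a - 1) / 2
  p_bb <- n_b * (n_b - 1) / 2
  u_aa <- s_aa / p_aa
  u_bb <- s_bb / p_bb
  u_ab <- s_ab / (n_a * n_b)
  b <- u_ab
  w <- (s_aa + s_bb) / (p_aa + p_bb)
  list(U_AA = u_aa, U_BB = u_bb, U_AB = u_ab, B = b, W = w,
       T_d = ratio_or_sentinel(b, w))
}

ratio_or_sentinel <- function(b, w) {
  if (w == 0) {
    if (b > 0) Inf else 1
  } else {
    b / w
  }
}

# Lean ratio used inside permutation loops (no validation, no list).
group_ratio_stat <- function(d, idx_a, idx_b, p_aa, p_bb) {
  s_aa <- sum(d[idx_a, idx_a]) / 2
  s_bb <- sum(d[idx_b, idx_b]) / 2
  b <- sum(d[idx_a, idx_b]) / (length(idx_a) * length(idx_b))
  w <- (s_aa + s_bb) / (p_aa + p_bb)
  ratio_or_sentinel(b, w)
}

#' Distance-based pseudo-F statistic
#'
#' PERMANOVA-style ratio \code{F* = D_between / D_within} on a Jaccard
#' distance matrix: the mean dissimilarity over all cross-group sample
#' pairs divided by the pair-count-weighted pooled mean over all
#' within-group pairs. Degenerate cases follow the same conventions as
#' \code{\link{global_u_statistic}}.
#'
#' @param d a Jaccard distance matrix from \code{\link{pairwise_distances}}.
#' @inheritParams global_u_statistic
#' @return The pseudo-F ratio (a single number, possibly \code{Inf}).
#' @export
global_f_statistic <- function(d, labels) {
  labels <- align_labels(d, labels)
  g <- group_split(labels)
  dissimilarity_components(d, g$a, g$b)$T_d
}

#' PCA-based group separation score
#'
#' Mean-centres each feature column (no variance scaling: all features are
#' on the common 0/1 scale), projects samples onto the first principal
#' component, and returns the absolute difference in mean PC1 scores
#' between the two groups, \code{S = |mean(z_A) - mean(z_B)|}. The score is
#' invariant to the arbitrary sign of the PC axis. A matrix with no
#' variance has all scores zero, hence \code{S = 0}.
#'
#' @param m a \code{\link{binary_matrix}} with at least 3 samples.
#' @inheritParams global_u_statistic
#' @return The separation score \code{S >= 0}.
#' @export
pca_separation <- function(m, labels) {
  m <- as_binary_matrix(m)
  if (nrow(m) < 3L) stop("need at least 3 samples for PCA")
  labels <- align_labels(m, labels)
  g <- group_split(labels)
  z <- pc1_scores(m)
  abs(mean(z[g$a]) - mean(z[g$b]))
}

pc1_scores <- function(m) {
  stats::prcomp(m, center = TRUE, scale. = FALSE)$x[, 1L]
}

#' Label-permutation significance test
#'
#' The shared significance engine behind every test in the package. Group
#' labels are permuted \code{n_perm} times by independent uniform shuffles
#' preserving the group sizes, the statistic is recomputed for each
#' relabeling, and the empirical p-value is
#' \code{(1 + n_exceed) / (n_perm + 1)}, where a null replicate counts as
#' an exceedance when its statistic is \code{>=} the observed value
#' (\code{tail = "greater"}; used for all ratio/score statistics) or
#' \code{<=} it (\code{tail = "lesser"}; used when the statistic is itself
#' a p-value, as in \code{\link{global_fisher_test}}). Ties at the observed
#' value count as exceedances, and \code{Inf >= Inf} holds, so degenerate
#' sentinels compare consistently. The smallest attainable p-value is
#' \code{1 / (n_perm + 1)}; the engine never returns 0.
#'
#' @param statistic function of \code{(data, labels)} returning a single
#'   number; must be deterministic.
#' @param data first argument passed through to \code{statistic} (a matrix,
#'   distance matrix, or anything the statistic closes over).
#' @param labels a \code{\link{group_labels}} vector.
#' @param n_perm number of permutation replicates \code{R >= 1}.
#' @param seed integer seed for the permutation stream; drawn (and
#'   recorded) from the session RNG when \code{NULL}.
#' @param tail \code{"greater"} or \code{"lesser"}.
#' @param keep_null if \code{TRUE}, store the null statistic values in the
#'   result.
#' @return A list of class \code{"perm_test"}: \code{observed},
#'   \code{n_perm}, \code{n_exceed}, \code{p_perm}, \code{seed},
#'   \code{tail}, and optionally \code{null_values}.
#' @examples
#' m <- simulate_grn("normal", gamma = 0.25, seed = 1)
#' d <- pairwise_distances(m$matrix, "hamming")
#' permutation_test(function(d, l) global_u_statistic(d, l)$T_d,
#'                  d, m$labels, n_perm = 99, seed = 1)
#' @export
permutation_test <- function(statistic, data, labels,
                             n_perm = 2000L, seed = NULL,
                             tail = c("greater", "lesser"),
                             keep_null = FALSE) {
  tail <- match.arg(tail)
  if (!is.function(statistic)) stop("'statistic' must be a function")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("'n_perm' must be a positive integer")
  if (!inherits(labels, "group_labels")) labels <- group_labels(labels)
  # from here on labels are positional: names must not trigger re-alignment
  # by id inside the statistic, or permutations would be undone
  names(labels) <- NULL
  seed <- resolve_seed(seed)

  observed <- statistic(data, labels)
  if (length(observed) != 1L || is.na(observed)) {
    stop("statistic must return a single non-NA number")
  }

  null_values <- numeric(n_perm)
  n <- length(labels)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_perm)) {
    perm <- labels[sample.int(n)]
    null_values[r] <- statistic(data, perm)
  }
  n_exceed <- if (tail == "greater") sum(null_values >= observed)
              else sum(null_values <= observed)

  out <- list(observed = observed, n_perm = n_perm, n_exceed = n_exceed,
              p_perm = (1 + n_exceed) / (n_perm + 1),
              seed = seed, tail = tail)
  if (keep_null) out$null_values <- null_values
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  stat <- if (is.null(x$statistic_name)) "statistic" else x$statistic_name
  cat(sprintf("Permutation test (%s)\n", stat))
  cat(sprintf("  observed = %.6g, R = %d, exceedances = %d\n",
              x$observed, x$n_perm, x$n_exceed))
  cat(sprintf("  p_perm = %.6g  (seed %d, tail %s)\n", x$p_perm, x$seed, x$tail))
  invisible(x)
}

resolve_seed <- function(seed) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  as.integer(seed)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Global U-statistic permutation test
#'
#' Tests for overall group difference via the Hamming-kernel dissimilarity
#' ratio \code{T_d} (see \code{\link{global_u_statistic}}). The distance
#' matrix is computed once; each permutation replicate only re-partitions
#' the cached pairwise distances.
#'
#' @param x a \code{\link{binary_matrix}}, or a precomputed Hamming
#'   distance matrix from \code{\link{pairwise_distances}}.
#' @inheritParams permutation_test
#' @return A \code{\link{permutation_test}} result.
#' @export
global_u_test <- function(x, labels, n_perm = 2000L, seed = NULL,
                          keep_null = FALSE) {
  d <- if (is_dist_matrix(x)) x else pairwise_distances(x, "hamming")
  labels <- align_labels(d, labels)
  res <- permutation_test(ratio_statistic_fn(), d, labels,
                          n_perm = n_perm, seed = seed,
                          tail = "greater", keep_null = keep_null)
  res$statistic_name <- "Global_U (Hamming dissimilarity ratio T_d)"
  res
}

#' Distance-based pseudo-F permutation test
#'
#' Tests for overall group difference via the Jaccard pseudo-F ratio
#' \code{F*} (see \code{\link{global_f_statistic}}), with the distance
#' matrix cached across permutation replicates.
#'
#' @param x a \code{\link{binary_matrix}}, or a precomputed Jaccard
#'   distance matrix from \code{\link{pairwise_distances}}.
#' @inheritParams permutation_test
#' @return A \code{\link{permutation_test}} result.
#' @export
global_f_test <- function(x, labels, n_perm = 2000L, seed = NULL,
                          keep_null = FALSE) {
  d <- if (is_dist_matrix(x)) x else pairwise_distances(x, "jaccard")
  labels <- align_labels(d, labels)
  res <- permutation_test(ratio_statistic_fn(), d, labels,
                          n_perm = n_perm, seed = seed,
                          tail = "greater", keep_null = keep_null)
  res$statistic_name <- "Global_F (Jaccard pseudo-F)"
  res
}

# Ratio statistic on a cached distance matrix; memoises the per-group pair
# counts on first call (group sizes are invariant under relabeling).
ratio_statistic_fn <- function() {
  function(d, labels) {
    g <- group_split(labels)
    p_aa <- length(g$a) * (length(g$a) - 1) / 2
    p_bb <- length(g$b) * (length(g$b) - 1) / 2
    group_ratio_stat(d, g$a, g$b, p_aa, p_bb)
  }
}

#' PCA separation permutation test
#'
#' Tests group separation along the first principal component. The PCA
#' embedding is fit once on the full matrix (it does not depend on the
#' labels); each permutation replicate re-averages the fixed PC1 scores,
#' making the null \code{O(N)} per replicate.
#'
#' @param m a \code{\link{binary_matrix}} with at least 3 samples.
#' @inheritParams permutation_test
#' @return A \code{\link{permutation_test}} result.
#' @export
pca_test <- function(m, labels, n_perm = 2000L, seed = NULL,
                     keep_null = FALSE) {
  m <- as_binary_matrix(m)
  if (nrow(m) < 3L) stop("need at least 3 samples for PCA")
  labels <- align_labels(m, labels)
  z <- pc1_scores(m)
  stat <- function(z, labels) {
    g <- group_split(labels)
    abs(mean(z[g$a]) - mean(z[g$b]))
  }
  res <- permutation_test(stat, z, labels, n_perm = n_perm, seed = seed,
                          tail = "greater", keep_null = keep_null)
  res$statistic_name <- "PCA (|mean PC1 score difference| S)"
  res
}
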