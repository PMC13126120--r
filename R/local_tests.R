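#' Per-feature Mann-Whitney p-values
#'
#' Applies the two-sided Mann-Whitney (Wilcoxon rank-sum) test
#' independently to each feature column, comparing case against control
#' samples. Binary data are maximally tied, so the tie-corrected normal
#' approximation is used throughout (no continuity correction). For a
#' binary feature the test reduces to a closed form in the number of
#' active case samples given the feature's total activation count, which
#' is what makes full recomputation across thousands of permutation
#' replicates cheap. A feature constant across all samples carries no rank
#' information and is assigned p = 1.
#'
#' @param m a \code{\link{binary_matrix}}.
#' @param labels a \code{\link{group_labels}} vector, both groups with at
#'   least 2 samples.
#' @return Numeric vector of G two-sided p-values in (0, 1], named by
#'   feature.
#' @export
mann_whitney_per_feature <- function(m, labels) {
  m <- as_binary_matrix(m)
  labels <- align_labels(m, labels)
  g <- group_split(labels)
  a <- colSums(m[g$a, , drop = FALSE])
  t <- colSums(m)
  p <- mw_binary_pvalue(a, t, length(g$a), length(g$b))
  names(p) <- colnames(m)
  p
}

# Two-sided tie-corrected normal-approximation Mann-Whitney p-value for a
# binary feature with `a` active entries among the n_a case samples and
# `t` active entries overall. Vectorised over (a, t).
mw_binary_pvalue <- function(a, t, n_a, n_b) {
  n <- n_a + n_b
  n1 <- t            # observations equal to 1
  n0 <- n - t        # observations equal to 0
  # midranks: zeros share (n0+1)/2, ones share n0 + (n1+1)/2
  w_case <- a * (n0 + (n1 + 1) / 2) + (n_a - a) * (n0 + 1) / 2
  u <- w_case - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  tie_term <- (n0^3 - n0 + n1^3 - n1) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  z <- (u - mu) / sqrt(sigma2)
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p[!is.finite(z)] <- 1  # constant feature: sigma2 = 0 and u = mu
  p
}

#' Fisher's method for combining p-values
#'
#' Combines a vector of p-values into \code{T = -2 * sum(log(p))}. Values
#' are clamped below at 1e-300 before taking logs so that numerically zero
#' p-values cannot produce an infinite statistic. The chi-squared reference
#' distribution (2G degrees of freedom under independence) is deliberately
#' not used for inference here: features within a TF matrix are correlated,
#' so significance comes from the permutation wrapper instead.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return The combined statistic \code{T >= 0}.
#' @examples
#' fisher_combine(c(0.1, 0.1))  # -4 * log(0.1)
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0L) stop("'p' must be non-empty")
  p <- pmax(p, 1e-300)
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  -2 * sum(log(p))
}

#' Local U permutation test
#'
#' Feature-level group-difference test: per-feature Mann-Whitney p-values
#' are aggregated with Fisher's method, and the combined statistic is
#' referred to a label-permutation null in which every per-feature test is
#' fully recomputed under each relabeling. This accounts for the
#' correlation among features that invalidates the chi-squared reference.
#'
#' @inheritParams mann_whitney_per_feature
#' @inheritParams permutation_test
#' @return A \code{\link{permutation_test}} result.
#' @export
local_u_test <- function(m, labels, n_perm = 2000L, seed = NULL,
                         keep_null = FALSE) {
  m <- as_binary_matrix(m)
  labels0 <- align_labels(m, labels)
  g0 <- group_split(labels0)
  n_a <- length(g0$a)
  n_b <- length(g0$b)
  t <- colSums(m)
  G <- ncol(m)
  # p depends only on the active-case count a in 0..n_a given fixed t:
  # precompute the (n_a+1) x G lookup once, re-index per replicate.
  lut <- mw_binary_pvalue(matrix(0:n_a, n_a + 1L, G),
                          matrix(t, n_a + 1L, G, byrow = TRUE), n_a, n_b)
  lut <- pmax(lut, 1e-300)
  col_off <- (seq_len(G) - 1L) * (n_a + 1L)
  stat <- function(m, labels) {
    idx_a <- which(unclass(labels) == 1L)
    a <- colSums(m[idx_a, , drop = FALSE])
    -2 * sum(log(lut[a + 1L + col_off]))
  }
  res <- permutation_test(stat, m, labels0, n_perm = n_perm, seed = seed,
                          tail = "greater", keep_null = keep_null)
  res$statistic_name <- "Local_U (Fisher-combined per-feature Mann-Whitney)"
  res
}

#' Aggregate active/inactive counts per group
#'
#' Collapses a binary matrix to the 2 x 2 contingency table of active and
#' inactive entries per group, the input of the aggregated Fisher exact
#' test of overall regulatory burden.
#'
#' @inheritParams mann_whitney_per_feature
#' @return A 2 x 2 integer matrix of class \code{"contingency_2x2"} with
#'   rows A (case) and B (control) and columns active / inactive.
#' @export
aggregate_counts <- function(m, labels) {
  m <- as_binary_matrix(m)
  labels <- align_labels(m, labels)
  g <- group_split(labels, min_per_group = 1L)
  G <- ncol(m)
  o_a <- sum(m[g$a, , drop = FALSE])
  o_b <- sum(m[g$b, , drop = FALSE])
  tab <- matrix(as.integer(c(o_a, o_b,
                             length(g$a) * G - o_a, length(g$b) * G - o_b)),
                nrow = 2L,
                dimnames = list(group = c("A", "B"),
                                state = c("active", "inactive")))
  class(tab) <- c("contingency_2x2", class(tab))
  tab
}

#' Two-sided Fisher exact p-value for a 2 x 2 table
#'
#' Exact hypergeometric p-value using the minimum-likelihood rule: the sum
#' of the probabilities of all tables (with the observed margins) whose
#' point probability does not exceed that of the observed table. This is
#' the most common two-sided convention for Fisher's exact test.
#'
#' @param tab a 2 x 2 matrix of non-negative counts (rows = groups,
#'   columns = active/inactive), e.g. from \code{\link{aggregate_counts}}.
#' @return The two-sided exact p-value in (0, 1].
#' @examples
#' fisher_exact_pvalue(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact_pvalue <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0)) {
    stop("'tab' must be a 2 x 2 matrix of non-negative counts")
  }
  row_a <- sum(tab[1L, ])
  col_active <- sum(tab[, 1L])
  col_inactive <- sum(tab[, 2L])
  support <- hyper_support(row_a, col_active, col_inactive)
  d <- stats::dhyper(support, col_active, col_inactive, row_a)
  d_obs <- d[match(tab[1L, 1L], support)]
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

hyper_support <- function(k_drawn, n_white, n_black) {
  max(0L, k_drawn - n_black):min(k_drawn, n_white)
}

#' Aggregated Fisher exact permutation test
#'
#' Computes the Fisher exact p-value of the pooled active/inactive table
#' (\code{\link{aggregate_counts}}) and refers it to a label-permutation
#' null to account for dependence among entries and small-sample
#' discreteness. Because permuting labels fixes both margins of the table,
#' the replicate statistic depends only on the number of active entries
#' assigned to the case group, so the p-value for every attainable table
#' is precomputed once over the hypergeometric support. A null replicate
#' counts as an exceedance when its Fisher p-value is less than or equal
#' to the observed one (smaller means more extreme).
#'
#' @inheritParams mann_whitney_per_feature
#' @inheritParams permutation_test
#' @return A \code{\link{permutation_test}} result (note
#'   \code{tail = "lesser"}).
#' @export
global_fisher_test <- function(m, labels, n_perm = 2000L, seed = NULL,
                               keep_null = FALSE) {
  m <- as_binary_matrix(m)
  labels0 <- align_labels(m, labels)
  g0 <- group_split(labels0)
  G <- ncol(m)
  row_tot <- rowSums(m)
  n_a <- length(g0$a)
  row_a <- n_a * G
  col_active <- sum(row_tot)
  col_inactive <- (length(labels0)) * G - col_active
  support <- hyper_support(row_a, col_active, col_inactive)
  d <- stats::dhyper(support, col_active, col_inactive, row_a)
  # cumulative minimum-likelihood p over the sorted point probabilities
  ord <- order(d)
  cum <- cumsum(d[ord])
  pv <- numeric(length(d))
  pv[ord] <- pmin(1, cum[findInterval(d[ord] * (1 + 1e-7), d[ord])])
  lookup_lo <- support[1L]
  stat <- function(m, labels) {
    idx_a <- which(unclass(labels) == 1L)
    pv[sum(row_tot[idx_a]) - lookup_lo + 1L]
  }
  res <- permutation_test(stat, m, labels0, n_perm = n_perm, seed = seed,
                          tail = "lesser", keep_null = keep_null)
  res$statistic_name <- "Fisher (aggregated exact test p-value)"
  res
}
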