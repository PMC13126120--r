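test_that("global U components reproduce the hand-worked example", {
  d <- pairwise_distances(toy_matrix(), "hamming")
  u <- global_u_statistic(d, toy_labels())
  expect_equal(u$U_AA, 1)
  expect_equal(u$U_BB, 1)
  expect_equal(u$U_AB, (3 + 2 + 2 + 3) / 4)
  expect_equal(u$T_d, 2.5)
})

test_that("pseudo-F reproduces the hand-worked Jaccard example", {
  d <- pairwise_distances(toy_matrix(), "jaccard")
  # within: 0.5 and 0.5; between: 1, 2/3, 1, 1
  expect_equal(global_f_statistic(d, toy_labels()),
               mean(c(1, 2 / 3, 1, 1)) / 0.5, tolerance = 1e-10)
})

test_that("degenerate ratios follow the sentinel conventions", {
  sep <- binary_matrix(rbind(matrix(1, 2, 3), matrix(0, 2, 3)))
  lab <- balanced_labels(4)
  expect_identical(
    global_u_statistic(pairwise_distances(sep, "hamming"), lab)$T_d, Inf)
  const <- binary_matrix(matrix(rep(c(1, 0, 1), each = 4), 4, 3))
  expect_identical(
    global_u_statistic(pairwise_distances(const, "hamming"), lab)$T_d, 1)
  expect_identical(
    global_f_statistic(pairwise_distances(const, "jaccard"), lab), 1)
})

test_that("ratio statistics are invariant to exchanging the group names", {
  set.seed(3)
  for (i in 1:20) {
    m <- random_binary_matrix(8, 10)
    lab <- group_labels(sample(rep(c("A", "B"), 4)))
    swapped <- group_labels(as.character(lab), case = "B")
    for (metric in c("hamming", "jaccard")) {
      d <- pairwise_distances(m, metric)
      expect_equal(global_u_statistic(d, lab)$T_d,
                   global_u_statistic(d, swapped)$T_d)
    }
  }
})

test_that("PCA separation detects block structure and is sign-invariant", {
  # perfect block separation: PC1 carries the full centroid distance
  m <- binary_matrix(rbind(matrix(rep(c(1, 1, 0, 0), each = 4), 4),
                           matrix(rep(c(0, 0, 1, 1), each = 4), 4)))
  lab <- balanced_labels(8)
  s <- pca_separation(m, lab)
  expect_gt(s, 0)
  # independent SVD oracle: project centered rows on the top right singular
  # vector and compare centroid separation
  xc <- scale(unclass(m), center = TRUE, scale = FALSE)
  v1 <- svd(xc)$v[, 1]
  z <- xc %*% v1
  expect_equal(s, abs(mean(z[1:4]) - mean(z[5:8])), tolerance = 1e-10)
  # centroid distance is fully captured by PC1 for this rank-1 contrast
  centroid_dist <- sqrt(sum((colMeans(xc[1:4, ]) - colMeans(xc[5:8, ]))^2))
  expect_equal(s, centroid_dist, tolerance = 1e-10)
  # zero-variance matrix
  expect_identical(pca_separation(binary_matrix(matrix(1, 4, 3)),
                                  balanced_labels(4)), 0)
  expect_error(pca_separation(binary_matrix(matrix(1, 2, 3)),
                              balanced_labels(2)), "at least 3")
})

test_that("permutation p-values follow the (1 + exceed)/(R + 1) estimator", {
  # observed strictly above every null replicate
  z <- c(rep(1, 3), rep(0, 3))
  stat <- function(data, labels) {
    g <- grndiff:::group_split(labels)
    sum(data[g$a])  # maximized only at the observed labeling
  }
  res <- permutation_test(stat, z, balanced_labels(6), n_perm = 99, seed = 1,
                          keep_null = TRUE)
  expect_equal(res$p_perm, (1 + res$n_exceed) / 100)
  expect_gte(res$p_perm, 1 / 100)
  # constant statistic: every relabeling ties the observed value
  res_const <- permutation_test(function(d, l) 1, z, balanced_labels(6),
                                n_perm = 50, seed = 1)
  expect_identical(res_const$p_perm, 1)
  expect_error(permutation_test(function(d, l) 1, z, balanced_labels(6),
                                n_perm = 0), "positive")
})

test_that("identical seeds give identical permutation results", {
  sim <- simulate_grn("normal", gamma = 0.2, seed = 9)
  a <- global_u_test(sim$matrix, sim$labels, n_perm = 99, seed = 5,
                     keep_null = TRUE)
  b <- global_u_test(sim$matrix, sim$labels, n_perm = 99, seed = 5,
                     keep_null = TRUE)
  expect_identical(a$p_perm, b$p_perm)
  expect_identical(a$null_values, b$null_values)
  c <- global_u_test(sim$matrix, sim$labels, n_perm = 99, seed = 6,
                     keep_null = TRUE)
  expect_false(identical(a$null_values, c$null_values))
})

test_that("infinite sentinels compare consistently in the null", {
  sep <- binary_matrix(rbind(matrix(1, 2, 4), matrix(0, 2, 4)))
  res <- global_u_test(sep, balanced_labels(4), n_perm = 199, seed = 2,
                       keep_null = TRUE)
  expect_identical(res$observed, Inf)
  # relabelings reproducing a perfect split also give Inf and count as ties
  expect_identical(res$n_exceed, sum(res$null_values == Inf))
  expect_gt(res$p_perm, 0)
})

test_that("Monte-Carlo p-values converge to the exhaustive enumeration", {
  set.seed(21)
  ratio_stat <- function(d, labels) {
    g <- grndiff:::group_split(labels)
    grndiff:::dissimilarity_components(d, g$a, g$b)$T_d
  }
  for (n in c(4, 6)) {
    m <- random_binary_matrix(n, 6, p = 0.4)
    lab <- balanced_labels(n)
    d <- pairwise_distances(m, "hamming")
    p_exact <- enumeration_pvalue(ratio_stat, d, lab, "greater")
    res <- global_u_test(d, lab, n_perm = 4000, seed = 11)
    # (1 + k)/(R + 1) estimates the inclusive enumeration p
    expect_equal(res$p_perm, p_exact, tolerance = 0.05)
  }
})

test_that("cached-distance engine is bit-identical to naive recomputation", {
  set.seed(13)
  for (i in 1:5) {
    n <- 8
    sim <- simulate_grn("normal", G = 12, N = n, n_case = 4, gamma = 0.25,
                        seed = 100 + i)
    lab <- sim$labels
    for (metric in c("hamming", "jaccard")) {
      cached_stat <- function(d, labels) {
        g <- grndiff:::group_split(labels)
        grndiff:::dissimilarity_components(d, g$a, g$b)$T_d
      }
      naive_stat <- function(m, labels) {
        # recompute all pairwise distances from scratch each replicate
        d <- pairwise_distances(m, metric)
        g <- grndiff:::group_split(labels)
        grndiff:::dissimilarity_components(d, g$a, g$b)$T_d
      }
      d <- pairwise_distances(sim$matrix, metric)
      a <- permutation_test(cached_stat, d, lab, n_perm = 200, seed = 31)
      b <- permutation_test(naive_stat, sim$matrix, lab, n_perm = 200, seed = 31)
      expect_identical(a$observed, b$observed)
      expect_identical(a$n_exceed, b$n_exceed)
      expect_identical(a$p_perm, b$p_perm)
    }
  }
})

test_that("T_d and F* increase under mean-shift contamination of one group", {
  set.seed(17)
  for (i in 1:10) {
    m <- matrix(rbinom(20 * 30, 1, 0.15), 20, 30)
    lab <- balanced_labels(20)
    shifted <- m
    shifted[1:10, 1:10] <- 1L  # activate a block in group A
    for (metric in c("hamming", "jaccard")) {
      d0 <- pairwise_distances(binary_matrix(m), metric)
      d1 <- pairwise_distances(binary_matrix(shifted), metric)
      expect_gt(global_f_statistic(d1, lab), global_f_statistic(d0, lab))
    }
  }
})
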