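test_that("per-feature Mann-Whitney matches the rank-sum oracle", {
  # perfect 2v2 split, hand-checkable via exhaustive midranks
  m <- binary_matrix(matrix(c(1, 1, 0, 0), ncol = 1))
  lab <- balanced_labels(4)
  p <- mann_whitney_per_feature(m, lab)
  oracle <- suppressWarnings(
    stats::wilcox.test(c(1, 1), c(0, 0), exact = FALSE, correct = FALSE)$p.value)
  expect_equal(unname(p), oracle, tolerance = 1e-12)
  # equal rank sums across groups: centered statistic is exactly 0
  m2 <- binary_matrix(matrix(c(1, 0, 0, 1), ncol = 1))
  lab2 <- group_labels(c("A", "B", "A", "B"))
  expect_equal(unname(mann_whitney_per_feature(m2, lab2)), 1)
  # constant features carry no rank information
  m3 <- binary_matrix(cbind(rep(0, 6), rep(1, 6)))
  expect_equal(unname(mann_whitney_per_feature(m3, balanced_labels(6))), c(1, 1))
})

test_that("per-feature Mann-Whitney agrees with wilcox.test on random data", {
  set.seed(5)
  for (i in 1:20) {
    n_a <- sample(2:8, 1); n_b <- sample(2:8, 1)
    m <- random_binary_matrix(n_a + n_b, 15, p = runif(1, 0.2, 0.8))
    lab <- group_labels(rep(c("A", "B"), c(n_a, n_b)))
    mine <- mann_whitney_per_feature(m, lab)
    for (g in seq_len(ncol(m))) {
      x <- m[seq_len(n_a), g]; y <- m[n_a + seq_len(n_b), g]
      expected <- if (length(unique(c(x, y))) == 1L) 1 else {
        suppressWarnings(
          stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
      }
      expect_equal(unname(mine[g]), expected, tolerance = 1e-12)
    }
  }
})

test_that("the per-feature decision is monotone in the 2x2 split", {
  # for fixed total activation, p decreases as the split grows more uneven
  n_a <- n_b <- 10
  for (t in c(4, 10, 16)) {
    a_grid <- max(0, t - n_b):min(n_a, t)
    p <- grndiff:::mw_binary_pvalue(a_grid, t, n_a, n_b)
    imbalance <- abs(a_grid / n_a - (t - a_grid) / n_b)
    expect_true(all(diff(p[order(imbalance)]) <= 1e-12))
  }
})

test_that("fisher_combine matches closed forms and its algebraic properties", {
  expect_identical(fisher_combine(c(1, 1, 1)), 0)
  expect_equal(fisher_combine(c(0.1, 0.1)), -4 * log(0.1), tolerance = 1e-10)
  expect_equal(fisher_combine(0.05), -2 * log(0.05), tolerance = 1e-10)
  set.seed(2)
  p <- runif(10)
  expect_equal(fisher_combine(p), fisher_combine(rev(p)))
  expect_equal(fisher_combine(c(p, p[1:3])),
               fisher_combine(p) + fisher_combine(p[1:3]))
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
  expect_error(fisher_combine(numeric(0)), "non-empty")
  # clamping keeps the statistic finite
  expect_lt(fisher_combine(c(1e-320, 0.5)), Inf)
})

test_that("aggregate_counts sums actives and inactives exactly", {
  m <- binary_matrix(rbind(c(1, 1), c(0, 1)))
  lab <- group_labels(c("A", "B"))
  tab <- aggregate_counts(m, lab)
  expect_identical(unname(tab["A", ]), c(2L, 0L))
  expect_identical(unname(tab["B", ]), c(1L, 1L))
  zero <- binary_matrix(matrix(0, 4, 3))
  tz <- aggregate_counts(zero, balanced_labels(4))
  expect_identical(unname(tz[, "active"]), c(0L, 0L))
  expect_identical(unname(tz[, "inactive"]), c(6L, 6L))
  set.seed(8)
  for (i in 1:20) {
    m <- random_binary_matrix(6, 5)
    tab <- aggregate_counts(m, balanced_labels(6))
    expect_identical(as.integer(rowSums(tab)), c(15L, 15L))  # n_group * G
  }
})

test_that("fisher_exact_pvalue matches enumeration and fisher.test", {
  expect_equal(fisher_exact_pvalue(matrix(c(2, 1, 0, 1), 2)), 1)
  expect_equal(fisher_exact_pvalue(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_pvalue(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:100) {
    tab <- matrix(rpois(4, sample(c(3, 15, 40), 1)), 2)
    expect_equal(fisher_exact_pvalue(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("local_u_test recovers a maximal separation at the smallest p", {
  m <- binary_matrix(cbind(rep(c(1, 0), c(10, 10)))[, rep(1, 5)])
  lab <- balanced_labels(20)
  res <- local_u_test(m, lab, n_perm = 199, seed = 4)
  expect_equal(res$p_perm, 1 / 200)
})

test_that("local_u_test on one feature reduces to the single-feature test", {
  set.seed(9)
  m <- random_binary_matrix(12, 1, p = 0.5)
  lab <- balanced_labels(12)
  res <- local_u_test(m, lab, n_perm = 300, seed = 14, keep_null = TRUE)
  expect_equal(res$observed,
               fisher_combine(mann_whitney_per_feature(m, lab)),
               tolerance = 1e-12)
  # monotone transform of the single p-value: same exceedance count as
  # testing the per-feature p directly with the lesser tail
  direct <- permutation_test(
    function(m, l) unname(mann_whitney_per_feature(m, l)),
    m, lab, n_perm = 300, seed = 14, tail = "lesser")
  expect_identical(res$n_exceed, direct$n_exceed)
})

test_that("local_u lookup path is bit-identical to naive full recomputation", {
  set.seed(10)
  for (i in 1:5) {
    sim <- simulate_grn("normal", G = 10, N = 10, n_case = 5, gamma = 0.3,
                        seed = 300 + i)
    naive_stat <- function(m, labels) {
      fisher_combine(mann_whitney_per_feature(m, labels))
    }
    a <- local_u_test(sim$matrix, sim$labels, n_perm = 150, seed = 77)
    b <- permutation_test(naive_stat, sim$matrix, sim$labels,
                          n_perm = 150, seed = 77)
    expect_identical(a$observed, b$observed)
    expect_identical(a$n_exceed, b$n_exceed)
  }
})

test_that("aggregated Fisher permutation test behaves per its contract", {
  # all samples identical: the table is invariant under relabeling
  m <- binary_matrix(matrix(rep(c(1, 0), each = 4), 4, 2))
  res <- global_fisher_test(m, balanced_labels(4), n_perm = 99, seed = 3)
  expect_identical(res$p_perm, 1)
  # observed statistic equals the exact Fisher p of the aggregated table
  set.seed(15)
  sim <- simulate_grn("normal", gamma = 0.3, seed = 6)
  res2 <- global_fisher_test(sim$matrix, sim$labels, n_perm = 99, seed = 8)
  expect_equal(res2$observed,
               fisher_exact_pvalue(aggregate_counts(sim$matrix, sim$labels)),
               tolerance = 1e-9)
})

test_that("aggregated Fisher p_perm converges to the enumeration oracle", {
  set.seed(19)
  m <- binary_matrix(rbind(c(1, 1, 1), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0)))
  lab <- balanced_labels(4)
  stat <- function(m, labels) {
    fisher_exact_pvalue(aggregate_counts(m, labels))
  }
  p_exact <- enumeration_pvalue(stat, m, lab, "lesser")
  res <- global_fisher_test(m, lab, n_perm = 4000, seed = 23)
  expect_equal(res$p_perm, p_exact, tolerance = 0.05)
})
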