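# Shared fixtures and independent oracles used across test files.

# report every failure across the whole suite rather than stopping at the
# progress reporter's default cap
options(testthat.progress.max_fails = 10000)

# 2x2 toy from the worked examples: A = {110, 100}, B = {001, 011}
toy_matrix <- function() {
  binary_matrix(rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1), c(0, 1, 1)),
                sample_ids = paste0("S", 1:4))
}

toy_labels <- function() {
  group_labels(stats::setNames(c("A", "A", "B", "B"), paste0("S", 1:4)))
}

random_binary_matrix <- function(n, g, p = 0.3) {
  binary_matrix(matrix(stats::rbinom(n * g, 1, p), n, g))
}

balanced_labels <- function(n) {
  group_labels(rep(c("A", "B"), each = n / 2))
}

# Exhaustive permutation p-value over all distinct A/B assignments with the
# observed group sizes (the enumeration oracle for small N). Every
# assignment, including the observed one, contributes to the null, mirroring
# the (1 + #exceed)/(R + 1) estimator's inclusion of the identity.
enumeration_pvalue <- function(statistic, data, labels,
                               tail = c("greater", "lesser")) {
  tail <- match.arg(tail)
  n <- length(labels)
  n_a <- sum(unclass(labels) == 1L)
  observed <- statistic(data, labels)
  combos <- utils::combn(n, n_a)
  null_values <- apply(combos, 2L, function(idx) {
    lab <- rep(levels(labels)[2L], n)
    lab[idx] <- levels(labels)[1L]
    statistic(data, group_labels(lab, case = levels(labels)[1L]))
  })
  if (tail == "greater") mean(null_values >= observed)
  else mean(null_values <= observed)
}

# Rejection rates over simulated datasets; methods share each dataset.
simulated_pvalues <- function(scenario, gamma, methods, n_reps, n_perm, seed) {
  p <- matrix(NA_real_, n_reps, length(methods), dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    sim <- if (scenario == "null") {
      simulate_grn("null", seed = seed + r)
    } else {
      simulate_grn(scenario, gamma = gamma, seed = seed + r)
    }
    fit <- grn_test(sim, methods = methods, n_perm = n_perm, seed = seed + 500000 + r)
    p[r, ] <- fit$table$p_perm
  }
  p
}
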