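#' Test a binary regulatory matrix for group differences
#'
#' The central fitting interface of the package: runs any subset of the
#' five complementary group-difference tests on one TF's binary
#' target-by-sample matrix and collects the results. The three global
#' tests (\code{global_u}, \code{global_f}, \code{pca}) target distributed
#' or coordinated shifts across many features; the two feature-level tests
#' (\code{local_u}, \code{fisher}) target localized changes and overall
#' activation burden. All five share the same label-permutation
#' significance engine (\code{\link{permutation_test}}).
#'
#' @param x a \code{\link{binary_matrix}} (samples as rows), a plain 0/1
#'   matrix, or a \code{\link{simulate_grn}} result.
#' @param labels a \code{\link{group_labels}} vector; may be omitted when
#'   \code{x} is a simulated dataset.
#' @param methods character vector from \code{c("global_u", "global_f",
#'   "pca", "local_u", "fisher")}, or \code{"all"}.
#' @param n_perm permutation replicates per test; default 2000.
#' @param seed integer seed; each method receives a deterministic seed
#'   derived from it.
#' @param keep_null store each test's null statistic values.
#' @return An object of class \code{"grn_test"}: a list with a results
#'   data frame (\code{$table}: method, observed, n_perm, p_perm, seed)
#'   and the individual \code{\link{permutation_test}} objects
#'   (\code{$tests}).
#' @examples
#' sim <- simulate_grn("normal", gamma = 0.25, seed = 7)
#' fit <- grn_test(sim, n_perm = 199, seed = 7)
#' fit
#' @export
grn_test <- function(x, labels = NULL,
                     methods = "all", n_perm = 2000L, seed = NULL,
                     keep_null = FALSE) {
  if (inherits(x, "sim_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$matrix
  }
  if (is.null(labels)) stop("'labels' is required unless 'x' is a simulated dataset")
  m <- as_binary_matrix(x)
  labels <- align_labels(m, labels)
  methods <- resolve_methods(methods)
  seed <- resolve_seed(seed)

  tests <- vector("list", length(methods))
  names(tests) <- methods
  for (i in seq_along(methods)) {
    tests[[i]] <- run_method(methods[i], m, labels, n_perm,
                             seed = derive_seed(seed, i), keep_null = keep_null)
  }
  table <- data.frame(
    method = methods,
    observed = vapply(tests, function(t) t$observed, numeric(1)),
    n_perm = vapply(tests, function(t) t$n_perm, integer(1)),
    p_perm = vapply(tests, function(t) t$p_perm, numeric(1)),
    seed = vapply(tests, function(t) t$seed, integer(1)),
    row.names = NULL
  )
  structure(list(table = table, tests = tests, n_A = sum(unclass(labels) == 1L),
                 n_B = sum(unclass(labels) == 2L), G = ncol(m), seed = seed),
            class = "grn_test")
}

all_methods <- c("global_u", "global_f", "pca", "local_u", "fisher")

resolve_methods <- function(methods) {
  if (identical(methods, "all")) return(all_methods)
  bad <- setdiff(methods, all_methods)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(all_methods, collapse = ", "), ")")
  }
  unique(methods)
}

run_method <- function(method, m, labels, n_perm, seed, keep_null = FALSE) {
  switch(method,
    global_u = global_u_test(m, labels, n_perm, seed, keep_null),
    global_f = global_f_test(m, labels, n_perm, seed, keep_null),
    pca      = pca_test(m, labels, n_perm, seed, keep_null),
    local_u  = local_u_test(m, labels, n_perm, seed, keep_null),
    fisher   = global_fisher_test(m, labels, n_perm, seed, keep_null)
  )
}

# Deterministic per-invocation seed stream, kept within 32-bit range.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 16807) %% 2147483647)
}

#' @export
print.grn_test <- function(x, ...) {
  cat(sprintf("Group-difference tests on a binary regulatory matrix (%d x %d, n_A = %d, n_B = %d)\n",
              x$n_A + x$n_B, x$G, x$n_A, x$n_B))
  tab <- x$table
  tab$observed <- signif(tab$observed, 4)
  print(tab[, c("method", "observed", "n_perm", "p_perm")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.grn_test <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  tab$significant <- tab$p_perm <= alpha
  structure(list(table = tab, alpha = alpha), class = "summary.grn_test")
}

#' @export
print.summary.grn_test <- function(x, ...) {
  tab <- x$table
  tab$observed <- signif(tab$observed, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("significance at alpha = %g (permutation p-values)\n", x$alpha))
  invisible(x)
}
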