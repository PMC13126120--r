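#' Empirical rejection rate
#'
#' The fraction of p-values at or below a significance threshold: power
#' under an alternative, type-I error under the null.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param alpha significance threshold in (0, 1).
#' @return The rejection rate in [0, 1].
#' @export
empirical_power <- function(pvals, alpha) {
  if (length(pvals) == 0L) stop("'pvals' must be non-empty")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (is.na(alpha) || alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  mean(pvals <= alpha)
}

#' Empirical power study over scenarios, methods and signal fractions
#'
#' Runs the full simulation benchmark: for every combination of scenario
#' and signal fraction it simulates \code{n_reps} datasets, applies each
#' requested test with \code{n_perm} label permutations, and tabulates the
#' rejection rate at each significance threshold. All methods within a
#' repetition share the same simulated dataset (a paired design that
#' removes between-method simulation noise); every repetition receives a
#' deterministic seed derived from \code{seed}, so any single cell can be
#' recomputed in isolation.
#'
#' The default grid mirrors the benchmark conditions: G = 80 features,
#' N = 40 samples split 20/20, signal fractions 0.05 to 0.30, 500
#' repetitions of 2000 permutations, thresholds \{0.05, 0.01, 0.005\}.
#' Smaller \code{n_reps}/\code{n_perm} give faster, noisier estimates; the
#' values used are recorded in every output row.
#'
#' @param scenarios character vector of scenario names (see
#'   \code{\link{simulate_grn}}).
#' @param gammas numeric vector of signal fractions; for \code{"null"} a
#'   single placeholder cell is run (gamma is not meaningful).
#' @param methods character vector of test names, or \code{"all"}.
#' @param n_reps simulated datasets per cell; default 500.
#' @param n_perm permutations per test; default 2000.
#' @param alphas significance thresholds; default \code{c(0.05, 0.01, 0.005)}.
#' @param seed study seed (integer).
#' @param ... further arguments (\code{G}, \code{N}, \code{p_hi}, ...)
#'   passed to \code{\link{simulate_grn}}.
#' @return A data frame of class \code{"power_table"} with columns
#'   scenario, method, gamma, alpha, power, n_reps, n_perm, seed.
#' @examples
#' pt <- power_study("normal", gammas = 0.25, methods = "global_u",
#'                   n_reps = 20, n_perm = 99, seed = 1)
#' pt
#' @export
power_study <- function(scenarios, gammas = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                        methods = "all", n_reps = 500L, n_perm = 2000L,
                        alphas = c(0.05, 0.01, 0.005), seed = 1L, ...) {
  methods <- resolve_methods(methods)
  seed <- resolve_seed(seed)
  n_reps <- as.integer(n_reps)
  n_perm <- as.integer(n_perm)
  rows <- list()
  cell <- 0L
  for (sc in scenarios) {
    g_grid <- if (sc == "null") NA_real_ else gammas
    for (gm in g_grid) {
      cell <- cell + 1L
      p <- power_cell(sc, gm, methods, n_reps, n_perm,
                      seed = derive_seed(seed, cell * 100003L), ...)
      for (me in methods) {
        for (al in alphas) {
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = sc, method = me, gamma = gm, alpha = al,
            power = empirical_power(p[, me], al),
            n_reps = n_reps, n_perm = n_perm, seed = seed)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_table", class(out))
  out
}

# One scenario x gamma cell: matrix of p-values (n_reps x methods).
power_cell <- function(scenario, gamma, methods, n_reps, n_perm, seed, ...) {
  p <- matrix(NA_real_, n_reps, length(methods),
              dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, r)
    sim <- if (scenario == "null") {
      simulate_grn("null", seed = rep_seed, ...)
    } else {
      simulate_grn(scenario, gamma = gamma, seed = rep_seed, ...)
    }
    for (j in seq_along(methods)) {
      res <- run_method(methods[j], sim$matrix, sim$labels, n_perm,
                        seed = derive_seed(rep_seed, j))
      p[r, j] <- res$p_perm
    }
  }
  p
}

#' Plot a power table
#'
#' Line plot of empirical power against signal fraction, one panel per
#' scenario/alpha combination, one line per method.
#'
#' @param x a \code{\link{power_study}} result.
#' @param ... passed to \code{\link[graphics]{matplot}}.
#' @return \code{x}, invisibly.
#' @export
plot.power_table <- function(x, ...) {
  cells <- unique(x[, c("scenario", "alpha")])
  methods <- unique(x$method)
  old <- graphics::par(mfrow = grDevices::n2mfrow(nrow(cells)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (i in seq_len(nrow(cells))) {
    sub <- x[x$scenario == cells$scenario[i] & x$alpha == cells$alpha[i], ]
    gam <- sort(unique(sub$gamma))
    mat <- sapply(methods, function(me)
      sub$power[sub$method == me][order(sub$gamma[sub$method == me])])
    mat <- matrix(mat, nrow = length(gam), dimnames = list(NULL, methods))
    graphics::matplot(gam, mat, type = "b", pch = 1, lty = 1, ylim = c(0, 1),
                      xlab = "signal fraction", ylab = "power",
                      main = sprintf("%s (alpha = %g)", cells$scenario[i],
                                     cells$alpha[i]), ...)
    graphics::legend("bottomright", legend = methods, col = seq_along(methods),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
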