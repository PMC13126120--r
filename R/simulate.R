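#' Simulate a binary regulatory matrix under one of five scenarios
#'
#' Generates a synthetic TF target-by-sample activation matrix with the
#' group structure of one of five benchmark scenarios, emulating the kinds
#' of signal observed in per-donor regulatory networks inferred from
#' single-cell data:
#'
#' \describe{
#'   \item{normal}{Sparse unidirectional activation: a fraction
#'     \code{gamma} of features are active with probability \code{p_hi}
#'     (default 0.3) in the case group and \code{p_lo} (default 0.05) in
#'     controls; all remaining features follow the shared background rate
#'     \code{p_bg} (default 0.1) in both groups.}
#'   \item{balanced}{Bidirectional signal: of the \code{round(gamma * G)}
#'     signal features, \code{ceiling(s/2)} are biased toward the case
#'     group (\code{p_hi}/\code{p_lo}) and \code{floor(s/2)} toward
#'     controls (\code{p_lo}/\code{p_hi}); background as in normal.}
#'   \item{noisy}{A normal-scenario matrix contaminated with spurious
#'     activations: each entry is OR-ed with an independent
#'     Bernoulli(\code{p_noise}) draw (noise only ever switches entries
#'     on, never off).}
#'   \item{coordinated}{Modular co-regulation: each case sample draws one
#'     shared indicator from Bernoulli(\code{p_hi}) and every signal
#'     feature of that sample takes that value, so signal features are
#'     perfectly correlated within the case group; control signal entries
#'     and all background entries are independent Bernoulli(\code{p_bg}).}
#'   \item{null}{No group structure: every entry is an independent
#'     Bernoulli(\code{p_bg}) draw; the set of signal features is empty.}
#' }
#'
#' After generation the feature columns are randomly shuffled (and the
#' signal index set updated) so that signal position carries no
#' information. The first \code{n_case} samples are the case group.
#'
#' @param scenario one of \code{"normal"}, \code{"balanced"},
#'   \code{"noisy"}, \code{"coordinated"}, \code{"null"}.
#' @param G number of features (TF-target links); default 80.
#' @param N number of samples; default 40.
#' @param n_case number of case samples; default \code{N / 2}.
#' @param gamma signal fraction in (0, 1); \code{round(gamma * G)} features
#'   carry signal (ignored for \code{"null"}).
#' @param p_hi activation probability of signal features in their favoured
#'   group; default 0.3.
#' @param p_lo activation probability of signal features in the other
#'   group; default 0.05.
#' @param p_bg background activation probability; default 0.1.
#' @param p_noise spurious-activation rate for the noisy scenario;
#'   default 0.05.
#' @param seed integer seed; drawn from the session RNG when \code{NULL}.
#' @return A list of class \code{"sim_dataset"}: \code{matrix} (a
#'   \code{\link{binary_matrix}}, samples as rows), \code{labels}
#'   (\code{\link{group_labels}}, case level \code{"A"}),
#'   \code{signal_features} (integer column indices after shuffling),
#'   \code{scenario}, and \code{seed}.
#' @examples
#' sim <- simulate_grn("coordinated", gamma = 0.05, seed = 42)
#' table(sim$matrix[sim$labels == "A", sim$signal_features])
#' @export
simulate_grn <- function(scenario = c("normal", "balanced", "noisy",
                                      "coordinated", "null"),
                         G = 80L, N = 40L, n_case = N / 2,
                         gamma = 0.05, p_hi = 0.3, p_lo = 0.05,
                         p_bg = 0.1, p_noise = 0.05, seed = NULL) {
  scenario <- match.arg(scenario)
  G <- as.integer(G)
  N <- as.integer(N)
  n_case <- as.integer(n_case)
  stopifnot(G >= 1L, N >= 2L, n_case >= 1L, n_case < N)
  for (p in c(p_hi, p_lo, p_bg, p_noise)) {
    if (is.na(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  n_ctl <- N - n_case
  if (scenario != "null") {
    if (is.na(gamma) || gamma <= 0 || gamma >= 1) {
      stop("'gamma' must lie in (0, 1)")
    }
    s <- round_half_up(gamma * G)
    if (s < 1L) stop("round(gamma * G) must be at least 1")
  } else {
    s <- 0L
  }

  seed <- resolve_seed(seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  # shuffle drawn before the entries: a noisy draw at the same seed then
  # shares its base matrix (and column order) with the normal draw
  shuffle <- sample.int(G)
  x <- matrix(stats::rbinom(N * G, 1L, p_bg), nrow = N, ncol = G)
  signal <- seq_len(s)

  if (scenario %in% c("normal", "noisy")) {
    x[seq_len(n_case), signal] <- stats::rbinom(n_case * s, 1L, p_hi)
    x[n_case + seq_len(n_ctl), signal] <- stats::rbinom(n_ctl * s, 1L, p_lo)
  } else if (scenario == "balanced") {
    s_up <- ceiling(s / 2)     # biased toward the case group
    up <- signal[seq_len(s_up)]
    dn <- setdiff(signal, up)  # biased toward controls
    x[seq_len(n_case), up] <- stats::rbinom(n_case * length(up), 1L, p_hi)
    x[n_case + seq_len(n_ctl), up] <- stats::rbinom(n_ctl * length(up), 1L, p_lo)
    x[seq_len(n_case), dn] <- stats::rbinom(n_case * length(dn), 1L, p_lo)
    x[n_case + seq_len(n_ctl), dn] <- stats::rbinom(n_ctl * length(dn), 1L, p_hi)
  } else if (scenario == "coordinated") {
    shared <- stats::rbinom(n_case, 1L, p_hi)
    x[seq_len(n_case), signal] <- shared  # recycled column-wise: one value per sample
    # control signal entries stay at the background rate already drawn
  }
  if (scenario == "noisy") {
    x <- (x == 1L) | (matrix(stats::rbinom(N * G, 1L, p_noise), N, G) == 1L)
    x <- x + 0L
  }

  x <- x[, shuffle, drop = FALSE]
  signal_features <- which(shuffle %in% signal)

  out <- list(
    matrix = binary_matrix(x,
                           sample_ids = paste0("S", seq_len(N)),
                           feature_ids = paste0("g", seq_len(G))),
    labels = group_labels(rep(c("A", "B"), c(n_case, n_ctl)), case = "A"),
    signal_features = signal_features,
    scenario = scenario,
    seed = seed
  )
  names(out$labels) <- paste0("S", seq_len(N))
  class(out) <- "sim_dataset"
  out
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: scenario '%s', %d samples x %d features, %d signal features (seed %d)\n",
              x$scenario, nrow(x$matrix), ncol(x$matrix),
              length(x$signal_features), x$seed))
  invisible(x)
}
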