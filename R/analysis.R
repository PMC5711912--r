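# Post-hoc analyses of lifetime learning: mutual information conveyed by a
# probability table and its change over a lifetime, frozen-feedback
# controls, gate census, and action-usage profiles.

#' Mutual information conveyed by a probability table
#'
#' Treats the rows of a row-stochastic table as conditional output
#' distributions and computes \eqn{I(I;O) = H(O) - H(O|I)} in bits. The
#' input marginal is uniform over all rows by default (rows of input
#' patterns the agent never experienced still enter the average); an
#' empirical marginal can be supplied as `input_weights`.
#'
#' @param P row-stochastic numeric matrix.
#' @param input_weights optional non-negative weights over rows (normalized
#'   internally), e.g. input-pattern visit counts.
#' @return mutual information in bits.
#' @examples
#' table_mutual_information(matrix(0.25, 4, 4)) # 0: output independent of input
#' table_mutual_information(diag(4))            # 2 bits: deterministic bijection
#' @export
table_mutual_information <- function(P, input_weights = NULL) {
  P <- as.matrix(P)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("P must be row-stochastic")
  }
  w <- input_weights %||% rep(1, nrow(P))
  if (length(w) != nrow(P) || any(w < 0) || sum(w) <= 0) {
    stop("invalid input weights")
  }
  w <- w / sum(w)
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  py <- colSums(P * w)
  h_out <- -sum(plogp(py))
  h_cond <- -sum(w * rowSums(plogp(P)))
  max(h_out - h_cond, 0)
}

#' Mean lifetime change in feedback-table mutual information
#'
#' For each snapshot pair (a feedback gate's table at birth and at the end
#' of the task on one mapping) computes `MI(P_end) - MI(P_birth)` and
#' averages over all pairs: the quantity written \eqn{\bar\Delta}. Positive
#' values mean the gate's table conveys more information about its inputs at
#' death than at birth.
#'
#' @param pairs list of pairs, each a list with `P_birth` and `P_end`
#'   (matrices of identical shape); [fitness()] with
#'   `collect_tables = TRUE` produces them (see [snapshot_pairs()]).
#' @param input_weights optional row weights passed to
#'   [table_mutual_information()].
#' @return mean MI change in bits.
#' @export
delta_mi <- function(pairs, input_weights = NULL) {
  if (length(pairs) == 0L) stop("no snapshot pairs")
  d <- vapply(pairs, function(p) {
    if (!all(dim(p$P_birth) == dim(p$P_end))) {
      stop("snapshot pair shape mismatch")
    }
    table_mutual_information(p$P_end, input_weights) -
      table_mutual_information(p$P_birth, input_weights)
  }, 0)
  mean(d)
}

#' Flatten fitness snapshots into gate-by-mapping table pairs
#'
#' @param fit an `mb_fitness` evaluated with `collect_tables = TRUE`.
#' @return a flat list of `P_birth`/`P_end` pairs (one per feedback gate per
#'   mapping).
#' @export
snapshot_pairs <- function(fit) {
  stopifnot(inherits(fit, "mb_fitness"))
  if (is.null(fit$snapshots)) stop("fitness was not run with collect_tables")
  do.call(c, lapply(fit$snapshots, unname))
}

#' Frozen-feedback control evaluation
#'
#' Re-evaluates a brain with its feedback gates kept from changing their
#' probability tables, then restores the learning switch. Comparing this
#' with the normal evaluation measures how much of the agent's performance
#' depends on lifetime learning rather than on working memory alone.
#'
#' @inheritParams fitness
#' @return an `mb_fitness` from the frozen evaluation.
#' @export
frozen_performance <- function(brain, T = 512L, b = 512, seed = NULL, ...) {
  was <- feedback_enabled(brain)
  set_feedback_enabled(brain, FALSE)
  on.exit({
    set_feedback_enabled(brain, was)
    reset_brain(brain)
  })
  fitness(brain, T = T, b = b, seed = seed, ...)
}

#' Count gates by kind
#'
#' @param brain an `mb_brain`.
#' @return named integer vector with `deterministic`, `probabilistic`,
#'   `feedback` counts.
#' @export
gate_census <- function(brain) {
  kinds <- vapply(brain$gates, `[[`, "", "kind")
  vapply(setNames(.mb_gate_kinds, .mb_gate_kinds),
         function(k) sum(kinds == k), 0L)
}

#' Action-usage profile
#'
#' Computes, per trace, the fraction of forward, do-nothing and turn
#' commands (left and right turns pooled), optionally averaged within
#' generations.
#'
#' @param traces either a list of action vectors (integer codes 0--3 or the
#'   action words), or a numeric matrix of action counts with columns
#'   forward, nothing, turn-left, turn-right (e.g. the `action_counts` of an
#'   `mb_fitness`).
#' @param generation optional integer vector (one per trace/row) to average
#'   within.
#' @return a data frame with columns `generation` (if given), `forward`,
#'   `nothing`, `turn`; proportions sum to 1 in every row.
#' @export
action_usage <- function(traces, generation = NULL) {
  if (is.list(traces) && !is.data.frame(traces)) {
    counts <- t(vapply(traces, function(tr) {
      if (is.character(tr)) tr <- match(tr, .actions) - 1L
      tabulate(as.integer(tr) + 1L, nbins = 4L)
    }, numeric(4)))
  } else {
    counts <- as.matrix(traces)
  }
  if (ncol(counts) != 4L) stop("expected 4 action classes")
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop("empty trace")
  prop <- data.frame(forward = counts[, 1] / tot, nothing = counts[, 2] / tot,
                     turn = (counts[, 3] + counts[, 4]) / tot)
  if (is.null(generation)) return(prop)
  agg <- aggregate(prop, by = list(generation = generation), FUN = mean)
  agg[order(agg$generation), ]
}

#' Bin lifetime MI change by performance and correlate
#'
#' Bins performance (mean goals reached per mapping) into unit-width bins
#' spanning the observed range, computes the mean and variance of
#' \eqn{\bar\Delta} within each bin, and the Pearson correlation between bin
#' centers and bin means.
#'
#' @param performance numeric vector of per-agent performances.
#' @param delta numeric vector of per-agent \eqn{\bar\Delta} values.
#' @return a list with `bins` (data frame: bin_lo, bin_hi, center, n,
#'   mean_delta, var_delta) and `r` (Pearson correlation over non-empty
#'   bins).
#' @export
binned_delta_vs_performance <- function(performance, delta) {
  stopifnot(length(performance) == length(delta))
  if (length(unique(performance)) < 2L) {
    stop("correlation undefined: fewer than 2 distinct performance values")
  }
  lo <- floor(min(performance))
  hi <- ceiling(max(performance))
  if (hi == lo) hi <- lo + 1
  edges <- seq(lo, hi, by = 1)
  idx <- findInterval(performance, edges, rightmost.closed = TRUE)
  bins <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  bins$center <- (bins$bin_lo + bins$bin_hi) / 2
  bins$n <- vapply(seq_len(nrow(bins)), function(k) sum(idx == k), 0L)
  bins$mean_delta <- vapply(seq_len(nrow(bins)), function(k) {
    if (bins$n[k] > 0) mean(delta[idx == k]) else NA_real_
  }, 0)
  bins$var_delta <- vapply(seq_len(nrow(bins)), function(k) {
    if (bins$n[k] > 1) var(delta[idx == k]) else NA_real_
  }, 0)
  use <- bins$n > 0
  if (sum(use) < 2L || var(bins$mean_delta[use]) == 0) {
    stop("correlation undefined: degenerate binned means")
  }
  list(bins = bins, r = cor(bins$center[use], bins$mean_delta[use]))
}
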