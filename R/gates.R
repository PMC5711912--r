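# Logic gates: deterministic, probabilistic, and feedback. Gates carry
# lifetime state (probability tables, decision buffers), so they are
# represented as environments and the operations below mutate them in place,
# mirroring the compiled engine's semantics.

.P_LO <- 0.01
.P_HI <- 0.99
.ROW_TOL <- 1e-9

.check_nodes <- function(x, what, n_nodes) {
  x <- as.integer(x)
  if (length(x) < 1L || length(x) > 4L) {
    stop(what, " must list between 1 and 4 nodes")
  }
  if (any(x < 0L) || any(x >= n_nodes)) {
    stop(what, " indices must be in [0, ", n_nodes - 1L, "]")
  }
  x
}

.new_gate <- function(kind, input_nodes, output_nodes, n_nodes) {
  g <- new.env(parent = emptyenv())
  g$kind <- kind
  g$input_nodes <- .check_nodes(input_nodes, "input_nodes", n_nodes)
  g$output_nodes <- .check_nodes(output_nodes, "output_nodes", n_nodes)
  class(g) <- c(paste0("mb_gate_", kind), "mb_gate")
  g
}

#' Construct a deterministic logic gate
#'
#' Maps every input pattern to exactly one output pattern via a logic table.
#' Patterns are integers: bit `k` of a pattern is the state of the `k`-th
#' listed node (first node = least significant bit). Node indices are
#' 0-based.
#'
#' @param input_nodes,output_nodes 1--4 node indices each, in `[0, 15]`.
#' @param table integer vector of length `2^n_inputs`, entry `i + 1` giving
#'   the output pattern (in `[0, 2^n_outputs)`) for input pattern `i`.
#' @param n_nodes number of brain nodes (default 16).
#' @return an `mb_gate` environment.
#' @export
deterministic_gate <- function(input_nodes, output_nodes, table,
                               n_nodes = 16L) {
  g <- .new_gate("deterministic", input_nodes, output_nodes, n_nodes)
  table <- as.integer(table)
  rows <- 2L^length(g$input_nodes)
  cols <- 2L^length(g$output_nodes)
  if (length(table) != rows) stop("table must have one entry per input pattern")
  if (any(table < 0L) || any(table >= cols)) stop("table entries out of range")
  g$table <- table
  g
}

.check_prob_table <- function(P, rows, cols) {
  P <- as.matrix(P)
  if (nrow(P) != rows || ncol(P) != cols) stop("probability table shape mismatch")
  if (any(P < 0) || any(P > 1)) stop("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop("each table row must sum to 1")
  unname(P)
}

#' Construct a probabilistic logic gate
#'
#' Row `i + 1` of `table` is the distribution over output patterns given
#' input pattern `i`; every row must sum to 1.
#'
#' @inheritParams deterministic_gate
#' @param table numeric matrix, `2^n_inputs` rows by `2^n_outputs` columns.
#' @return an `mb_gate` environment.
#' @export
probabilistic_gate <- function(input_nodes, output_nodes, table,
                               n_nodes = 16L) {
  g <- .new_gate("probabilistic", input_nodes, output_nodes, n_nodes)
  g$table <- .check_prob_table(table, 2L^length(g$input_nodes),
                               2L^length(g$output_nodes))
  g
}

#' Construct a feedback gate
#'
#' A probabilistic gate that can alter its own probability table during the
#' agent's lifetime. Two extra wired inputs carry internally generated
#' feedback: reading a 1 on the positive (negative) line triggers an upward
#' (downward) multiplicative-style shift of the probabilities credited in a
#' buffer of the gate's most recent (input, output) decisions, up to `depth`
#' (at most 4) steps back. The shift magnitude for the decision `k` steps
#' back is drawn uniformly from `[0, delta_pos[k]]` (or `delta_neg[k]`).
#' Entries are clamped to `[0.01, 0.99]` and the row renormalized after each
#' shift. `table_birth` preserves the genome-decoded table so the gate can be
#' reset between lifetimes.
#'
#' @inheritParams probabilistic_gate
#' @param pos_node,neg_node node indices (0-based) of the positive and
#'   negative feedback lines.
#' @param depth decision-buffer depth, 1--4.
#' @param delta_pos,delta_neg numeric vectors of length `depth`, each in
#'   `[0, 1]`: the per-slot maximum feedback magnitudes.
#' @return an `mb_gate` environment.
#' @export
feedback_gate <- function(input_nodes, output_nodes, table, pos_node,
                          neg_node, depth = 1L, delta_pos = 0.5,
                          delta_neg = delta_pos, n_nodes = 16L) {
  g <- .new_gate("feedback", input_nodes, output_nodes, n_nodes)
  g$table <- .check_prob_table(table, 2L^length(g$input_nodes),
                               2L^length(g$output_nodes))
  g$table_birth <- g$table
  g$pos_node <- .check_nodes(pos_node, "pos_node", n_nodes)
  g$neg_node <- .check_nodes(neg_node, "neg_node", n_nodes)
  depth <- as.integer(depth)
  if (depth < 1L || depth > 4L) stop("depth must be in [1, 4]")
  g$depth <- depth
  delta_pos <- rep_len(as.numeric(delta_pos), depth)
  delta_neg <- rep_len(as.numeric(delta_neg), depth)
  if (any(delta_pos < 0) || any(delta_pos > 1) ||
      any(delta_neg < 0) || any(delta_neg > 1)) {
    stop("delta schedules must lie in [0, 1]")
  }
  g$delta_pos <- delta_pos
  g$delta_neg <- delta_neg
  g$history <- matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("i", "o")))
  g
}

#' @export
print.mb_gate <- function(x, ...) {
  cat(x$kind, " gate: inputs {", paste(x$input_nodes, collapse = ","),
      "} -> outputs {", paste(x$output_nodes, collapse = ","), "}\n", sep = "")
  if (x$kind == "feedback") {
    cat("  feedback lines: +", x$pos_node, " / -", x$neg_node,
        ", buffer depth ", x$depth, "\n", sep = "")
  }
  invisible(x)
}

#' Deep-copy a gate
#'
#' Gates are mutable environments; `copy_gate` returns an independent copy
#' (used e.g. to snapshot tables before a lifetime).
#'
#' @param gate an `mb_gate`.
#' @return a new `mb_gate` with identical fields.
#' @export
copy_gate <- function(gate) {
  g <- new.env(parent = emptyenv())
  for (nm in ls(gate)) assign(nm, get(nm, envir = gate), envir = g)
  class(g) <- class(gate)
  g
}

#' Evaluate a deterministic gate
#'
#' @param gate a deterministic `mb_gate`.
#' @param input_pattern integer in `[0, 2^n_inputs)`.
#' @return the output pattern (integer).
#' @export
eval_deterministic <- function(gate, input_pattern) {
  stopifnot(inherits(gate, "mb_gate_deterministic"))
  input_pattern <- as.integer(input_pattern)
  if (is.na(input_pattern) || input_pattern < 0L ||
      input_pattern >= length(gate$table)) {
    stop("input pattern out of range")
  }
  gate$table[input_pattern + 1L]
}

#' Sample outputs from a probabilistic or feedback gate
#'
#' Draws output patterns from the table row of the given input pattern. For a
#' feedback gate each draw is additionally pushed onto the decision buffer
#' (most recent first), evicting the oldest entry beyond `depth`.
#'
#' @param gate a probabilistic or feedback `mb_gate`.
#' @param input_pattern integer in `[0, 2^n_inputs)`.
#' @param n number of draws (default 1).
#' @return integer vector of `n` output patterns.
#' @export
eval_probabilistic <- function(gate, input_pattern, n = 1L) {
  if (!inherits(gate, c("mb_gate_probabilistic", "mb_gate_feedback"))) {
    stop("gate must be probabilistic or feedback")
  }
  input_pattern <- as.integer(input_pattern)
  if (is.na(input_pattern) || input_pattern < 0L ||
      input_pattern >= nrow(gate$table)) {
    stop("input pattern out of range")
  }
  row <- gate$table[input_pattern + 1L, ]
  if (abs(sum(row) - 1) > 1e-6) {
    stop("internal consistency error: table row is not a distribution")
  }
  draws <- sample.int(length(row), n, replace = TRUE, prob = row) - 1L
  if (gate$kind == "feedback") {
    for (o in draws) {
      gate$history <- rbind(c(i = input_pattern, o = o),
                            gate$history)[seq_len(min(nrow(gate$history) + 1L,
                                                      gate$depth)), , drop = FALSE]
    }
  }
  draws
}

# Shift one row entry by u (signed), clamp to [0.01, 0.99] and to row
# feasibility, rescale the remaining entries proportionally, then iteratively
# floor entries below 0.01 and rescale the rest.
.apply_one_r <- function(row, o, u, sign) {
  K <- length(row)
  t <- row[o] + sign * u
  t <- min(max(t, .P_LO), .P_HI)
  t <- min(t, 1 - .P_LO * (K - 1))
  rest <- sum(row[-o])
  if (rest <= 0) row[-o] <- (1 - t) / (K - 1)
  else row[-o] <- row[-o] * (1 - t) / rest
  row[o] <- t
  fixed <- rep(FALSE, K)
  fixed[o] <- TRUE
  repeat {
    low <- !fixed & row < .P_LO - 1e-12
    if (!any(low)) break
    row[low] <- .P_LO
    fixed <- fixed | low
    if (all(fixed)) break
    row[!fixed] <- row[!fixed] * (1 - sum(row[fixed])) / sum(row[!fixed])
  }
  row
}

#' Apply feedback to a feedback gate
#'
#' For each buffered decision `(i, o)` at queue position `k` (1 = most
#' recent) a magnitude `u` is drawn uniformly from `[0, delta_pos[k]]`
#' (positive feedback) or `[0, delta_neg[k]]` (negative feedback), the table
#' entry `P[i, o]` is shifted by `+u` or `-u`, clamped to `[0.01, 0.99]`, and
#' the rest of row `i` is renormalized proportionally (with an iterative
#' floor at 0.01) so the row sums to 1. An empty buffer is a no-op.
#'
#' @param gate a feedback `mb_gate`.
#' @param sign `"positive"` or `"negative"`.
#' @param amounts optional numeric vector of fixed magnitudes (one per
#'   buffered decision) replacing the random draws; used for deterministic
#'   analyses and tests.
#' @return the gate, invisibly (it is modified in place).
#' @export
apply_feedback <- function(gate, sign = c("positive", "negative"),
                           amounts = NULL) {
  stopifnot(inherits(gate, "mb_gate_feedback"))
  sign <- match.arg(sign)
  sgn <- if (sign == "positive") 1 else -1
  deltas <- if (sign == "positive") gate$delta_pos else gate$delta_neg
  nh <- nrow(gate$history)
  if (nh == 0L) return(invisible(gate))
  for (k in seq_len(nh)) {
    u <- if (is.null(amounts)) runif(1, 0, deltas[k]) else amounts[k]
    i <- gate$history[k, 1L] + 1L
    o <- gate$history[k, 2L] + 1L
    gate$table[i, ] <- .apply_one_r(gate$table[i, ], o, u, sgn)
  }
  invisible(gate)
}

#' Read a feedback gate's feedback lines from a node-state vector
#'
#' A 0 on a line has no effect; a 1 triggers the corresponding feedback.
#'
#' @param gate a feedback `mb_gate`.
#' @param node_states binary vector of node states (element `k` is node
#'   `k - 1`).
#' @return one of `"none"`, `"positive"`, `"negative"`, `"both"`. When both
#'   lines read 1 the brain applies positive feedback first, then negative.
#' @export
check_feedback_inputs <- function(gate, node_states) {
  stopifnot(inherits(gate, "mb_gate_feedback"))
  pos <- node_states[gate$pos_node + 1L] != 0
  neg <- node_states[gate$neg_node + 1L] != 0
  if (pos && neg) "both" else if (pos) "positive" else if (neg) "negative" else "none"
}

#' Decode a gene span into a gate
#'
#' Payload bytes are interpreted, in order: input count and output count
#' (byte mod 4, plus 1), four input node addresses (byte mod `n_nodes`), four
#' output node addresses (mapped into the writable nodes 4--15, so gates
#' never overwrite sensors), then -- for feedback gates -- the positive and
#' negative feedback node addresses, the buffer depth (byte mod 4, plus 1)
#' and two four-byte delta schedules (byte / 255). The logic table follows:
#' for deterministic gates one byte per input pattern (mod `2^n_outputs`);
#' for probabilistic and feedback gates one byte per table cell, incremented
#' by 1 and row-normalized (so no row is degenerate and every byte string
#' decodes to a valid gate).
#'
#' @param span a gene span from [find_genes()].
#' @param n_nodes number of brain nodes (default 16).
#' @return an `mb_gate`.
#' @export
decode_gate <- function(span, n_nodes = 16L) {
  p <- span$payload
  n_in <- p[1] %% 4L + 1L
  n_out <- p[2] %% 4L + 1L
  input_nodes <- p[3:6][seq_len(n_in)] %% n_nodes
  output_nodes <- 4L + p[7:10][seq_len(n_out)] %% (n_nodes - 4L)
  rows <- 2L^n_in
  cols <- 2L^n_out
  kind <- span$gate_kind
  if (kind == "deterministic") {
    tb <- p[10L + seq_len(rows)] %% cols
    return(deterministic_gate(input_nodes, output_nodes, tb, n_nodes))
  }
  off <- if (kind == "feedback") 21L else 10L
  bytes <- p[off + seq_len(rows * cols)]
  M <- matrix(bytes + 1, nrow = rows, byrow = TRUE)
  P <- M / rowSums(M)
  if (kind == "probabilistic") {
    return(probabilistic_gate(input_nodes, output_nodes, P, n_nodes))
  }
  feedback_gate(
    input_nodes, output_nodes, P,
    pos_node = p[11] %% n_nodes, neg_node = p[12] %% n_nodes,
    depth = p[13] %% 4L + 1L,
    delta_pos = (p[14:17] / 255)[seq_len(p[13] %% 4L + 1L)],
    delta_neg = (p[18:21] / 255)[seq_len(p[13] %% 4L + 1L)],
    n_nodes = n_nodes
  )
}

# plain-list view of a gate, used by the compiled engine and JSON dumps
.gate_as_list <- function(gate) {
  out <- list(kind = gate$kind, input_nodes = gate$input_nodes,
              output_nodes = gate$output_nodes, table = gate$table)
  if (gate$kind == "feedback") {
    out <- c(out, list(pos_node = gate$pos_node, neg_node = gate$neg_node,
                       depth = gate$depth, delta_pos = gate$delta_pos,
                       delta_neg = gate$delta_neg))
  }
  out
}

#' Serialize gates to JSON
#'
#' Writes gate kind, wiring and full logic/probability tables.
#'
#' @param gates list of `mb_gate` objects.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gates_json <- function(gates, path) {
  jsonlite::write_json(lapply(gates, .gate_as_list), path, digits = NA,
                       matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}
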