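# Markov Brains: 16 binary nodes (0-3 sensors, 4-5 motor outputs, 6-15
# hidden) plus the gates decoded from a genome. Updates are synchronous and
# double-buffered with OR-combination of multiple writers; gate order is
# therefore irrelevant. Brains hold lifetime state (node states, feedback
# tables, decision buffers) in a compiled engine object and are modified in
# place.

#' Build a Markov Brain from a genome
#'
#' Discovers genes via [find_genes()], decodes one gate per gene (optionally
#' restricted to a subset of gate kinds, for the experimental conditions that
#' allow only some gate types), and assembles them into a 16-node brain with
#' all-zero state and feedback enabled.
#'
#' @param genome an `mb_genome`.
#' @param gate_types gate kinds to decode; genes of other kinds are skipped.
#' @param n_nodes number of nodes (default 16: 4 sensors, 2 outputs, 10
#'   hidden).
#' @param feedback_enabled initial state of the lifetime-learning switch.
#' @return an object of class `mb_brain`. The `gates` field holds the
#'   birth-state gate objects; live tables are read with [brain_tables()].
#' @export
build_brain <- function(genome, gate_types = .mb_gate_kinds, n_nodes = 16L,
                        feedback_enabled = TRUE) {
  gate_types <- match.arg(gate_types, .mb_gate_kinds, several.ok = TRUE)
  spans <- find_genes(genome)
  spans <- spans[vapply(spans, `[[`, "", "gate_kind") %in% gate_types]
  gates <- lapply(spans, decode_gate, n_nodes = n_nodes)
  ptr <- cpp_build_brain(lapply(gates, .gate_as_list), n_nodes,
                         feedback_enabled)
  structure(list(gates = gates, n_nodes = n_nodes, ptr = ptr,
                 genome_id = genome$id),
            class = "mb_brain")
}

#' Assemble a brain directly from gate objects
#'
#' Used for hand-constructed exemplar brains in analyses and tests.
#'
#' @param gates list of `mb_gate` objects.
#' @inheritParams build_brain
#' @return an `mb_brain`.
#' @export
brain_from_gates <- function(gates, n_nodes = 16L, feedback_enabled = TRUE) {
  ptr <- cpp_build_brain(lapply(gates, .gate_as_list), n_nodes,
                         feedback_enabled)
  structure(list(gates = gates, n_nodes = n_nodes, ptr = ptr,
                 genome_id = NA_integer_),
            class = "mb_brain")
}

#' @export
print.mb_brain <- function(x, ...) {
  census <- gate_census(x)
  cat("Markov Brain: ", x$n_nodes, " nodes, ", length(x$gates), " gates (",
      census[["deterministic"]], " det, ", census[["probabilistic"]],
      " prob, ", census[["feedback"]], " fb), feedback ",
      if (cpp_get_feedback(x$ptr)) "enabled" else "frozen", "\n", sep = "")
  invisible(x)
}

#' Advance a brain by one synchronous update
#'
#' Sensor nodes 0--3 are overwritten with `sensor_bits`; each feedback gate
#' then reads its feedback lines from the current state and (if lifetime
#' learning is enabled) applies feedback (positive before negative); all
#' gates then read their inputs from the current state and OR their outputs
#' into a fresh zero next-state, which replaces the hidden and output nodes.
#' Output nodes are not latched: they must be rewritten every update.
#'
#' @param brain an `mb_brain` (modified in place).
#' @param sensor_bits binary vector of length 4.
#' @param seed optional integer seed for the update's random draws; by
#'   default drawn from R's RNG, so `set.seed()` makes sequences
#'   reproducible.
#' @return integer vector of the two output bits (nodes 4 and 5).
#' @export
brain_step <- function(brain, sensor_bits, seed = NULL) {
  stopifnot(length(sensor_bits) == 4L)
  cpp_brain_step(brain$ptr, as.integer(sensor_bits), seed %||% .draw_seed())
}

#' Return a brain to its birth state
#'
#' Zeroes the node states, restores every feedback gate's table to the
#' genome-decoded birth table, and clears the decision buffers. Idempotent.
#'
#' @param brain an `mb_brain` (modified in place).
#' @return the brain, invisibly.
#' @export
reset_brain <- function(brain) {
  cpp_reset_brain(brain$ptr)
  invisible(brain)
}

#' Enable or disable lifetime learning
#'
#' When disabled ("frozen feedback"), feedback gates still sample outputs and
#' buffer decisions, but never alter their probability tables. Used for the
#' frozen-feedback control that measures how much of an agent's performance
#' depends on lifetime learning.
#'
#' @param brain an `mb_brain` (modified in place).
#' @param flag logical.
#' @return the brain, invisibly.
#' @export
set_feedback_enabled <- function(brain, flag) {
  cpp_set_feedback(brain$ptr, isTRUE(flag))
  invisible(brain)
}

#' @rdname set_feedback_enabled
#' @export
feedback_enabled <- function(brain) cpp_get_feedback(brain$ptr)

#' Current node states of a brain
#'
#' @param brain an `mb_brain`.
#' @return integer vector of node states (element `k` is node `k - 1`).
#' @export
brain_state <- function(brain) cpp_brain_state(brain$ptr)

#' Live gate tables of a brain
#'
#' @param brain an `mb_brain`.
#' @return a list with one entry per gate: for deterministic gates the logic
#'   table; for probabilistic and feedback gates the current table, the birth
#'   table and the decision buffer.
#' @export
brain_tables <- function(brain) cpp_gate_tables(brain$ptr)

#' Snapshot a brain to JSON
#'
#' Writes wiring, birth tables, current tables and node states, e.g. for
#' before/after comparisons of feedback tables.
#'
#' @param brain an `mb_brain`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_brain_json <- function(brain, path) {
  snap <- list(
    n_nodes = brain$n_nodes,
    state = brain_state(brain),
    gates = lapply(brain$gates, .gate_as_list),
    live_tables = brain_tables(brain)
  )
  jsonlite::write_json(snap, path, digits = NA, matrix = "rowmajor",
                       auto_unbox = TRUE)
  invisible(path)
}
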