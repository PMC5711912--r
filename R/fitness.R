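# Fitness: an agent is evaluated on all 24 option-to-action mappings, each
# in a freshly generated maze for 512 updates, spawning at distance 32 from
# the goal. Every update it collects 1/(1 + d) for its current tile distance
# d, plus a bonus b per goal reached; overall fitness is the product of the
# 24 per-mapping scores, accumulated in log-domain.

#' Evaluate a brain on one option-to-action mapping
#'
#' Generates a fresh maze (unless one is supplied), resets the brain, spawns
#' the agent at a uniformly random spawn-distance tile with a random heading,
#' and runs `T` updates: read the tile's relative-arrow sensors, step the
#' brain, translate the 2-bit option (node 4 is the low bit, consistent with
#' gate patterns: first listed node = least significant bit) through the
#' mapping, apply the action, and accrue `1 / (1 + d)` for the resulting
#' tile. Reaching the goal increments the goal count and respawns the agent
#' (same maze, same lifetime: learned tables persist).
#'
#' @param brain an `mb_brain`.
#' @param map an integer action map from [enumerate_action_maps()], or an
#'   index 1--24 into that list.
#' @param T number of updates (default 512).
#' @param b per-goal bonus added to the score as `goals * b` (default 512,
#'   so one goal outweighs the maximal dwell score).
#' @param seed integer seed for the evaluation's randomness (maze, spawns,
#'   gate sampling); drawn from R's RNG when `NULL`.
#' @param maze optional fixed `mb_maze` to evaluate in.
#' @param reset reset the brain (state, feedback tables, buffers) before the
#'   episode (default `TRUE`).
#' @param trace also return the per-update trajectory.
#' @param size,fill,spawn_dist,max_tries maze generation parameters, see
#'   [generate_maze()].
#' @return an object of class `mb_eval`: `score`, `goal_count`,
#'   `action_counts` (named), `fb_tables` (end-of-episode feedback tables),
#'   and optionally `trace` (data frame with t, row, col, heading, option,
#'   action, d).
#' @export
evaluate_on_mapping <- function(brain, map, T = 512L, b = 512, seed = NULL,
                                maze = NULL, reset = TRUE, trace = FALSE,
                                size = 64L, fill = 1 / 7, spawn_dist = 32L,
                                max_tries = 1000L) {
  if (length(map) == 1L) map <- enumerate_action_maps()[[map]]
  stopifnot(length(map) == 4L, setequal(map, 0:3))
  res <- cpp_evaluate_mapping(
    brain$ptr, as.integer(map), as.integer(T), b, seed %||% .draw_seed(),
    isTRUE(reset), isTRUE(trace),
    if (is.null(maze)) NULL else unclass(maze),
    as.integer(size), fill, as.integer(spawn_dist), as.integer(max_tries)
  )
  fb_tables <- res$fb_tables
  if (length(fb_tables)) names(fb_tables) <- paste0("gate", res$fb_gates)
  out <- list(score = res$score, goal_count = res$goal_count,
              action_counts = setNames(res$action_counts, .actions),
              fb_tables = fb_tables)
  if (isTRUE(trace)) {
    tr <- as.data.frame(res$trace)
    names(tr) <- c("t", "row", "col", "heading", "option", "action", "d")
    out$trace <- tr
  }
  class(out) <- "mb_eval"
  out
}

#' @export
print.mb_eval <- function(x, ...) {
  cat("episode: score ", format(x$score, digits = 6), ", ", x$goal_count,
      " goals, actions [", paste(x$action_counts, collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Evaluate fitness over all 24 option-to-action mappings
#'
#' Runs [evaluate_on_mapping()] for every mapping (brain reset before each,
#' fresh maze per mapping) and combines the per-mapping scores into the
#' overall fitness
#' \deqn{W = \prod_{n=0}^{n<24} \Big( \sum_{t=0}^{t<T} \frac{1}{1+d} + g_n b \Big)}
#' where \eqn{g_n} is the number of goals reached under mapping \eqn{n}. The
#' product is accumulated in log-domain; selection compares `logW`.
#'
#' @inheritParams evaluate_on_mapping
#' @param maps list of action maps (default all 24).
#' @param collect_tables keep before/after snapshots of every feedback
#'   gate's table for each mapping (for mutual-information analyses).
#' @param trace keep per-mapping trajectories.
#' @return an object of class `mb_fitness`: `W`, `logW`, `scores` (24),
#'   `goals` (24), `mean_goals`, `action_counts` (24 x 4 matrix), `b`, `T`,
#'   and optionally `snapshots` (list over mappings of per-gate
#'   `P_birth`/`P_end` pairs) and `traces`.
#' @export
fitness <- function(brain, T = 512L, b = 512, seed = NULL,
                    maps = enumerate_action_maps(), collect_tables = FALSE,
                    trace = FALSE, size = 64L, fill = 1 / 7,
                    spawn_dist = 32L, max_tries = 1000L) {
  seed <- seed %||% .draw_seed()
  n <- length(maps)
  scores <- numeric(n)
  goals <- integer(n)
  acts <- matrix(0L, n, 4L, dimnames = list(NULL, .actions))
  snapshots <- if (collect_tables) vector("list", n)
  traces <- if (trace) vector("list", n)
  birth <- if (collect_tables) {
    fb <- which(vapply(brain$gates, `[[`, "", "kind") == "feedback")
    lapply(brain$gates[fb], `[[`, "table_birth")
  }
  for (m in seq_len(n)) {
    ev <- evaluate_on_mapping(brain, maps[[m]], T = T, b = b,
                              seed = seed_stream(seed, m), reset = TRUE,
                              trace = trace, size = size, fill = fill,
                              spawn_dist = spawn_dist, max_tries = max_tries)
    scores[m] <- ev$score
    goals[m] <- ev$goal_count
    acts[m, ] <- ev$action_counts
    if (collect_tables) {
      snapshots[[m]] <- Map(function(Pb, Pe) list(P_birth = Pb, P_end = Pe,
                                                  mapping = m),
                            birth, ev$fb_tables)
    }
    if (trace) traces[[m]] <- ev$trace
  }
  if (any(!is.finite(scores)) || (any(scores <= 0) && T > 0L)) {
    stop("non-finite or non-positive per-mapping score")
  }
  logW <- if (all(scores > 0)) sum(log(scores)) else -Inf
  out <- list(W = exp(logW), logW = logW, scores = scores, goals = goals,
              mean_goals = mean(goals), action_counts = acts, b = b, T = T)
  if (collect_tables) out$snapshots <- snapshots
  if (trace) out$traces <- traces
  class(out) <- "mb_fitness"
  out
}

#' @export
print.mb_fitness <- function(x, ...) {
  cat("fitness over ", length(x$scores), " mappings: log W = ",
      format(x$logW, digits = 6), ", goals per mapping ",
      format(x$mean_goals, digits = 4), " (max ", max(x$goals), ")\n",
      sep = "")
  invisible(x)
}
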