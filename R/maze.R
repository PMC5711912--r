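# The arrow-labelled maze task. Coordinates are 1-based (row, col) on the R
# side, row 1 at the top; heading 0 = up (decreasing row), 1 = right,
# 2 = down, 3 = left. Every empty reachable tile carries an arrow (absolute
# direction) toward a neighbour strictly closer to the goal.

.headings <- c("up", "right", "down", "left")
.actions <- c("forward", "nothing", "turn-left", "turn-right")
.DX <- c(-1L, 0L, 1L, 0L) # row delta per heading
.DY <- c(0L, 1L, 0L, -1L) # col delta per heading

#' Generate an arrow-labelled maze
#'
#' Builds a square grid with a solid wall border, fills each interior tile
#' with probability `fill`, places the goal uniformly on an empty tile,
#' computes shortest-path distances from every empty tile to the goal
#' (4-neighbour moves), and labels each reachable tile with an arrow toward a
#' neighbour with strictly smaller distance, breaking ties uniformly at
#' random. If no tile lies at exactly `spawn_dist` (the agent spawn
#' distance), the whole maze is regenerated.
#'
#' @param seed integer seed; by default drawn from R's RNG.
#' @param size grid side length (default 64).
#' @param fill interior wall probability (default 1/7).
#' @param spawn_dist required spawn distance (default 32).
#' @param max_tries regeneration cap before erroring.
#' @return an object of class `mb_maze`: list with `size`, `walls` (logical
#'   matrix), `goal` (row, col), `dist` (integer matrix, `NA` on walls and
#'   unreachable tiles), `arrows` (integer matrix of absolute directions
#'   0--3, `NA` where undefined) and `spawns` (matrix of tiles at
#'   `spawn_dist`).
#' @export
generate_maze <- function(seed = NULL, size = 64L, fill = 1 / 7,
                          spawn_dist = 32L, max_tries = 1000L) {
  m <- cpp_generate_maze(seed %||% .draw_seed(), as.integer(size), fill,
                         as.integer(spawn_dist), as.integer(max_tries))
  m$spawn_dist <- as.integer(spawn_dist)
  class(m) <- "mb_maze"
  m
}

#' Construct a maze object from explicit grids
#'
#' Used for fixtures (e.g. an open maze with no interior walls). Distances
#' and arrows must satisfy the maze invariants; they are not recomputed.
#'
#' @param walls logical matrix (border must be all `TRUE`).
#' @param goal `(row, col)` of the goal tile.
#' @param dist integer matrix of shortest-path distances (`NA` on walls).
#' @param arrows integer matrix of absolute arrow directions (`NA` where
#'   undefined).
#' @param spawn_dist spawn distance used to derive the spawn set.
#' @return an `mb_maze`.
#' @export
new_maze <- function(walls, goal, dist, arrows, spawn_dist = 32L) {
  size <- nrow(walls)
  stopifnot(ncol(walls) == size, all(dim(dist) == size),
            all(dim(arrows) == size))
  sp <- which(!is.na(dist) & dist == spawn_dist, arr.ind = TRUE)
  structure(list(size = size, walls = walls, goal = as.integer(goal),
                 dist = dist, arrows = arrows,
                 spawns = matrix(as.integer(sp), ncol = 2),
                 spawn_dist = as.integer(spawn_dist)),
            class = "mb_maze")
}

#' @export
print.mb_maze <- function(x, ...) {
  cat("maze ", x$size, "x", x$size, ": goal (", x$goal[1], ",", x$goal[2],
      "), ", sum(x$walls), " walls, ", nrow(x$spawns),
      " spawn tiles at distance ", x$spawn_dist, "\n", sep = "")
  invisible(x)
}

#' Construct an agent state
#'
#' @param position `(row, col)` tile coordinate.
#' @param heading one of `"up"`, `"right"`, `"down"`, `"left"`, or the
#'   corresponding integer 0--3.
#' @return a list with `position` and integer `heading`, class
#'   `mb_agent`.
#' @export
agent_state <- function(position, heading) {
  if (is.character(heading)) heading <- match(heading, .headings) - 1L
  heading <- as.integer(heading) %% 4L
  structure(list(position = as.integer(position), heading = heading),
            class = "mb_agent")
}

#' Sensor vector seen by an agent
#'
#' The tile's absolute arrow is rotated into the agent's frame and one-hot
#' encoded over (forward, right, backward, left); a tile indicating north
#' reads as a forward arrow only if the agent also faces north. Tiles without
#' an arrow give an all-zero vector.
#'
#' @param maze an `mb_maze`.
#' @param agent an `mb_agent`.
#' @return named binary integer vector of length 4.
#' @export
sensor_vector <- function(maze, agent) {
  out <- setNames(integer(4), c("forward", "right", "backward", "left"))
  a <- maze$arrows[agent$position[1], agent$position[2]]
  if (!is.na(a)) out[(a - agent$heading) %% 4L + 1L] <- 1L
  out
}

#' Apply a movement action to an agent
#'
#' `forward` advances one tile in the current heading unless the target tile
#' is a wall, in which case the move is a no-op; turns rotate the heading by
#' 90 degrees; `nothing` leaves the state unchanged.
#'
#' @param maze an `mb_maze`.
#' @param agent an `mb_agent`.
#' @param action one of `"forward"`, `"nothing"`, `"turn-left"`,
#'   `"turn-right"`, or the corresponding integer code 0--3.
#' @return the new `mb_agent`.
#' @export
apply_action <- function(maze, agent, action) {
  if (is.character(action)) action <- match(action, .actions) - 1L
  action <- as.integer(action)
  if (action == 0L) {
    tgt <- agent$position + c(.DX[agent$heading + 1L], .DY[agent$heading + 1L])
    if (!maze$walls[tgt[1], tgt[2]]) agent$position <- tgt
  } else if (action == 2L) {
    agent$heading <- (agent$heading + 3L) %% 4L
  } else if (action == 3L) {
    agent$heading <- (agent$heading + 1L) %% 4L
  }
  agent
}

#' Enumerate all 24 option-to-action mappings
#'
#' The brain's two output bits select one of four options (00, 01, 10, 11);
#' at birth the options are mapped onto the four actions by one of the
#' 4! = 24 bijections, so the agent has to discover its own motor mapping
#' each lifetime.
#'
#' @return a list of 24 integer vectors; element `o + 1` of each vector is
#'   the action code (0 forward, 1 nothing, 2 turn-left, 3 turn-right)
#'   assigned to option `o`. Names give the action words. Order is
#'   lexicographic and stable.
#' @export
enumerate_action_maps <- function() {
  perms <- list()
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) for (d in 0:3) {
    if (length(unique(c(a, b, cc, d))) == 4L) {
      perms[[length(perms) + 1L]] <- setNames(c(a, b, cc, d),
                                              .actions[c(a, b, cc, d) + 1L])
    }
  }
  perms
}

#' Render a maze as ASCII art
#'
#' `#` wall, `G` goal, `.` empty, arrows `^>v<`, `A` agent, `*` trajectory.
#'
#' @param maze an `mb_maze`.
#' @param agent optional `mb_agent` to mark.
#' @param path optional 2-column matrix of visited (row, col) tiles.
#' @param arrows draw arrow labels instead of dots.
#' @return character vector of rows.
#' @export
render_maze <- function(maze, agent = NULL, path = NULL, arrows = FALSE) {
  chars <- matrix(".", maze$size, maze$size)
  if (arrows) {
    glyph <- c("^", ">", "v", "<")
    lab <- !is.na(maze$arrows)
    chars[lab] <- glyph[maze$arrows[lab] + 1L]
  }
  chars[maze$walls] <- "#"
  if (!is.null(path)) chars[path] <- "*"
  chars[maze$goal[1], maze$goal[2]] <- "G"
  if (!is.null(agent)) chars[agent$position[1], agent$position[2]] <- "A"
  apply(chars, 1, paste, collapse = "")
}
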