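# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (list queues, direct summation) so they are independent
# of the package's implementations.

# breadth-first-search distance field from the goal over 4-neighbour moves;
# relies on the border being solid wall (all traversable tiles interior).
oracle_bfs <- function(walls, goal) {
  sz <- nrow(walls)
  n <- sz * sz
  d <- rep(NA_integer_, n)
  q <- integer(n)
  gi <- (goal[2] - 1L) * sz + goal[1]
  d[gi] <- 0L
  q[1] <- gi
  head <- 1L
  tail <- 1L
  offs <- c(-1L, 1L, -sz, sz)
  while (head <= tail) {
    cur <- q[head]
    head <- head + 1L
    for (o in offs) {
      nb <- cur + o
      if (walls[nb] || !is.na(d[nb])) next
      d[nb] <- d[cur] + 1L
      tail <- tail + 1L
      q[tail] <- nb
    }
  }
  matrix(d, sz, sz)
}

# follow the tile arrows greedily from `start`; returns the number of moves
# to the goal (Inf if not reached within `cap`)
oracle_follow_arrows <- function(maze, start, cap = 10000L) {
  step <- rbind(c(-1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, -1L))
  pos <- as.integer(start)
  moves <- 0L
  while (!(pos[1] == maze$goal[1] && pos[2] == maze$goal[2])) {
    a <- maze$arrows[pos[1], pos[2]]
    if (is.na(a)) return(Inf)
    pos <- pos + step[a + 1L, ]
    moves <- moves + 1L
    if (moves > cap) return(Inf)
  }
  moves
}

# open maze fixture: no interior walls, arrows toward the goal (first
# minimizing neighbour), distances = Manhattan distance
open_maze <- function(size = 64L, goal = c(32L, 32L), spawn_dist = 32L) {
  walls <- matrix(FALSE, size, size)
  walls[c(1, size), ] <- TRUE
  walls[, c(1, size)] <- TRUE
  d <- outer(seq_len(size), seq_len(size),
             function(r, c) abs(r - goal[1]) + abs(c - goal[2]))
  d[walls] <- NA_integer_
  arrows <- matrix(NA_integer_, size, size)
  step <- rbind(c(-1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, -1L))
  for (r in 2:(size - 1)) for (c2 in 2:(size - 1)) {
    if (is.na(d[r, c2]) || d[r, c2] == 0) next
    for (a in 0:3) {
      nb <- c(r, c2) + step[a + 1, ]
      if (!walls[nb[1], nb[2]] && !is.na(d[nb[1], nb[2]]) &&
          d[nb[1], nb[2]] < d[r, c2]) {
        arrows[r, c2] <- a
        break
      }
    }
  }
  new_maze(walls, goal, d, arrows, spawn_dist = spawn_dist)
}

# brain that ignores its sensors and always emits the option mapped to the
# requested action under `map` (default: "nothing" -> a stationary agent)
constant_option_brain <- function(map, action_code = 1L) {
  o <- unname(which(map == action_code) - 1L)
  brain_from_gates(list(deterministic_gate(0L, c(4L, 5L), rep(o, 2L))))
}

# hand-built learner whose navigation depends on its feedback gate: one
# feedback gate maps the four one-hot sensor rows to the four options,
# starting uniform; its positive feedback line is the forward-arrow sensor,
# so decisions that lead to seeing a forward arrow are reinforced; the
# negative line is wired to a never-written hidden node.
learner_brain <- function(depth = 1L, delta = 0.45) {
  P <- matrix(0.25, 16, 4)
  g <- feedback_gate(0:3, c(4L, 5L), P, pos_node = 0L, neg_node = 15L,
                     depth = depth, delta_pos = rep(delta, depth),
                     delta_neg = rep(0, depth))
  brain_from_gates(list(g))
}

# random feedback gate of varied shape with a valid random table
random_fb_gate <- function() {
  n_in <- sample(1:2, 1)
  n_out <- sample(1:2, 1)
  rows <- 2L^n_in
  cols <- 2L^n_out
  M <- matrix(runif(rows * cols, 0.05, 1), rows)
  depth <- sample(1:4, 1)
  feedback_gate(sample(0:15, n_in), sample(4:15, n_out), M / rowSums(M),
                pos_node = sample(0:15, 1), neg_node = sample(0:15, 1),
                depth = depth, delta_pos = runif(depth),
                delta_neg = runif(depth))
}

# push random decisions through a feedback gate and pepper it with random
# positive/negative feedback; returns the gate
hammer_fb_gate <- function(gate, events = 1000L) {
  rows <- nrow(gate$table)
  for (e in seq_len(events)) {
    eval_probabilistic(gate, sample.int(rows, 1L) - 1L)
    apply_feedback(gate, sample(c("positive", "negative"), 1L))
  }
  gate
}

# direct-summation mutual information oracle (uniform input marginal)
oracle_mi <- function(P) {
  w <- rep(1 / nrow(P), nrow(P))
  joint <- P * w
  py <- colSums(joint)
  s <- 0
  for (i in seq_len(nrow(P))) for (o in seq_len(ncol(P))) {
    if (joint[i, o] > 0) {
      s <- s + joint[i, o] * log2(joint[i, o] / (w[i] * py[o]))
    }
  }
  s
}
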