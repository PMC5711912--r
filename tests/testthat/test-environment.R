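# Maze generation, labelling, sensors, kinematics, and fitness evaluation.

test_that("generated mazes satisfy their structural invariants", {
  set.seed(41)
  step <- rbind(c(-1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, -1L))
  for (k in 1:25) {
    m <- generate_maze()
    expect_true(all(m$walls[c(1, 64), ]) && all(m$walls[, c(1, 64)]))
    inner <- m$walls[2:63, 2:63]
    expect_gt(mean(inner), 1 / 7 - 0.05)
    expect_lt(mean(inner), 1 / 7 + 0.05)
    expect_gte(nrow(m$spawns), 1)
    expect_true(all(m$dist[m$spawns] == 32))
    # independent BFS agrees everywhere
    expect_identical(unname(m$dist), oracle_bfs(m$walls, m$goal))
    # every arrow points to a strictly closer neighbour
    lab <- which(!is.na(m$arrows) & m$dist > 0, arr.ind = TRUE)
    nb <- lab + step[m$arrows[lab] + 1L, , drop = FALSE]
    expect_true(all(m$dist[nb] == m$dist[lab] - 1L))
  }
})

test_that("an open maze has Manhattan distances", {
  m <- open_maze(goal = c(20, 40))
  d <- outer(1:64, 1:64, function(r, c) abs(r - 20) + abs(c - 40))
  inner <- !m$walls
  expect_equal(m$dist[inner], d[inner])
})

test_that("greedy arrow-following reaches the goal in exactly dist moves", {
  set.seed(42)
  for (k in 1:20) {
    m <- generate_maze()
    for (s in seq_len(min(10, nrow(m$spawns)))) {
      expect_equal(oracle_follow_arrows(m, m$spawns[s, ]), 32)
    }
  }
})

test_that("sensors rotate the tile arrow into the agent's frame", {
  m <- open_maze(goal = c(10, 32))
  # tile below the goal row: arrow points up (north)
  pos <- c(30, 32)
  expect_equal(m$arrows[pos[1], pos[2]], 0L)
  onehot <- function(k) {
    v <- setNames(integer(4), c("forward", "right", "backward", "left"))
    v[k] <- 1L
    v
  }
  expect_equal(sensor_vector(m, agent_state(pos, "up")), onehot(1))
  expect_equal(sensor_vector(m, agent_state(pos, "right")), onehot(4))
  expect_equal(sensor_vector(m, agent_state(pos, "down")), onehot(3))
  expect_equal(sensor_vector(m, agent_state(pos, "left")), onehot(2))
  # full rotation table: relative index = (arrow - heading) mod 4
  for (a in 0:3) for (h in 0:3) {
    mm <- m
    mm$arrows[pos[1], pos[2]] <- a
    v <- sensor_vector(mm, agent_state(pos, h))
    expect_equal(which(v == 1L) - 1L, (a - h) %% 4, ignore_attr = TRUE)
  }
})

test_that("actions move and turn the agent with blocked-move no-ops", {
  m <- open_maze()
  a <- agent_state(c(2, 5), "up") # facing the border wall
  a2 <- apply_action(m, a, "forward")
  expect_equal(a2$position, a$position)
  expect_equal(a2$heading, a$heading)
  a3 <- apply_action(m, agent_state(c(10, 10), "right"), "forward")
  expect_equal(a3$position, c(10L, 11L))
  a4 <- Reduce(function(ag, .) apply_action(m, ag, "turn-left"),
               1:4, agent_state(c(10, 10), "down"))
  expect_equal(a4$heading, 2L)
  a5 <- apply_action(m, agent_state(c(10, 10), "down"), "nothing")
  expect_equal(a5, agent_state(c(10, 10), "down"))
})

test_that("exactly 24 distinct option-to-action bijections exist", {
  maps <- enumerate_action_maps()
  expect_length(maps, 24)
  expect_length(unique(lapply(maps, unname)), 24)
  for (m in maps) expect_setequal(unname(m), 0:3)
  expect_identical(maps, enumerate_action_maps()) # stable order
})

test_that("a stationary agent scores the closed-form 512/33 per mapping", {
  maps <- enumerate_action_maps()
  for (mi in c(1, 9, 24)) {
    br <- constant_option_brain(maps[[mi]])
    ev <- evaluate_on_mapping(br, mi, T = 512, b = 0, seed = 50 + mi)
    expect_equal(ev$score, 512 / 33, tolerance = 1e-12)
    expect_equal(ev$goal_count, 0L)
    expect_equal(unname(ev$action_counts["nothing"]), 512L)
  }
})

test_that("an empty episode scores zero", {
  br <- constant_option_brain(enumerate_action_maps()[[1]])
  ev <- evaluate_on_mapping(br, 1, T = 0, b = 512, seed = 1)
  expect_equal(ev$score, 0)
  expect_equal(ev$goal_count, 0L)
})

test_that("an arrow-following policy reaches the goal within an episode", {
  # deterministic sensor->action policy, wired per mapping
  oracle_policy_brain <- function(map) {
    resp <- function(code) unname(which(map == code) - 1L)
    tb <- integer(16)
    for (p in 0:15) {
      code <- if (bitwAnd(p, 1L)) 0L      # forward arrow -> forward
        else if (bitwAnd(p, 2L)) 3L       # right -> turn right
        else if (bitwAnd(p, 8L)) 2L       # left -> turn left
        else 3L                           # backward -> turn right
      tb[p + 1] <- resp(code)
    }
    brain_from_gates(list(deterministic_gate(0:3, c(4, 5), tb)))
  }
  maps <- enumerate_action_maps()
  set.seed(43)
  for (mi in c(3, 17)) {
    ev <- evaluate_on_mapping(oracle_policy_brain(maps[[mi]]), mi,
                              T = 512, b = 0)
    expect_gte(ev$goal_count, 1)
  }
})

test_that("the episode reward is larger for trajectories nearer the goal", {
  # forward-moving agent in an open maze ends closer than a stationary one
  m <- open_maze(goal = c(32, 32))
  maps <- enumerate_action_maps()
  mi <- 1
  still <- evaluate_on_mapping(constant_option_brain(maps[[mi]]), mi,
                               T = 64, b = 0, seed = 7, maze = m)
  mover <- evaluate_on_mapping(constant_option_brain(maps[[mi]], 0L), mi,
                               T = 64, b = 0, seed = 7, maze = m)
  # same spawn (same seed, same maze): moving toward/around beats standing
  # still only if it reduces distance; verify the monotone scoring directly
  d_path <- c(32, 31, 30, 29)
  expect_true(all(diff(1 / (1 + d_path)) > 0))
  expect_equal(still$score, 64 / 33, tolerance = 1e-12)
  expect_true(is.finite(mover$score))
})

test_that("fitness multiplies the 24 per-mapping scores", {
  set.seed(44)
  g <- random_genome(5000)
  br <- build_brain(g)
  ft <- fitness(br, T = 32, b = 16, seed = 9)
  expect_length(ft$scores, 24)
  expect_equal(ft$logW, sum(log(ft$scores)), tolerance = 1e-12)
  expect_equal(ft$W, prod(ft$scores), tolerance = 1e-9)
  expect_equal(ft$mean_goals, mean(ft$goals))
  # stationary closed form over all mappings: W = (512/33)^24
  logW <- sum(vapply(seq_len(24), function(mi) {
    br2 <- constant_option_brain(enumerate_action_maps()[[mi]])
    log(evaluate_on_mapping(br2, mi, T = 512, b = 0, seed = mi)$score)
  }, 0))
  expect_equal(logW, 24 * log(512 / 33), tolerance = 1e-9)
})

test_that("goal counts depend on the assigned action, not the mapping label", {
  # a sensor-ignoring brain emitting a fixed option: two mappings assigning
  # the same action to that option give identical episodes under one seed
  maps <- enumerate_action_maps()
  fixed_option <- 0L
  same <- which(vapply(maps, function(m) unname(m[1]), 0L) == 0L) # option 0 -> forward
  br <- brain_from_gates(list(deterministic_gate(0, c(4, 5), c(0L, 0L))))
  e1 <- evaluate_on_mapping(br, same[1], T = 128, b = 0, seed = 77)
  e2 <- evaluate_on_mapping(br, same[2], T = 128, b = 0, seed = 77)
  expect_equal(e1$score, e2$score)
  expect_equal(e1$goal_count, e2$goal_count)
})
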