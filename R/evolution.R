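# Generational genetic algorithm: complete (elitism-free) replacement, N
# independent tournaments of size 5 with replacement, asexual inheritance
# with mutation. Every individual's evaluation gets its own seed substream
# derived from the master seed, so any single evaluation can be replayed.

#' Configuration for an evolution run
#'
#' @param population_size number of agents per generation (default 100).
#' @param generations number of generations to run.
#' @param tournament_size tournament size (default 5).
#' @param T updates per mapping evaluation (default 512).
#' @param b per-goal fitness bonus (default 512).
#' @param gate_types gate kinds available to this condition: any subset of
#'   deterministic / probabilistic / feedback. Initial genomes are seeded
#'   only with codons of these kinds and the decoder skips the others.
#' @param genome_length initial genome length (default 5000).
#' @param mutation mutation parameters from [mutation_rates()].
#' @param seed master seed; every stochastic component derives a named
#'   substream from it via [seed_stream()].
#' @param size,fill,spawn_dist maze parameters (see [generate_maze()]).
#' @param snapshot_genomes archive full genomes every generation (default
#'   `TRUE`), enabling exact ancestor reconstruction and replay.
#' @return a list of class `mb_config`.
#' @export
evolution_config <- function(population_size = 100L, generations = 100L,
                             tournament_size = 5L, T = 512L, b = 512,
                             gate_types = .mb_gate_kinds,
                             genome_length = 5000L,
                             mutation = mutation_rates(), seed = 1L,
                             size = 64L, fill = 1 / 7, spawn_dist = 32L,
                             snapshot_genomes = TRUE) {
  gate_types <- match.arg(gate_types, .mb_gate_kinds, several.ok = TRUE)
  if (tournament_size > population_size) {
    stop("tournament_size must not exceed population_size")
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 T = as.integer(T), b = b, gate_types = gate_types,
                 genome_length = as.integer(genome_length),
                 mutation = mutation, seed = as.integer(seed),
                 size = as.integer(size), fill = fill,
                 spawn_dist = as.integer(spawn_dist),
                 snapshot_genomes = isTRUE(snapshot_genomes)),
            class = "mb_config")
}

#' Tournament selection
#'
#' Samples `k` individuals uniformly with replacement and returns the index
#' of the one with maximal fitness, breaking ties uniformly at random.
#'
#' @param fitness numeric vector of population fitnesses (log-scale fitness
#'   is used throughout to avoid overflow).
#' @param k tournament size (default 5).
#' @return the selected index.
#' @export
tournament_select <- function(fitness, k = 5L) {
  n <- length(fitness)
  if (n == 0L) stop("population is empty")
  cand <- sample.int(n, k, replace = TRUE)
  f <- fitness[cand]
  best <- cand[f == max(f)]
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best[1L]
}

#' Produce the next generation
#'
#' Each of the N offspring is the mutated genome of a tournament-selected
#' parent.
#'
#' @param genomes list of parent `mb_genome` objects.
#' @param fitness numeric vector of parent fitnesses (same order).
#' @param config an `mb_config`.
#' @param next_id first id to assign to offspring.
#' @return list of offspring `mb_genome` objects (with `parent_id` set).
#' @export
next_generation <- function(genomes, fitness, config, next_id = 1L) {
  n <- config$population_size
  offspring <- vector("list", n)
  for (i in seq_len(n)) {
    p <- tournament_select(fitness, config$tournament_size)
    offspring[[i]] <- mutate_genome(genomes[[p]], config$mutation,
                                    id = next_id + i - 1L)
  }
  offspring
}

.census_row <- function(brain) {
  cs <- gate_census(brain)
  c(n_det = cs[["deterministic"]], n_prob = cs[["probabilistic"]],
    n_fb = cs[["feedback"]])
}

#' Run an evolution experiment
#'
#' Executes the generational loop: evaluate every individual on all 24
#' option-to-action mappings, archive ancestry and statistics, select by
#' tournament, mutate. Fully reproducible from `config$seed`: generation
#' `g`, individual `i`, mapping `m` always evaluates under seed
#' `seed_stream(seed, 2, g, i)` + mapping substream, independent of
#' execution order.
#'
#' @param config an `mb_config` from [evolution_config()].
#' @param verbose print per-generation progress.
#' @return an object of class `mb_run`: `config`, `stats` (per-generation
#'   data frame), `archive` (per-individual data frame with generation, id,
#'   parent_id, idx, logW, mean_goals and gate census), `genomes` (list
#'   keyed by id when `snapshot_genomes`), `final_ids`.
#' @export
run_evolution <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "mb_config"))
  N <- config$population_size
  G <- config$generations
  master <- config$seed
  # founders
  genomes <- vector("list", N)
  for (i in seq_len(N)) {
    set.seed(seed_stream(master, 1L, 0L, i))
    genomes[[i]] <- random_genome(config$genome_length, config$gate_types,
                                  id = i)
  }
  next_id <- N + 1L
  archive <- vector("list", G + 1L)
  stats <- vector("list", G + 1L)
  genome_store <- list()
  # founders are generation 0; each subsequent generation is selected and
  # mutated from the previous one, so the archive spans 0..G and a line of
  # descent from generation G has G + 1 links.
  for (g in 0:G) {
    logW <- numeric(N)
    mgoals <- numeric(N)
    census <- matrix(0L, N, 3L)
    for (i in seq_len(N)) {
      brain <- build_brain(genomes[[i]], config$gate_types)
      fit <- fitness(brain, T = config$T, b = config$b,
                     seed = seed_stream(master, 2L, g, i),
                     size = config$size, fill = config$fill,
                     spawn_dist = config$spawn_dist)
      logW[i] <- fit$logW
      mgoals[i] <- fit$mean_goals
      census[i, ] <- .census_row(brain)
    }
    ids <- vapply(genomes, function(x) as.integer(x$id), 0L)
    pids <- vapply(genomes, function(x) as.integer(x$parent_id), 0L)
    archive[[g + 1L]] <- data.frame(
      generation = g, id = ids, parent_id = pids, idx = seq_len(N),
      logW = logW, mean_goals = mgoals,
      n_det = census[, 1], n_prob = census[, 2], n_fb = census[, 3]
    )
    stats[[g + 1L]] <- data.frame(
      generation = g, best_logW = max(logW), mean_logW = mean(logW),
      best_goals = max(mgoals), mean_goals = mean(mgoals),
      mean_n_det = mean(census[, 1]), mean_n_prob = mean(census[, 2]),
      mean_n_fb = mean(census[, 3])
    )
    if (config$snapshot_genomes) {
      genome_store[as.character(ids)] <- genomes
    }
    if (verbose) {
      message(sprintf("generation %d: best logW %.3f, best goals %.3f",
                      g, max(logW), max(mgoals)))
    }
    if (g < G) {
      set.seed(seed_stream(master, 3L, g))
      genomes <- next_generation(genomes, logW, config, next_id = next_id)
      next_id <- next_id + N
    }
  }
  structure(list(config = config, stats = do.call(rbind, stats),
                 archive = do.call(rbind, archive), genomes = genome_store,
                 final_ids = archive[[G + 1L]]$id),
            class = "mb_run")
}

#' @export
print.mb_run <- function(x, ...) {
  s <- x$stats
  cat("evolution run: N = ", x$config$population_size, ", ",
      x$config$generations, " generations, gates {",
      paste(x$config$gate_types, collapse = ", "), "}, seed ",
      x$config$seed, "\n", sep = "")
  cat("  final generation: best goals/mapping ",
      format(s$best_goals[nrow(s)], digits = 4), ", best log W ",
      format(s$best_logW[nrow(s)], digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mb_run <- function(object, ...) {
  s <- object$stats
  out <- list(
    config = object$config,
    first = s[1, ], last = s[nrow(s), ],
    improvement_goals = s$best_goals[nrow(s)] - s$best_goals[1],
    improvement_logW = s$best_logW[nrow(s)] - s$best_logW[1]
  )
  class(out) <- "summary.mb_run"
  out
}

#' @export
print.summary.mb_run <- function(x, ...) {
  print(x$config$gate_types)
  cat("best goals/mapping: ", format(x$first$best_goals, digits = 4), " -> ",
      format(x$last$best_goals, digits = 4), "\n", sep = "")
  cat("best log W: ", format(x$first$best_logW, digits = 6), " -> ",
      format(x$last$best_logW, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
plot.mb_run <- function(x, ...) {
  s <- x$stats
  graphics::par(mfrow = c(1, 2))
  graphics::plot(s$generation, s$best_logW, type = "l", xlab = "generation",
                 ylab = "log W", main = "fitness", ...)
  graphics::lines(s$generation, s$mean_logW, lty = 2)
  graphics::plot(s$generation, s$best_goals, type = "l", xlab = "generation",
                 ylab = "goals per mapping", main = "goal reaching", ...)
  graphics::lines(s$generation, s$mean_goals, lty = 2)
  invisible(x)
}

#' Trace the line of descent
#'
#' Follows parent links from a final-generation individual back to
#' generation 1, and finds the most recent common ancestor (MRCA) of the
#' whole final population. Every mutation that swept the population lies on
#' the line of descent at or before the MRCA.
#'
#' @param run an `mb_run`, or its `archive` data frame.
#' @param from id of the final-generation individual to start from; a random
#'   one when `NULL`.
#' @param seed seed for the random pick.
#' @return a list with `lod` (ids, oldest first), `lod_table` (archive rows
#'   along the path), `mrca_id`, `mrca_generation`.
#' @export
trace_lod <- function(run, from = NULL, seed = NULL) {
  archive <- if (inherits(run, "mb_run")) run$archive else run
  G <- max(archive$generation)
  finals <- archive$id[archive$generation == G]
  parent <- setNames(archive$parent_id, archive$id)
  walk <- function(id) {
    path <- id
    repeat {
      p <- parent[[as.character(id)]]
      if (is.na(p)) break
      if (!as.character(p) %in% names(parent)) {
        stop("broken parent link at id ", id)
      }
      id <- p
      path <- c(p, path)
    }
    path
  }
  if (is.null(from)) {
    if (!is.null(seed)) set.seed(seed)
    from <- finals[sample.int(length(finals), 1L)]
  }
  lod <- walk(from)
  # MRCA: deepest id shared by the ancestor paths of all final individuals
  common <- Reduce(intersect, lapply(finals, walk))
  mrca <- if (length(common)) common[length(common)] else NA_integer_
  list(
    lod = lod,
    lod_table = archive[match(lod, archive$id), ],
    mrca_id = mrca,
    mrca_generation = if (is.na(mrca)) NA_integer_ else
      archive$generation[match(mrca, archive$id)]
  )
}
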