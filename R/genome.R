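# Byte-string genomes: creation, start-codon gene discovery, mutation.

# Two-byte start codons, second byte = ones'-complement of the first, so
# accidental occurrences in random sequence are rare (p = 3/256^2 per site).
.mb_codons <- list(
  deterministic = c(42L, 213L),
  probabilistic = c(43L, 212L),
  feedback      = c(44L, 211L)
)

.mb_gate_kinds <- names(.mb_codons)

.MB_MIN_GENOME <- 1000L
.MB_MAX_GENOME <- 20000L

#' Create a random genome
#'
#' A genome is an ordered sequence of byte values (0--255). Fresh genomes are
#' filled with uniform random bytes and then seeded with 12 two-byte start
#' codons at non-overlapping random positions, split evenly over the allowed
#' gate kinds, each at least 200 sites from the genome end so payloads have
#' room (payloads additionally wrap around the end, so every codon decodes).
#'
#' @param length genome length in sites; must be at least 1000. Default 5000,
#'   the initial-population length.
#' @param gate_types character vector of gate kinds to seed codons for; any
#'   subset of `c("deterministic", "probabilistic", "feedback")`. The 12
#'   codons are divided evenly among them.
#' @param n_codons total number of start codons to insert (default 12).
#' @param id,parent_id optional identifiers carried on the genome.
#' @return an object of class `mb_genome` with fields `sites`, `id`,
#'   `parent_id`.
#' @examples
#' g <- random_genome(5000)
#' length(g$sites)
#' @export
random_genome <- function(length = 5000L, gate_types = .mb_gate_kinds,
                          n_codons = 12L, id = NA_integer_,
                          parent_id = NA_integer_) {
  length <- as.integer(length)
  if (is.na(length) || length < .MB_MIN_GENOME) {
    stop("genome length must be at least ", .MB_MIN_GENOME)
  }
  gate_types <- match.arg(gate_types, .mb_gate_kinds, several.ok = TRUE)
  if (n_codons %% length(gate_types) != 0) {
    stop("n_codons must be divisible by the number of gate types")
  }
  sites <- sample(0:255, length, replace = TRUE)
  kinds <- rep(gate_types, each = n_codons / length(gate_types))
  # non-overlapping codon positions, >= 200 sites from the end
  hi <- length - 200L
  repeat {
    pos <- sort(sample.int(hi, n_codons))
    if (all(diff(pos) >= 2L)) break
  }
  pos <- sample(pos) # random assignment of positions to kinds
  for (k in seq_along(kinds)) {
    codon <- .mb_codons[[kinds[k]]]
    sites[pos[k]] <- codon[1]
    sites[pos[k] + 1L] <- codon[2]
  }
  new_genome(sites, id = id, parent_id = parent_id)
}

#' Construct a genome from a site vector
#'
#' @param sites integer vector with values in 0--255.
#' @param id,parent_id optional identifiers.
#' @return an `mb_genome` object.
#' @export
new_genome <- function(sites, id = NA_integer_, parent_id = NA_integer_) {
  sites <- as.integer(sites)
  if (any(is.na(sites)) || any(sites < 0L) || any(sites > 255L)) {
    stop("genome sites must be integers in [0, 255]")
  }
  structure(list(sites = sites, id = id, parent_id = parent_id),
            class = "mb_genome")
}

#' @export
length.mb_genome <- function(x) length(x$sites)

#' @export
print.mb_genome <- function(x, ...) {
  genes <- find_genes(x)
  kinds <- vapply(genes, `[[`, "", "gate_kind")
  cat("Markov Brain genome: ", length(x$sites), " sites, ",
      length(genes), " genes (",
      sum(kinds == "deterministic"), " det, ",
      sum(kinds == "probabilistic"), " prob, ",
      sum(kinds == "feedback"), " fb)\n", sep = "")
  invisible(x)
}

# circular slice of n sites starting at `from` (1-based)
.circ <- function(sites, from, n) {
  L <- length(sites)
  sites[((from - 1L + seq_len(n) - 1L) %% L) + 1L]
}

#' Locate genes (start codons) on a genome
#'
#' Scans the genome left to right for the two-byte start codons of each gate
#' kind (detection wraps around the end, as do payloads, so every codon marks
#' a complete gene). Overlapping genes are permitted.
#'
#' @param genome an `mb_genome`.
#' @return a list of gene spans; each span is a list with `gate_kind`,
#'   `start` (1-based index of the codon's first site) and `payload` (the
#'   bytes following the codon, read circularly, long enough for any gate).
#' @export
find_genes <- function(genome) {
  sites <- genome$sites
  L <- length(sites)
  nxt <- c(sites[-1L], sites[1L])
  spans <- list()
  for (kind in .mb_gate_kinds) {
    codon <- .mb_codons[[kind]]
    at <- which(sites == codon[1] & nxt == codon[2])
    for (s in at) {
      spans[[length(spans) + 1L]] <- list(
        gate_kind = kind, start = s,
        payload = .circ(sites, from = ((s + 1L) %% L) + 1L, n = 277L)
      )
    }
  }
  spans[order(vapply(spans, `[[`, 0L, "start"))]
}

#' Default mutation parameters
#'
#' Per-offspring mutation scheme: each site is independently replaced by a
#' uniform random byte with probability `point_rate`; with probability
#' `dup_prob` (and only below the maximum genome size) a stretch of random
#' length in `dup_range` is copied and re-inserted outside the source
#' interval; with probability `del_prob` (and only above the minimum size) a
#' stretch of random length in `del_range` is deleted. Offspring length is
#' kept inside `[min_len, max_len]` by truncating the inserted or deleted
#' stretch.
#'
#' @param point_rate per-site substitution probability (default 0.003).
#' @param dup_prob per-offspring duplication probability (default 0.02).
#' @param del_prob per-offspring deletion probability (default 0.02).
#' @param dup_range inclusive duplication length range (default 128--512).
#' @param del_range inclusive deletion length range (default 128--255).
#' @param min_len,max_len genome length bounds (1000, 20000).
#' @return a named list of parameters.
#' @export
mutation_rates <- function(point_rate = 0.003, dup_prob = 0.02,
                           del_prob = 0.02, dup_range = c(128L, 512L),
                           del_range = c(128L, 255L),
                           min_len = .MB_MIN_GENOME, max_len = .MB_MAX_GENOME) {
  list(point_rate = point_rate, dup_prob = dup_prob, del_prob = del_prob,
       dup_range = as.integer(dup_range), del_range = as.integer(del_range),
       min_len = as.integer(min_len), max_len = as.integer(max_len))
}

#' Mutate a genome
#'
#' Applies, in order: per-site point mutations, then at most one gene
#' duplication, then at most one deletion (see [mutation_rates()]). The
#' operator is total: any valid genome yields a valid offspring genome with
#' length in `[min_len, max_len]`.
#'
#' @param genome an `mb_genome`.
#' @param rates parameter list from [mutation_rates()].
#' @param id identifier for the offspring genome.
#' @return the offspring `mb_genome`, with `parent_id` set to the parent's id.
#' @export
mutate_genome <- function(genome, rates = mutation_rates(), id = NA_integer_) {
  sites <- genome$sites
  L <- length(sites)
  # point mutations
  if (rates$point_rate > 0) {
    hit <- which(runif(L) < rates$point_rate)
    if (length(hit)) sites[hit] <- sample(0:255, length(hit), replace = TRUE)
  }
  # duplication: copy a stretch and insert it outside the source interval
  if (runif(1) < rates$dup_prob && L < rates$max_len) {
    len <- sample(rates$dup_range[1]:rates$dup_range[2], 1L)
    len <- min(len, rates$max_len - L) # never exceed the maximum size
    if (len >= 1L && L - len + 1L >= 1L) {
      src <- sample.int(L - len + 1L, 1L)
      stretch <- sites[src:(src + len - 1L)]
      # insertion point j means "insert after site j"; j outside the source
      ok <- c(0:(src - 1L), (src + len - 1L):L)
      j <- ok[sample.int(length(ok), 1L)]
      sites <- append(sites, stretch, after = j)
    }
  }
  L <- length(sites)
  # deletion
  if (runif(1) < rates$del_prob && L > rates$min_len) {
    len <- sample(rates$del_range[1]:rates$del_range[2], 1L)
    len <- min(len, L - rates$min_len) # never drop below the minimum size
    if (len >= 1L) {
      start <- sample.int(L - len + 1L, 1L)
      sites <- sites[-(start:(start + len - 1L))]
    }
  }
  new_genome(sites, id = id, parent_id = genome$id)
}

#' Write genomes to a plain-text CSV with a JSON sidecar
#'
#' One genome per row, comma-separated byte values (rows may have different
#' lengths). A JSON sidecar records `id`, `parent_id` and `generation` in row
#' order.
#'
#' @param genomes list of `mb_genome` objects.
#' @param csv_path output CSV path.
#' @param json_path sidecar path; defaults to `csv_path` with a `.json`
#'   extension.
#' @param generation optional integer vector of generations (recycled).
#' @return invisibly, the CSV path.
#' @export
write_genomes <- function(genomes, csv_path,
                          json_path = sub("\\.csv$", ".json", csv_path),
                          generation = NA_integer_) {
  lines <- vapply(genomes, function(g) paste(g$sites, collapse = ","), "")
  writeLines(lines, csv_path)
  meta <- data.frame(
    id = vapply(genomes, function(g) as.integer(g$id), 0L),
    parent_id = vapply(genomes, function(g) as.integer(g$parent_id), 0L),
    generation = rep_len(as.integer(generation), length(genomes))
  )
  jsonlite::write_json(meta, json_path, dataframe = "columns", na = "null")
  invisible(csv_path)
}

#' Read genomes written by [write_genomes()]
#'
#' @inheritParams write_genomes
#' @return a list of `mb_genome` objects; the sidecar's `generation` is
#'   attached as attribute `generation` on the list.
#' @export
read_genomes <- function(csv_path,
                         json_path = sub("\\.csv$", ".json", csv_path)) {
  lines <- readLines(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    sites <- as.integer(strsplit(lines[k], ",", fixed = TRUE)[[1]])
    out[[k]] <- new_genome(sites,
                           id = if (k <= length(meta$id)) meta$id[k] else NA_integer_,
                           parent_id = if (k <= length(meta$parent_id)) meta$parent_id[k] else NA_integer_)
  }
  attr(out, "generation") <- meta$generation
  out
}
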