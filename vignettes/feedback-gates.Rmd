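---
title: "Evolving lifetime learning with feedback gates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving lifetime learning with feedback gates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovbrain)
```

## The model

A Markov Brain is a network of logic gates over 16 binary nodes: nodes 0--3
are sensors, nodes 4--5 are motor outputs, nodes 6--15 are hidden. Updates
are synchronous and double-buffered: all gates read the current state, then
their outputs are OR-combined into a fresh zero next-state that replaces the
hidden and output nodes. Because the next-state starts from zero, outputs
and hidden values are not latched: any information the agent wants to keep
must be actively rewritten each update, which is what makes hidden-node
memory analogous to working memory.

Three gate kinds exist. A *deterministic* gate maps each input pattern to
one output pattern through a logic table. A *probabilistic* gate holds a
row-stochastic matrix $P$ with $P_{io}$ the probability of emitting output
pattern $o$ given input pattern $i$; each row must satisfy
$\sum_o P_{io} = 1$. A *feedback* gate is a probabilistic gate that can
additionally rewrite its own $P$ during the agent's lifetime — the package's
core mechanism, a multiplicative-weights-style lifetime update embedded in
an evolvable substrate. Two extra genetically wired inputs carry positive
and negative feedback; reading a 0 does nothing, reading a 1 triggers an
update. The gate keeps a buffer (depth 1--4, evolvable) of its most recent
$(i, o)$ decisions. On feedback of either sign, for the decision $k$ steps
back a magnitude $u \sim \mathcal{U}[0, \delta_k]$ is drawn (separate
evolvable $\delta$ schedules for positive and negative feedback) and
$P_{io}$ is shifted by $\pm u$, clamped to $[0.01, 0.99]$, and the row
renormalized. Crucially, the feedback is *internal*: it originates from
other nodes of the same brain, so the machinery that decides what counts as
"good" must itself evolve.

### Numerical choices in the feedback update

The renormalization after a shift is not fully determined by the row-sum
constraint, so the package fixes it as: set the credited entry to its
clamped target, rescale the remaining entries proportionally (preserving
their relative odds), then iteratively raise any entry that fell below 0.01
back to the floor and rescale the rest. With $K$ columns this gives every
entry an effective ceiling of $\min(0.99,\, 1 - 0.01(K-1))$; the floors keep
every output reachable forever, so a feedback gate can always un-learn. The
same routine exists twice — in R (`apply_feedback`) as the reference
implementation and in C++ inside the episode engine — and a property test
checks they agree to $10^{-12}$ on random rows. Further fixed choices, each
made once:

* simultaneous positive and negative feedback applies positive first, then
  negative, in one update — deterministic, order-stable semantics;
* feedback lines are read from the pre-update state and applied *before*
  the gate samples its output for the current update, because feedback
  refers to the consequences of past decisions; the new decision is
  buffered after sampling;
* the buffer stores $(i, o)$ index pairs rather than probability values,
  since the update targets the current table entry;
* decoded probability rows are built as (byte value + 1) and normalized, so
  every byte string decodes to a valid gate and no row is degenerate.

## Genome and mutation

Gates are encoded on a byte-string genome (values 0--255, length kept in
$[1000, 20000]$). A gene starts at a two-byte start codon — one codon per
gate kind; the second byte is the ones'-complement of the first
(deterministic 42/213, probabilistic 43/212, feedback 44/211), making
accidental codons rare ($3 \cdot 256^{-2}$ per site). Founding genomes have
5000 random sites with 12 codons written at non-overlapping positions,
split evenly across the allowed gate kinds and placed at least 200 sites
from the end; payloads additionally wrap circularly past the genome end so
every codon decodes to a complete gate. Per offspring: each site mutates
with probability 0.003; with probability 0.02 (below the 20000-site cap) a
stretch of 128--512 sites is duplicated and re-inserted outside its source
interval; with probability 0.02 (above the 1000-site floor) a stretch of
128--255 sites is deleted. The duplication/deletion probabilities are
treated as per-offspring events, and the inserted or deleted stretch is
truncated where needed so the bounds are never crossed. There is no
crossover: inheritance is strictly asexual.

## The task

The environment is a 64×64 grid with a solid border; each interior tile is
a wall with probability 1/7. A goal tile is drawn uniformly among empty
tiles, shortest-path distances $d$ to the goal are computed over 4-neighbour
moves, and every reachable tile gets an arrow toward a strictly closer
neighbour (ties broken uniformly). If no tile has $d = 32$ the maze is
regenerated. The agent spawns on a uniformly random $d = 32$ tile with a
random heading and sees only the arrow of its own tile, rotated into its
frame (forward/right/backward/left, one-hot on the four sensors).

The brain's two output bits select one of four options; a per-lifetime
bijection maps options onto the actions *forward*, *nothing*, *turn-left*,
*turn-right*. There are $4! = 24$ such mappings, and fitness evaluates all
of them — so a high-scoring agent cannot hard-wire its motor code; it must
discover, within each lifetime, which mapping currently applies. Each
mapping runs for $T = 512$ updates in a fresh maze with the brain reset to
birth state; reaching the goal respawns the agent (same maze, learned
tables intact). Every update contributes $1/(1+d)$ from the tile the agent
ends the update on, plus a bonus $b$ per goal, giving

$$W = \prod_{n=0}^{n<24}\left(\sum_{t=0}^{t<512} \frac{1}{1+d} + g_n b\right)$$

with $g_n$ the goal count under mapping $n$. Design choices here: a blocked
forward move is a no-op (walls hinder, they do not terminate); a fresh maze
is generated per mapping (each of the 24 lifetimes is an independent
learning problem); $b$ is configurable with default 512, so a single goal
outweighs the maximal dwell score of a whole episode without overflowing
the product; the product is accumulated in log-domain and selection
compares $\log W$; $d$ is read after the action from the resulting tile,
and dwell reward accrues on every update including "do nothing", because
the reward depends only on position. The closed form for a stationary agent
spawned at $d = 32$, $512/33$ per mapping, anchors the implementation in
tests.

## Evolution

Generations replace completely (no elitism). Each of the $N$ offspring is
the mutated genome of a parent chosen by a tournament of 5 drawn uniformly
with replacement, ties broken at random. Population size is not dictated by
the model; the default is 100, and the desk-scale experiments in the test
suite use 50. The archive records every individual's id, parent id, log
fitness, mean goals and gate census, plus (by default) full genome
snapshots, so any ancestor can be reconstructed exactly and the line of
descent (LOD) of a random final individual traced to generation 0; the most
recent common ancestor of the final population is the deepest id shared by
all final ancestor paths.

Every stochastic component draws from a named seed substream
(`seed_stream(master, stream, generation, individual, ...)`), so a single
archived evaluation can be replayed bit-exactly regardless of execution
order — reproducibility is part of the package's tested surface
(`cmd_evolve` twice with one config yields byte-identical archives).

## Analyses

* **Frozen-feedback control** (`frozen_performance`): re-evaluate with
  table updates disabled; sampling and buffering proceed unchanged. The gap
  to the normal evaluation measures how much performance depends on
  lifetime learning rather than working memory.
* **Mutual information of a table** (`table_mutual_information`):
  $I(I;O) = H(O) - H(O\mid I)$ in bits, with a uniform input marginal by
  default; unvisited rows deliberately enter the average, and an empirical
  marginal (row visit weights) is available behind an argument. Base-2
  logarithms are used throughout. $\bar\Delta$ (`delta_mi`) is the mean of
  $MI(P_\mathrm{end}) - MI(P_\mathrm{birth})$ over feedback gates and
  mappings.
* **Binned correlation** (`binned_delta_vs_performance`): unit-width bins
  over performance (mean goals per mapping), Pearson correlation of bin
  centers against mean $\bar\Delta$ per bin.
* **Gate census and action usage**: counts by decoded kind, and per-trace
  fractions of forward / nothing / turn (left and right pooled).

Performance in these analyses means goals reached per mapping; the
product-form $W$ is logged alongside but is unwieldy for binning.

## What the desk-scale experiments do and do not show

The generator and task defaults above *are* the study conditions; the test
suite exercises them at sizes a single CPU handles in minutes: populations
of 50 evolved for 200 generations at $T = 128$ across 5 seeds (the
evolvability check asks only that the median best goal count improves from
generation 1 to 200), plus hand-built exemplars. A hand-wired reactive
arrow-follower reaches the goal about 11--12 times in 512 updates, bounding
what a perfect policy achieves; a one-gate feedback learner whose positive
line is its own forward sensor reaches the goal 1--3 times per mapping with
learning enabled and essentially never frozen — a minimal, fully
inspectable demonstration that internally generated feedback suffices for
lifetime learning. What desk scale does *not* show: the long-run phenomena
(hundreds of replicates over $5\times10^5$ generations), population-level
statistics at that scale, or the asymptotic division of labour between
heuristic and learning strategies. The operations that compute those
statistics are all present; their published-scale values are not reproduced
here.

## Known limitations

* Feedback rewires probabilities only, never connections.
* The maze offers full local observability of the arrow label; no noise on
  sensors or actuators is modelled.
* The mutual-information estimator with a uniform marginal is one of
  several defensible conventions; absolute MI levels depend on it, though
  lifetime *changes* are less sensitive.
* Brains hold lifetime state in an external-pointer engine object; they are
  rebuilt from genomes rather than serialized.
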