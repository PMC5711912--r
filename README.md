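# markovbrain

Evolvable Markov Brains with lifetime-learning **feedback gates**, for
studying how learning itself can evolve.

## The problem

Evolution adapts populations across generations; learning adapts an
individual within its lifetime. Most systems that combine the two hand the
agent an *external*, objective reward signal. Natural organisms get no such
signal: the machinery that decides whether an outcome was good or bad must
itself evolve. This package implements a model system for that question —
Markov Brains (networks of deterministic and probabilistic logic gates over
16 binary nodes, genetically encoded and evolved by a genetic algorithm)
extended with **feedback gates**: probabilistic gates that modify their own
probability tables from *internally generated* positive/negative feedback,
using a buffered multiplicative-style update. Hidden node states give the
agent volatile working memory; feedback gates give it long-term memory that
physically changes the controller.

A feedback gate holds a row-stochastic table $P_{io}$ (row sums 1), buffers
its recent $(i,o)$ decisions (depth 1–4, evolvable), and on a 1 at its
positive (negative) feedback input shifts each buffered $P_{io}$ by a random
amount in $[0, \delta_k]$ up (down), clamps it to $[0.01, 0.99]$, and
renormalizes the row.

Agents live in a procedurally generated 64×64 maze whose tiles carry arrows
along shortest paths to a goal. The catch: the brain's two output bits pick
one of four *options*, and a per-lifetime random bijection maps options to
the actions (forward / nothing / turn-left / turn-right). Fitness evaluates
all 24 bijections, 512 updates each, spawning at shortest-path distance 32:

$$W=\prod_{n=0}^{n<24}\Big(\sum_{t=0}^{t<512}\tfrac{1}{1+d}+g_n b\Big)$$

so an agent only scores well if it *learns its own motor mapping* within
each lifetime. Tournament selection (size 5), asexual inheritance, byte
string genomes with point mutation, gene duplication and deletion, and
line-of-descent tracing complete the loop.

## Worked example

A minimal, fully inspectable learner: one feedback gate wired sensors →
options, whose *positive feedback line is its own forward-arrow sensor* —
actions that lead to tiles pointing straight ahead get reinforced. No
external reward is involved anywhere.

```r
library(markovbrain)
set.seed(42)

gate <- feedback_gate(
  input_nodes = 0:3, output_nodes = c(4, 5),
  table = matrix(0.25, 16, 4),          # uniform at birth: knows nothing
  pos_node = 0, neg_node = 15, depth = 1, delta_pos = 0.45, delta_neg = 0
)
brain <- brain_from_gates(list(gate))
brain
#> Markov Brain: 16 nodes, 1 gates (0 det, 0 prob, 1 fb), feedback enabled

fitness(brain, b = 0, seed = 1)
#> fitness over 24 mappings: log W = 76.4398, goals per mapping 2.5 (max 10)

frozen_performance(brain, b = 0, seed = 1)   # same agent, learning disabled
#> fitness over 24 mappings: log W = 67.2709, goals per mapping 0 (max 0)

fit <- fitness(brain, b = 0, seed = 2, collect_tables = TRUE)
delta_mi(snapshot_pairs(fit))
#> [1] 0.3143534
```

With learning enabled the agent reaches the goal 2.5 times per mapping on
average (up to 10 under favourable mappings); frozen, it never reaches it —
the performance gap is pure lifetime learning. The last number is
$\bar\Delta$: the mean gain in mutual information between a feedback
table's input and output over a lifetime (in bits), i.e. how much the gate
physically learned.

Evolution experiments run from a config object or YAML file:

```r
cfg <- evolution_config(population_size = 50, generations = 200, T = 128,
                        seed = 1)
run <- run_evolution(cfg)      # or: cmd_evolve("config.yaml", "runs/exp1")
plot(run)
lod <- trace_lod(run)          # line of descent + MRCA
```

A thin command-line wrapper (`inst/cli/markovbrain.R`) exposes
`evolve` / `analyze` / `replay`; `analyze` writes the line of descent, the
frozen-vs-normal control, per-gate mutual-information change and
action-usage profiles; `replay` re-runs any archived evaluation bit-exactly
from its derived seed.

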