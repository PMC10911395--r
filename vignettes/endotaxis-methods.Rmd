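---
title: "Endotaxis: model, algorithms, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endotaxis: model, algorithms, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotaxis)
```

This vignette documents the model equations, the learning and navigation
algorithms, and the statistical machinery implemented by the package,
including the modelling decisions where several formalizations were
possible.

## 1. Circuit model

The environment is a connected undirected graph with `n` nodes (0-based
ids everywhere in the public API). Three cell populations:

* **Point cells** `u`: one-hot code of the agent's location. With
  habituation active, the active entry is the node's sensitivity `h`
  instead of 1.
* **Map cells** `v`: a recurrent network with synapses `M` (`M[i, j]`
  from cell `j` onto cell `i`, zero diagonal) and neuron gain `gamma`.
  Steady state solves `v = f(u + M v)`.
* **Goal cells** `r = G v`: linear readouts whose synapses `G` memorize
  map-activity profiles.

Two activation functions `f` are supported:

* **linear**: `f(w) = gamma * w`, so `v = (I/gamma - M)^{-1} u`. This is
  computed by a direct solve; it requires `gamma * rho(M) < 1` where
  `rho` is the spectral radius, otherwise the functions stop with an
  "unstable gain" error. The *critical gain* of a graph is
  `1 / rho(A)` (`critical_gain()`): 0.5 for the 50-node ring, ~0.3827 for
  the 127-node binary tree.
* **saturating**: `f(w) = gamma * min(w, 1)`. The fixed point is found by
  direct iteration to absolute tolerance 1e-10 (warm-started during
  walks). Saturation keeps every map cell's output at most `gamma`, which
  allows stable operation above the linear critical gain.

With a perfect map (`M = A`) and linear activation, the goal signal
between agent node `x` and goal node `y` is the matrix
`E = t(Y) Y` with `Y = (I/gamma - A)^{-1}` (`theory_goal_matrix()`). For
small gain `E[x, y] ~ gamma^(2 + D[x, y])`, so the signal is a strictly
decreasing function of graph distance `D` — the basis of navigation.

**Decision — adjacency diagonal.** All adjacency matrices are
zero-diagonal: the printed critical gains above hold only without
self-loops, and the learning rule never potentiates diagonal synapses.
`adjacency_matrix(g, self_loops = TRUE)` provides the variant with ones
on the diagonal for sensitivity experiments.

## 2. Learning (Algorithm: map + goal plasticity)

During a random exploration walk the agent applies, at each step into
node `s(t)`:

1. compute `v(t)` with the **pre-update** map synapses;
2. **map rule**: for every cell pair with presynaptic activity
   `v_j(t-1) > theta` and postsynaptic activity `v_i(t) > theta`, set
   `M[i, j] = M[j, i] = 1` (one-shot potentiation; only the traveled
   direction in `directed` mode);
3. **goal rule**: for every goal cell `k` whose resource is present at
   `s(t)` (`F[k, s] > 0`), update
   `G[k, ] += alpha * (F[k, s] - r_k) * v(t)`.

The threshold `theta` must sit between the recurrently driven activity of
non-adjacent cells and the directly driven activity `~gamma`; the
convention `theta = 0.9 * gamma` is used wherever a caption does not fix
it. `v(t)` is carried to the next step as the presynaptic trace — it is
*not* recomputed after the map update, which is what lets a single
traversal imprint one edge at a time.

**Decision — goal update sign.** The update is applied with its natural
sign whenever the resource is present, so an over-predicted resource
(`r_k > F`) is corrected downward. This follows the error-correcting
form of the rule; the gate is presence of the resource, not positivity of
the shortfall.

**Decision — first node of a walk.** Goal learning also runs at the
walk's first node before any step. This is required by the homing
scenario, where the entrance is tagged as a goal before the agent has
any map.

### Forgetting (`delta > 0`)

With a positive forgetting rate the potentiation branch is complemented
by depression:

* map: a high-pre / low-post event multiplies both `M[i, j]` and
  `M[j, i]` by `exp(-delta)`; traveled links are reset to 1, so only
  links that are never traversed decay.
* goals: with prediction error `d_k = F[k, s] - r_k`, positive error
  potentiates (`G[k, ] += alpha * d_k * v`), otherwise the goal synapses
  decay as `G[k, j] *= exp(-delta * v_j)` — activity-weighted, so only
  the neighborhood the agent currently occupies forgets.

**Decision — depression gate.** The goal-depression branch runs at every
node (not only at resource sites): a vanished resource must be unlearned
precisely where `F = 0` while the stale goal signal is still positive.

### Habituation during learning

`learn_walk(..., habituation = TRUE)` scales the point-cell drive by the
node's sensitivity: `u_i = delta_{i, s(t)} * h_i`, with
`h_s *= exp(-beta)` after each visit and global recovery
`h <- 1 - (1 - h) exp(-1/tau)` per step. Habituation slows map learning —
a traversal between two recently visited nodes stays below the plasticity
threshold — but does not prevent it: every edge is eventually crossed
with recovered sensitivity, so sufficiently long walks (the reference
habituation scenario uses 30,000 steps) still recover the map exactly.

## 3. Navigation (noisy greedy ascent)

At each decision the agent evaluates the goal signal it would receive at
each neighbor `j` of its node (one-step lookahead `g . v(j)`), adds
i.i.d. Gaussian noise with standard deviation `epsilon / 2`, and moves to
the argmax (`navigate()`).

**Decision — noise normalization.** `epsilon` is specified *relative to
the maximal goal signal*: candidate values are divided by
`max_x(g . v(x))` before the noise is added. Resource strengths of 1 make
the learned peak signal ~1, so learned and theory states are comparable.
If a goal cell has learned nothing (no positive signal), the values are
left at zero and navigation honestly degrades to a noise-driven random
walk.

### Exact route statistics

Because candidate values are position-independent, the noisy walk is a
Markov chain. `step_probabilities()` computes the exact probability that
candidate `i` wins the noisy argmax via 64-node Gauss–Hermite
quadrature of `E[prod_{j != i} Phi((v_i - v_j + noise)/sd)]`.
`expected_route_lengths()` assembles the column-stochastic transition
matrix with the goal absorbing and solves

* expected steps to absorption: `(I - t(Q)) h = 1` on the transient set,
* probability of a shortest route: a dynamic program over distance
  layers (a shortest route must reduce the distance by one at every
  step).

Starts from which absorption is not certain (possible for badly learned
signals at `epsilon = 0`) report `Inf` (`partial = TRUE`) or raise an
error. `random_walk_hitting_times()` is the same computation with flat
values — the baseline for speed-up statistics.

### Range of the goal signal

`goal_signal_range()` reports the largest distance `d` such that for
*every* distance `d' <= d` the mean shortest-route probability is at
least 1/2 (equivalently: the median navigated length equals the graph
distance). The prefix rule matters: a distance that fails caps the range
even if larger distances happen to pass.

**Decision — speed-up metrics.** "Speed-up vs a random walk" is
evaluated per task: on the ring over pairs within the signal's range
(beyond it the expected length is dominated by the diffusive tail), on
the tree over all pairs, and on Tower of Hanoi for the start-to-solution
task. These choices reproduce the canonical ~40/~100/~10-fold orders of
magnitude.

## 4. Patrolling

`patrol()` implements habituation-driven coverage: a patrol cell sums all
map output, each visit habituates the visited node's point cell by
`exp(-beta)`, sensitivities recover with time constant `tau`, and the
agent ascends the habituation-weighted patrol signal
`h_j * colSums((I/gamma - M)^{-1})_j` with the same readout noise as
navigation.

On the 127-node tree with `gamma = 0.33, beta = 1.2, tau = 100` the
noise-free agent locks into an exactly repeating 252-step cycle
(= twice the edge count, visiting all 64 leaves once per lap;
`detect_cycle()`).

**Decision — cycle statistic under noise.** At `epsilon = 0.01` the
trajectory is *not* exactly periodic: near-ties between sibling branches
resolve differently on different laps. Coverage per 252-step window
remains perfect. `patrol_cycle_length()` therefore reports the exact
period when one exists and otherwise the median steady-state interval
between returns to the same end node, which equals 252 for this regime.

## 5. Scenario runners

* `run_ring_timeline()` — 14-node ring with resources appearing at steps
  200/400 (both feeding one goal cell) and a chord added at step 600
  (preset `fig4`), or with forgetting and a link added/removed at
  200/400 (preset `fig10`). Records per-step goal-signal profiles, map
  snapshots at event boundaries, and the trace of the synapses 4–5 and
  4–11.
* `run_homing()` — entrance tagged before exploration (`alpha = 10` so a
  single visit imprints it), one scripted excursion
  entrance→leaf→leaf, then noisy return navigation. The goal signal is
  nonzero only on visited nodes and increases monotonically toward the
  entrance; the return follows the shortest path and does not re-enter
  the explored dead branch.
* `run_parameter_sweep()` / `run_activation_comparison()` — range as a
  function of `(gamma, theta)` and activation, learning each cell from an
  edge-covering walk (~10 traversals per edge, the standard sweep
  convention). Unstable cells score range 0 rather than erroring.

**Decision — sweep exploration length.** Plain random walks of a fixed
length occasionally leave a whole subtree untraversed on the 127-node
tree, which makes sweep cells fail for reasons unrelated to the
parameters. Sweeps therefore use `edge_covering_walk()`: walk until every
edge has ~10 traversals (step cap 50 × edges).

## 6. Reproducibility

All stochastic entry points accept a `seed`; the acceptance script
(`scripts/acceptance.R --seed N --out f.json`) recomputes every headline
number from scratch. Exact quantities (critical gains, graph distances,
Markov statistics) are deterministic; learned ranges depend on the walk
realization only through the recovered map, which is exact for the
standard walk lengths.
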