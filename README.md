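# endotaxis

An R implementation of **endotaxis**: a neuromorphic algorithm in which an
agent learns a cognitive map of a graph-structured environment through
Hebbian plasticity, tags resource locations with goal cells, and then
navigates by greedily ascending an internally generated "virtual odor"
signal. The package provides the full circuit simulator plus exact
analysis tools (closed-form goal signals, absorbing-Markov route-length
statistics), along with scenario runners for homing, link-change
timelines, forgetting, habituation-driven patrolling, and parameter
sweeps.

## The model in one paragraph

The environment is an undirected graph. Each node drives one *point cell*
(a one-hot location code). Point cells feed a recurrent network of *map
cells* whose synapses `M` learn the graph's adjacency matrix during a
random exploration walk: a synapse between two map cells is potentiated
when both cells are active above a threshold `theta` in consecutive
steps, which (thanks to the recurrent gain `gamma`) happens exactly when
the agent traverses that edge. *Goal cells* read out the map activity
through synapses `G` that are imprinted with the map's activity profile
whenever the agent encounters the corresponding resource. The resulting
goal signal decays roughly as `gamma^distance` from the goal, so an agent
that repeatedly steps to the neighbor with the highest (noisy) goal
signal follows shortest paths — up to a distance called the signal's
*range*, which depends on the gain and on the readout noise `epsilon`.

## Quick start

```r
library(endotaxis)

# 1. An environment: the 127-node binary-tree labyrinth
g <- build_binary_tree(6)
critical_gain(g)            # ~0.383: the gain must stay below this

# 2. Learn map and per-node goals from a random exploration walk
params <- model_params(gamma = 0.33, theta = 0.30, alpha = 0.1,
                       epsilon = 0.01)
walk   <- edge_covering_walk(g, visits_per_edge = 10, seed = 1)
state  <- learn_walk(g, walk, params, per_node_resources(g))
map_recovery_error(state, g)   # 0: the adjacency was learned exactly

# 3. Navigate by ascending the learned goal signal
route <- navigate(g, state, start = 126, goal = 0, params, seed = 1)
route$length                  # equals the graph distance

# 4. Exact route-length statistics for all pairs (no sampling)
routes <- all_pairs_navigation(g, state, params, "markov")
goal_signal_range(routes)     # largest distance with >= 50% shortest routes
summarize_routes(routes)

# 5. Patrol the labyrinth via point-cell habituation
pp  <- model_params(0.33, beta = 1.2, tau = 100, epsilon = 0.01)
pat <- patrol(g, theory_state(g, pp, goals = integer(0)), 3000, pp,
              seed = 1)
patrol_cycle_length(g, pat$nodes)$period   # 252 = twice the edge count
```

## Package tour

| Area | Functions |
| --- | --- |
| Environments | `env_graph`, `build_ring`, `build_binary_tree`, `build_hanoi`, `add_link`, `remove_link`, `read_edgelist`, `write_edgelist` |
| Graph analysis | `adjacency_matrix`, `shortest_distances`, `critical_gain` |
| Circuit | `model_params`, `circuit_state`, `theory_state`, `map_output`, `goal_signals`, `resolvent`, `theory_goal_matrix` |
| Learning | `random_walk`, `edge_covering_walk`, `learn_walk`, `learn_step`, `resource_field`, `per_node_resources`, `map_recovery_error` |
| Navigation | `navigate`, `step_probabilities`, `expected_route_lengths`, `all_pairs_navigation`, `goal_signal_range`, `summarize_routes`, `random_walk_hitting_times`, `navigation_speedup` |
| Patrolling | `patrol`, `end_node_discovery_curve`, `detect_cycle`, `patrol_cycle_length` |
| Scenarios | `endotaxis_preset`, `run_ring_timeline`, `run_homing`, `run_parameter_sweep`, `run_activation_comparison` |

Conventions: nodes are **0-based** in all public interfaces; matrices
carry node ids as dimnames. `M[i, j]` is the synapse from map cell `j`
onto map cell `i`.

## Command line

A thin CLI ships under `inst/cli/endotaxis` (installed to
`system.file("cli", "endotaxis", package = "endotaxis")`):

```sh
endotaxis graph    --graph ring:50 --out out/
endotaxis theory   --graph tree:6 --gamma 0.2 --out out/
endotaxis navigate --graph hanoi:4 --gamma 0.29 --theta 0.27 --out out/
endotaxis patrol   --graph tree:6 --gamma 0.33 --beta 1.2 --out out/
endotaxis reproduce fig4 --seed 1 --out out/
```

Outputs are CSV tables plus a `metadata.json` echoing the configuration.

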