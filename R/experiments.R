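#' Named scenario presets
#'
#' Bundles the graph and model parameters of the package's reference
#' scenarios so that experiments and tests can refer to a preset by name
#' instead of scattering literals. Available presets:
#'
#' * `fig3` — 127-node binary tree, theory state, linear gain 0.34, with a
#'   gain grid for goal-signal-vs-distance curves.
#' * `fig4` — 14-node ring timeline: resource at node 4 from step 200, a
#'   second location (node 10) of the same resource from step 400, a chord
#'   (4, 11) added at step 600; 800 steps, gamma 0.32, theta 0.27,
#'   alpha 0.3.
#' * `fig5-ring` — 50-node ring, 10,000-step learning walk, gamma 0.41,
#'   theta 0.39, alpha 0.1.
#' * `fig5-tree` — 127-node tree, gamma 0.33, theta 0.30, alpha 0.1.
#' * `fig5-hanoi` — 4-disk Tower of Hanoi (81 states), gamma 0.29,
#'   theta 0.27, alpha 0.1.
#' * `fig7` — 127-node tree with the saturating activation, gain 0.37, plus
#'   a gain grid for range-vs-gain scans.
#' * `fig8` — homing on the 127-node tree: gamma 0.33, theta 0.30,
#'   alpha 10, plus the scripted excursion walk.
#' * `fig9` — patrolling the tree: gamma 0.33, beta 1.2, tau 100, 3000
#'   steps.
#' * `fig10` — ring timeline with forgetting (delta 0.1): chord (4, 11)
#'   added at step 200 and removed at step 400; 1000 steps.
#' * `fig11` — learning with habituation on the tree: 30,000 steps,
#'   beta 1.2, tau 100.
#'
#' @param name Preset name.
#' @return List with `name`, `graph`, `params` and scenario-specific extras
#'   (`steps`, `resource_events`, `link_events`, `walk`, `gammas`, ...).
#' @export
endotaxis_preset <- function(name) {
  tree <- function() build_binary_tree(6L)
  p <- switch(
    name,
    "fig3" = list(
      graph = tree(),
      params = model_params(0.34),
      gammas = c(0.1, 0.2, 0.3, 0.34, 0.36)),
    "fig4" = list(
      graph = build_ring(14L),
      params = model_params(0.32, theta = 0.27, alpha = 0.3),
      steps = 800L,
      resource_events = data.frame(step = c(200L, 400L),
                                   node = c(4L, 10L)),
      link_events = data.frame(step = 600L, action = "add",
                               from = 4L, to = 11L)),
    "fig5-ring" = list(
      graph = build_ring(50L),
      params = model_params(0.41, theta = 0.39, alpha = 0.1),
      steps = 10000L),
    "fig5-tree" = list(
      graph = tree(),
      params = model_params(0.33, theta = 0.30, alpha = 0.1),
      steps = 10000L),
    "fig5-hanoi" = list(
      graph = build_hanoi(4L),
      params = model_params(0.29, theta = 0.27, alpha = 0.1),
      steps = 10000L),
    "fig7" = list(
      graph = tree(),
      params = model_params(0.37, activation = "saturating"),
      gammas = seq(0.30, 0.42, by = 0.02)),
    "fig8" = list(
      graph = tree(),
      params = model_params(0.33, theta = 0.30, alpha = 10),
      walk = c(0L, 1L, 3L, 7L, 15L, 31L, 63L, 31L, 15L, 32L, 65L)),
    "fig9" = list(
      graph = tree(),
      params = model_params(0.33, beta = 1.2, tau = 100),
      steps = 3000L),
    "fig10" = list(
      graph = build_ring(14L),
      params = model_params(0.32, theta = 0.27, alpha = 0.3,
                            delta = 0.1),
      steps = 1000L,
      resource_events = data.frame(step = 0L, node = 4L),
      link_events = data.frame(step = c(200L, 400L),
                               action = c("add", "remove"),
                               from = 4L, to = 11L)),
    "fig11" = list(
      graph = tree(),
      params = model_params(0.33, theta = 0.30, alpha = 0.1,
                            beta = 1.2, tau = 100),
      steps = 30000L),
    stop(sprintf("unknown preset '%s'", name)))
  c(list(name = name), p)
}

#' Ring timeline with resource and link events
#'
#' Simulates the canonical small-ring learning timeline: a random
#' exploration walk during which resource locations appear at given steps
#' (all feeding one goal cell) and links are added to or removed from the
#' graph at given steps. Per step it records the goal-signal profile the
#' goal cell would report from every node, and it snapshots the map matrix
#' at every event boundary.
#'
#' @param preset A preset list from [endotaxis_preset()] (`"fig4"` or
#'   `"fig10"`), or a hand-built list with the same fields.
#' @param seed RNG seed for the exploration walk.
#' @return List with `walk` (0-based nodes), `goal_profile` (steps x n
#'   matrix of goal signals by would-be position), `snapshots` (named list
#'   of M at each event boundary and at the end), `m_trace` (steps x 2
#'   matrix tracing the synapses 4-5 and 4-11), `state`, `graph` (final
#'   graph).
#' @export
run_ring_timeline <- function(preset = endotaxis_preset("fig4"),
                              seed = 1L) {
  set.seed(seed)
  graph <- preset$graph
  params <- preset$params
  n <- graph$n_nodes
  steps <- preset$steps
  res_ev <- preset$resource_events
  if (is.null(res_ev)) res_ev <- data.frame(step = integer(),
                                            node = integer())
  link_ev <- preset$link_events
  if (is.null(link_ev))
    link_ev <- data.frame(step = integer(), action = character(),
                          from = integer(), to = integer())
  event_steps <- sort(unique(c(res_ev$step, link_ev$step)))
  event_steps <- event_steps[event_steps > 0L & event_steps <= steps]

  active_nodes <- res_ev$node[res_ev$step <= 0L]
  resources <- matrix(0, 1L, n)
  resources[1L, active_nodes + 1L] <- 1
  state <- circuit_state(n, 1L, goal_nodes = if (length(active_nodes))
    active_nodes[1L] else NA_integer_)
  nb <- neighbor_list(graph)
  walk <- integer(steps + 1L)
  walk[1L] <- 1L
  profile <- matrix(NA_real_, steps + 1L, n)
  m_trace <- matrix(NA_real_, steps + 1L, 2L,
                    dimnames = list(NULL, c("4-5", "4-11")))
  snapshots <- list()
  prev_v <- NULL
  s <- 0L
  for (t in 0:steps) {
    if (t > 0L) {
      if (t %in% event_steps) {
        # apply environment changes and snapshot the map just before them
        snapshots[[sprintf("t%d", t)]] <- state$M
        active_nodes <- c(active_nodes, res_ev$node[res_ev$step == t])
        resources[1L, active_nodes + 1L] <- 1
        if (is.na(state$goal_nodes[1L]) && length(active_nodes))
          state$goal_nodes[1L] <- active_nodes[1L]
        ev <- link_ev[link_ev$step == t, ]
        for (i in seq_len(nrow(ev))) {
          graph <- if (ev$action[i] == "add")
            add_link(graph, ev$from[i], ev$to[i])
          else remove_link(graph, ev$from[i], ev$to[i])
        }
        nb <- neighbor_list(graph)
      }
      cand <- nb[[s + 1L]]
      s <- cand[sample.int(length(cand), 1L)] - 1L
      walk[t + 1L] <- s + 1L
    }
    res <- learn_step(state, prev_v, s, params, resources)
    state <- res$state
    prev_v <- res$activity$v
    V <- map_outputs_all(state$M, params)
    profile[t + 1L, ] <- as.vector(state$G %*% V)
    m_trace[t + 1L, ] <- c(state$M[5L, 6L], state$M[5L, 12L])
  }
  snapshots[["final"]] <- state$M
  attr(state, "v_last") <- prev_v
  list(walk = walk - 1L, goal_profile = profile, snapshots = snapshots,
       m_trace = m_trace, state = state, graph = graph)
}

#' Homing after a single excursion
#'
#' Runs the homing scenario: the entrance of the labyrinth is tagged as a
#' goal before any exploration (resource present at the walk's first node),
#' the agent performs one scripted excursion, and then navigates home by
#' ascending the freshly learned goal signal.
#'
#' @param preset Preset from [endotaxis_preset()] (default `"fig8"`).
#' @param seed RNG seed for the noisy return navigation.
#' @return List with `walk` (the excursion), `state`, `goal_profile`
#'   (goal signal from every node after the excursion), `route` (the
#'   [navigate()] result from the last excursion node to the entrance),
#'   `visited` (0-based nodes seen during the excursion).
#' @export
run_homing <- function(preset = endotaxis_preset("fig8"), seed = 1L) {
  graph <- preset$graph
  params <- preset$params
  walk <- preset$walk
  resources <- resource_field(graph, walk[1L])
  state <- learn_walk(graph, walk, params, resources)
  profile <- goal_values(state, params, 1L, normalize = FALSE)
  route <- navigate(graph, state, start = walk[length(walk)],
                    goal = walk[1L], params, goal_row = 1L, seed = seed)
  list(walk = walk, state = state, goal_profile = profile, route = route,
       visited = sort(unique(walk)))
}

# learn a state on `graph` with per-node goals from an edge-covering walk
# (internal helper shared by sweeps and comparisons)
learn_for_sweep <- function(graph, params, visits_per_edge = 10L,
                            steps = NULL, seed = NULL) {
  walk <- if (is.null(steps))
    edge_covering_walk(graph, visits_per_edge, seed = seed)
  else random_walk(graph, steps, seed = seed)
  learn_walk(graph, walk, params, per_node_resources(graph))
}

#' Parameter sweep of the goal-signal range
#'
#' For each parameter combination: learn map and per-node goal synapses
#' from an edge-covering exploration walk, evaluate all-pairs navigation
#' exactly (Markov first-capture), and report the goal-signal range. Rows
#' whose gain is unstable for the learned map report range 0.
#'
#' @param graph An `endo_graph`.
#' @param gammas Gains to scan.
#' @param thetas Thresholds to scan (`NULL`: 0.9 * gamma each).
#' @param alpha Goal learning rate.
#' @param epsilon Readout noise.
#' @param activation `"linear"` or `"saturating"`.
#' @param visits_per_edge Exploration length (traversals per edge).
#' @param goals Subset of 0-based goal nodes to evaluate (default all;
#'   a subset speeds up large sweeps).
#' @param seed RNG seed (one walk per gamma/theta cell).
#' @return A data.frame with columns `gamma`, `theta`, `range`.
#' @export
run_parameter_sweep <- function(graph, gammas, thetas = NULL, alpha = 0.1,
                                epsilon = 0.01, activation = "linear",
                                visits_per_edge = 10L, goals = NULL,
                                seed = 1L) {
  rows <- list()
  for (gam in gammas) {
    ths <- if (is.null(thetas)) 0.9 * gam else thetas
    for (th in ths) {
      params <- model_params(gam, activation = activation, theta = th,
                             alpha = alpha, epsilon = epsilon)
      rng <- tryCatch({
        st <- learn_for_sweep(graph, params,
                              visits_per_edge = visits_per_edge,
                              seed = seed)
        routes <- all_pairs_navigation(graph, st, params, "markov",
                                       goals = goals)
        goal_signal_range(routes)
      }, error = function(e) 0L)
      rows[[length(rows) + 1L]] <- data.frame(gamma = gam, theta = th,
                                              range = rng)
    }
  }
  do.call(rbind, rows)
}

#' Linear vs saturating activation comparison
#'
#' Scans the gain for both activation functions (learning from an
#' edge-covering walk at each gain, threshold 0.9 * gamma) and reports the
#' range-vs-gain curves and the best range per activation.
#'
#' @inheritParams run_parameter_sweep
#' @param gammas_linear,gammas_saturating Gain grids for the two curves.
#' @return List with `curves` (data.frame `activation`, `gamma`, `range`)
#'   and `best` (named vector of the best range per activation).
#' @export
run_activation_comparison <- function(graph,
                                      gammas_linear = seq(0.26, 0.38, 0.02),
                                      gammas_saturating = seq(0.30, 0.42, 0.02),
                                      alpha = 0.1, epsilon = 0.01,
                                      visits_per_edge = 10L, goals = NULL,
                                      seed = 1L) {
  lin <- run_parameter_sweep(graph, gammas_linear, alpha = alpha,
                             epsilon = epsilon, activation = "linear",
                             visits_per_edge = visits_per_edge,
                             goals = goals, seed = seed)
  sat <- run_parameter_sweep(graph, gammas_saturating, alpha = alpha,
                             epsilon = epsilon, activation = "saturating",
                             visits_per_edge = visits_per_edge,
                             goals = goals, seed = seed)
  curves <- rbind(cbind(activation = "linear", lin),
                  cbind(activation = "saturating", sat))
  list(curves = curves,
       best = c(linear = max(lin$range), saturating = max(sat$range)))
}
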