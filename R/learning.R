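#' Resource fields
#'
#' A resource field is a k x n matrix `F`: `F[k, x]` is the strength of the
#' resource driving goal cell `k` when the agent is at node `x` (columns are
#' 0-based nodes, so node `x` is column `x + 1`). Entries default to 1 at
#' the listed nodes; the goal signal then saturates at 1, which makes the
#' readout-noise width `epsilon` directly interpretable as a fraction of the
#' maximal signal.
#'
#' `resource_field` builds one goal row per element of `nodes` (an element
#' may be a vector when several locations deliver the same resource);
#' `per_node_resources` gives every node its own goal cell, the setup used
#' for all-pairs navigation experiments.
#'
#' @param graph An `endo_graph`.
#' @param nodes List (or vector) of 0-based node ids, one element per goal
#'   cell.
#' @param strength Resource strength at the marked nodes.
#' @return A k x n matrix with `goal_nodes` attribute.
#' @export
resource_field <- function(graph, nodes, strength = 1) {
  if (!is.list(nodes)) nodes <- as.list(nodes)
  k <- length(nodes)
  F_ <- matrix(0, k, graph$n_nodes)
  for (i in seq_len(k)) F_[i, nodes[[i]] + 1L] <- strength
  attr(F_, "goal_nodes") <- vapply(nodes, function(x) as.integer(x[1L]), 1L)
  F_
}

#' @rdname resource_field
#' @export
per_node_resources <- function(graph, strength = 1) {
  resource_field(graph, 0:(graph$n_nodes - 1L), strength)
}

#' Random exploration walk
#'
#' Uniform random walk on the graph: at every step the agent moves to a
#' neighbor of its current node chosen uniformly at random.
#'
#' @param graph An `endo_graph`.
#' @param steps Number of steps (the walk has `steps + 1` entries).
#' @param start Start node (0-based).
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer vector of 0-based node ids, length `steps + 1`.
#' @export
random_walk <- function(graph, steps, start = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- neighbor_list(graph)
  start <- as.integer(start)
  if (start < 0L || start >= graph$n_nodes) stop("invalid start node")
  if (steps > 0L && length(nb[[start + 1L]]) == 0L)
    stop(sprintf("start node %d is isolated", start))
  walk <- integer(steps + 1L)
  walk[1L] <- start + 1L
  s <- start + 1L
  for (t in seq_len(steps)) {
    cand <- nb[[s]]
    s <- cand[sample.int(length(cand), 1L)]
    walk[t + 1L] <- s
  }
  walk - 1L
}

#' Edge-covering exploration walk
#'
#' Random walk continued until every undirected edge has been traversed at
#' least `visits_per_edge` times (in either direction), or until a step cap
#' of `cap_per_edge` times the edge count is reached. This is the "medium
#' length" exploration used by parameter sweeps: on all the built-in graphs
#' the stationary traversal rate is uniform across edges, so the walk length
#' is close to `2 * visits_per_edge * |edges|`.
#'
#' @inheritParams random_walk
#' @param visits_per_edge Required traversals per undirected edge.
#' @param cap_per_edge Step cap as a multiple of the edge count.
#' @return Integer vector of 0-based node ids.
#' @export
edge_covering_walk <- function(graph, visits_per_edge = 10L, start = 0L,
                               seed = NULL, cap_per_edge = 50L) {
  if (!is.null(seed)) set.seed(seed)
  nb <- neighbor_list(graph)
  m <- nrow(graph$edges)
  cap <- cap_per_edge * m
  counts <- matrix(0L, graph$n_nodes, graph$n_nodes)
  walk <- integer(cap + 1L)
  s <- as.integer(start) + 1L
  walk[1L] <- s
  n_short <- m  # edges still below the quota
  t <- 0L
  while (n_short > 0L && t < cap) {
    t <- t + 1L
    cand <- nb[[s]]
    s2 <- cand[sample.int(length(cand), 1L)]
    cnt <- counts[s, s2] + counts[s2, s] + 1L
    counts[s, s2] <- counts[s, s2] + 1L
    if (cnt == visits_per_edge) n_short <- n_short - 1L
    s <- s2
    walk[t + 1L] <- s
  }
  walk[seq_len(t + 1L)] - 1L
}

# Shared plasticity rules (internal). `prev_v` and `v` are activity vectors
# (pre- and post-step); `cur` is the 1-based current node. Without
# forgetting (delta = 0) this is the three-parameter learning rule: synapse
# pairs with both activities above theta jump to full strength, and goal
# synapses take an error-correcting Hebbian update gated by the resource
# signal. With delta > 0 the potentiation is complemented by synaptic
# depression: a high-presynaptic / low-postsynaptic event multiplies the map
# synapse by exp(-delta), and an over-predicted resource multiplies the goal
# synapses by exp(-delta * v).
apply_plasticity <- function(M, G, prev_v, v, cur, params, resources,
                             directed = FALSE) {
  theta <- params$theta
  delta <- params$delta
  m_changed <- FALSE
  if (!is.null(prev_v)) {
    pre <- which(prev_v > theta)
    if (length(pre)) {
      post <- which(v > theta)
      for (j in pre) {
        pot <- setdiff(post, j)
        if (length(pot) && any(M[pot, j] != 1)) {
          M[pot, j] <- 1
          if (!directed) M[j, pot] <- 1
          m_changed <- TRUE
        }
        if (delta > 0) {
          dep <- setdiff(which(v <= theta), j)
          if (length(dep)) {
            fac <- exp(-delta)
            M[dep, j] <- M[dep, j] * fac
            M[j, dep] <- M[j, dep] * fac
            m_changed <- TRUE
          }
        }
      }
    }
  }
  if (nrow(G)) {
    if (delta == 0) {
      hit <- which(resources[, cur] > 0)
      for (k in hit) {
        rk <- sum(G[k, ] * v)
        G[k, ] <- G[k, ] + params$alpha * (resources[k, cur] - rk) * v
      }
    } else {
      r <- as.vector(G %*% v)
      d <- resources[, cur] - r
      for (k in seq_len(nrow(G))) {
        if (d[k] > 0) G[k, ] <- G[k, ] + params$alpha * d[k] * v
        else G[k, ] <- G[k, ] * exp(-delta * v)
      }
    }
  }
  list(M = M, G = G, m_changed = m_changed)
}

#' One learning step
#'
#' Applies the plasticity rules for a single move of the agent to
#' `cur_node`. The map output `v` at the new position is computed with the
#' map synapses as they stand *before* this step's updates; `prev_v` must be
#' the map output from the previous position (computed with the then-current
#' map). Map synapses are potentiated to full strength for every cell pair
#' whose pre- (previous step) and post- (this step) activities both exceed
#' `theta`; goal synapses of resource cells active at `cur_node` move toward
#' predicting the resource signal. With `delta > 0` the forgetting variants
#' of both rules are applied as well.
#'
#' @param state An `endo_state`.
#' @param prev_v Map output at the previous position, or `NULL` on the first
#'   step of a walk.
#' @param cur_node Current node (0-based).
#' @param params An `endo_params`.
#' @param resources Resource field matrix (see [resource_field()]).
#' @param directed Update only the synapse in the traveled direction.
#' @return List with the updated `state` and the activity vector `v` used
#'   (an `ActivityVectors`-style list: `u`, `w`, `v`, `r`).
#' @export
learn_step <- function(state, prev_v, cur_node, params, resources,
                       directed = FALSE) {
  n <- nrow(state$M)
  cur <- as.integer(cur_node) + 1L
  if (params$theta >= params$gamma && all(state$M == 0))
    warning(sprintf(
      "theta = %g >= gamma = %g: with an empty map no activity can cross the plasticity threshold",
      params$theta, params$gamma))
  u <- numeric(n)
  u[cur] <- state$h[cur]
  v <- as.vector(map_output(u, state$M, params))
  upd <- apply_plasticity(state$M, state$G, prev_v, v, cur, params,
                          resources, directed)
  state$M <- upd$M
  state$G <- upd$G
  list(state = state,
       activity = list(u = u, w = u + as.vector(state$M %*% v), v = v,
                       r = goal_signals(v, state$G)))
}

#' Learn map and goals from an exploration walk
#'
#' Folds the learning rule over a walk, starting from empty synapses (or
#' from a supplied state, so walks can be chained across environment
#' changes). Goal learning is also applied at the walk's first node, so a
#' salient start location (e.g. a labyrinth entrance) is tagged before any
#' exploration.
#'
#' With `habituation = TRUE` the point-cell sensitivities evolve as during
#' patrolling: every visit multiplies the current node's sensitivity by
#' `exp(-beta)` and all sensitivities relax back to 1 with time constant
#' `tau`; the point-cell drive is scaled accordingly.
#'
#' @param graph An `endo_graph` (used for sanity checks only; the walk
#'   carries the topology).
#' @param walk Integer vector of 0-based nodes, consecutive entries
#'   adjacent.
#' @param params An `endo_params`.
#' @param resources Resource field matrix; defaults to no resources.
#' @param state Optional starting `endo_state` (for chained walks supply the
#'   state returned by the previous call, which carries its last activity
#'   vector). A chained walk must continue where the previous one ended:
#'   its first node must equal the previous walk's last node (the
#'   duplicate is dropped) or be one of its neighbors; anything else would
#'   teleport the agent and imprint a non-existent link.
#' @param directed Use the directed map-learning rule.
#' @param habituation Let point cells habituate during the walk.
#' @param record `"none"`, or `"goal_profile"` to record, at every step, the
#'   goal signal each goal cell would report from every node (an
#'   `steps x k x n` array in `attr(state, "history")`).
#' @return The final `endo_state`; attributes `v_last` (activity at the last
#'   node) and optionally `history`.
#' @export
learn_walk <- function(graph, walk, params, resources = NULL, state = NULL,
                       directed = FALSE, habituation = FALSE,
                       record = c("none", "goal_profile")) {
  record <- match.arg(record)
  n <- graph$n_nodes
  walk1 <- as.integer(walk) + 1L
  if (any(walk1 < 1L | walk1 > n)) stop("walk contains invalid node ids")
  if (is.null(resources))
    resources <- matrix(0, 0L, n)
  if (is.null(state)) {
    state <- circuit_state(n, nrow(resources),
                           goal_nodes = attr(resources, "goal_nodes"))
    prev_v <- NULL
    if (params$theta >= params$gamma)
      warning(sprintf(
        "theta = %g >= gamma = %g: with an empty map no activity can cross the plasticity threshold",
        params$theta, params$gamma))
  } else {
    prev_v <- attr(state, "v_last")
    last <- attr(state, "last_node")
    if (!is.null(prev_v) && !is.null(last) && length(walk1)) {
      if (walk1[1L] == last + 1L) {
        # continuation walks may repeat the node the previous walk ended on
        walk1 <- walk1[-1L]
        if (length(walk1) == 0L) return(state)
      } else if (!any(neighbor_list(graph)[[last + 1L]] == walk1[1L])) {
        stop(sprintf(
          "chained walk must continue from node %d (or a neighbor); got %d",
          last, walk1[1L] - 1L))
      }
    }
  }
  M <- state$M; G <- state$G; h <- state$h
  gamma <- params$gamma
  sat <- params$activation == "saturating"
  linear_cache <- NULL
  if (!sat) {
    rho <- spectral_radius(M)
    if (gamma * rho >= 1) stop_unstable(gamma, rho)
    linear_cache <- solve(diag(n) / gamma - M)
  }
  hist <- if (record == "goal_profile")
    array(NA_real_, dim = c(length(walk1), nrow(G), n)) else NULL
  v_sat <- NULL  # warm start for the saturating fixed point
  for (t in seq_along(walk1)) {
    cur <- walk1[t]
    if (t > 1L && habituation) h <- 1 - (1 - h) * exp(-1 / params$tau)
    drive <- if (habituation) h[cur] else 1
    if (sat) {
      u <- numeric(n); u[cur] <- drive
      v <- map_output(u, M, params, v_init = v_sat)
      v_sat <- v
    } else {
      v <- drive * linear_cache[, cur]
    }
    if (t == 1L && is.null(prev_v) && nrow(G)) {
      # tag resources present at the start node before any exploration
      upd <- apply_plasticity(M, G, NULL, v, cur, params, resources,
                              directed)
      G <- upd$G
    } else if (t > 1L || !is.null(prev_v)) {
      upd <- apply_plasticity(M, G, prev_v, v, cur, params, resources,
                              directed)
      G <- upd$G
      if (upd$m_changed) {
        M <- upd$M
        if (!sat) {
          rho <- spectral_radius(M)
          if (gamma * rho >= 1) stop_unstable(gamma, rho)
          linear_cache <- solve(diag(n) / gamma - M)
        }
      }
    }
    if (habituation) h[cur] <- h[cur] * exp(-params$beta)
    if (!is.null(hist)) {
      V_all <- if (sat) map_outputs_all(M, params) else linear_cache
      hist[t, , ] <- G %*% V_all
    }
    prev_v <- v
  }
  state$M <- M; state$G <- G; state$h <- h
  attr(state, "v_last") <- prev_v
  if (length(walk1)) attr(state, "last_node") <- walk1[length(walk1)] - 1L
  if (!is.null(hist)) attr(state, "history") <- hist
  state
}

#' Map recovery error
#'
#' Number of off-diagonal map-synapse entries that disagree with the graph's
#' adjacency matrix after rounding. Zero means the map was learned exactly;
#' each missed or spurious undirected link contributes 2 (both directions).
#'
#' @param M Map synapse matrix (or an `endo_state`).
#' @param graph An `endo_graph`.
#' @return Non-negative integer count.
#' @export
map_recovery_error <- function(M, graph) {
  if (inherits(M, "endo_state")) M <- M$M
  A <- adjacency_matrix(graph)
  R <- round(M)
  diag(R) <- 0
  sum(R != A)
}
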