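#' Patrol an environment by habituation
#'
#' With no resource goal active, the agent follows the output of a single
#' "patrol cell" that sums all map-cell activity. Each point cell
#' habituates when its node is visited (sensitivity multiplied by
#' `exp(-beta)`) and recovers toward 1 with time constant `tau`; recently
#' visited nodes therefore contribute a weaker signal and the agent is
#' steered toward stale territory. Per step the agent evaluates, for each
#' neighbor `j`, the patrol signal it would receive there —
#' `h[j] * S[j]` with `S = colSums((I / gamma - M)^{-1})` for the linear
#' activation — normalized by the current maximum, adds Gaussian readout
#' noise of sd `epsilon / 2`, and moves to the best.
#'
#' @param graph An `endo_graph`.
#' @param state An `endo_state` (a learned or [theory_state()] map; goal
#'   cells are ignored). Its `h` field seeds the sensitivities.
#' @param steps Number of patrol steps.
#' @param params An `endo_params` with `beta > 0`.
#' @param start 0-based start node.
#' @param seed Optional RNG seed.
#' @return An `endo_patrol`: list with `nodes` (0-based visited sequence,
#'   length `steps + 1`), `h` (final sensitivities), and `state` (the input
#'   state with updated `h`).
#' @export
patrol <- function(graph, state, steps, params, start = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (params$beta <= 0)
    warning("beta = 0: no habituation, patrolling has no drive to move on")
  n <- graph$n_nodes
  nb <- neighbor_list(graph)
  sat <- params$activation == "saturating"
  if (!sat) {
    V <- map_outputs_all(state$M, params)
    S <- colSums(V)  # patrol-cell signal from each candidate position
  }
  h <- state$h
  sd <- params$epsilon / 2
  s <- as.integer(start) + 1L
  nodes <- integer(steps + 1L)
  nodes[1L] <- s
  for (t in seq_len(steps)) {
    h[s] <- h[s] * exp(-params$beta)
    h <- 1 - (1 - h) * exp(-1 / params$tau)
    cand <- nb[[s]]
    if (sat) {
      cv <- vapply(cand, function(j) {
        u <- numeric(n); u[j] <- h[j]
        sum(map_output(u, state$M, params))
      }, 0)
    } else {
      cv <- h[cand] * S[cand]
    }
    m <- max(cv)
    if (is.finite(m) && m > 0) cv <- cv / m
    r <- cv + stats::rnorm(length(cand), 0, if (sd > 0) sd else 0)
    best <- which(r == max(r))
    s <- cand[best[sample.int(length(best), 1L)]]
    nodes[t + 1L] <- s
  }
  state$h <- h
  structure(list(nodes = nodes - 1L, h = h, state = state),
            class = "endo_patrol")
}

#' @export
print.endo_patrol <- function(x, ...) {
  cat(sprintf("<endo_patrol> %d steps over %d distinct nodes\n",
              length(x$nodes) - 1L, length(unique(x$nodes))))
  invisible(x)
}

#' End-node discovery curve
#'
#' For a walk on a graph with designated end nodes (e.g. the leaves of a
#' labyrinth), the cumulative number of distinct end nodes visited after
#' each step — the standard efficiency measure for exploration and
#' patrolling.
#'
#' @param graph An `endo_graph` with non-empty `end_nodes`.
#' @param nodes Integer vector of visited 0-based nodes (a walk, or
#'   `$nodes` of an [patrol()] result).
#' @return Integer vector, same length as `nodes`: entry `t` counts the
#'   distinct end nodes among `nodes[1:t]`.
#' @export
end_node_discovery_curve <- function(graph, nodes) {
  if (length(graph$end_nodes) == 0L) stop("graph has no end nodes")
  is_new <- !duplicated(nodes) & nodes %in% graph$end_nodes
  cumsum(is_new)
}

#' Detect an exactly repeating cycle
#'
#' Checks whether the tail of a walk settles into exact periodic
#' repetition: the shortest period `p` such that the last `window` entries
#' satisfy `x[t] == x[t - p]`. Deterministic patrolling (`epsilon = 0`) on
#' a tree settles into such a cycle of length twice the edge count.
#'
#' @param nodes Integer vector of visited nodes.
#' @param max_period Largest period to try.
#' @param window Length of the tail that must repeat (default
#'   `2 * max_period`, capped by the walk length).
#' @return The period, or `NA` if no exact repetition is found.
#' @export
detect_cycle <- function(nodes, max_period = floor(length(nodes) / 3),
                         window = NULL) {
  n <- length(nodes)
  if (is.null(window)) window <- min(2L * max_period, n - max_period)
  tail_idx <- (n - window + 1L):n
  for (p in seq_len(max_period)) {
    if (all(nodes[tail_idx] == nodes[tail_idx - p])) return(p)
  }
  NA_integer_
}

#' Effective patrol cycle length
#'
#' The period of the steady-state patrol. If the walk repeats exactly
#' ([detect_cycle()]) that period is returned. With readout noise the
#' trajectory is not exactly periodic (near-ties between branches resolve
#' differently on different laps), so the fallback statistic is the median
#' interval between successive visits to the same end node, pooled over all
#' end nodes, using only the second half of the walk (steady state). On an
#' ideally patrolled tree both notions give twice the edge count.
#'
#' @param graph An `endo_graph` with end nodes.
#' @param nodes Integer vector of visited 0-based nodes.
#' @return List with `period` (the effective cycle length), `exact`
#'   (logical: was it an exact repetition), and `return_intervals` (all
#'   pooled end-node return intervals used by the fallback; empty when
#'   exact).
#' @export
patrol_cycle_length <- function(graph, nodes) {
  p <- detect_cycle(nodes)
  if (!is.na(p))
    return(list(period = as.integer(p), exact = TRUE,
                return_intervals = integer()))
  if (length(graph$end_nodes) == 0L) stop("graph has no end nodes")
  tail_nodes <- nodes[(floor(length(nodes) / 2) + 1L):length(nodes)]
  ivs <- unlist(lapply(graph$end_nodes, function(e) {
    diff(which(tail_nodes == e))
  }), use.names = FALSE)
  if (length(ivs) == 0L)
    return(list(period = NA_integer_, exact = FALSE,
                return_intervals = integer()))
  list(period = as.integer(round(stats::median(ivs))), exact = FALSE,
       return_intervals = as.integer(ivs))
}
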