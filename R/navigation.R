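# Package-local cache (Gauss-Hermite nodes, etc.)
.endo_cache <- new.env(parent = emptyenv())

#' Step probabilities under noisy greedy choice
#'
#' The agent picks the candidate with the largest `value + noise`, the noise
#' being independent Gaussian with standard deviation `epsilon / 2` per
#' candidate. Returns the exact probability that each candidate wins,
#' computed by 64-node Gauss-Hermite quadrature of
#' `P_i = E[ prod_{j != i} Phi((value_i - value_j + noise) / sd) ]`.
#' With `epsilon = 0` ties split uniformly among the maxima.
#'
#' @param values Numeric vector of candidate values.
#' @param epsilon Readout-noise full width (sd is `epsilon / 2`).
#' @return Probability vector summing to 1.
#' @export
step_probabilities <- function(values, epsilon) {
  k <- length(values)
  if (k == 1L) return(1)
  if (epsilon <= 0) {
    p <- as.numeric(values == max(values))
    return(p / sum(p))
  }
  gh <- .endo_cache$gh
  if (is.null(gh)) {
    gh <- pracma::gaussHermite(64L)
    .endo_cache$gh <- gh
  }
  sd <- epsilon / 2
  p <- numeric(k)
  for (i in seq_len(k)) {
    # noise of candidate i at quadrature nodes: sd * sqrt(2) * x
    z <- outer(values[i] + sd * sqrt(2) * gh$x, values[-i], "-") / sd
    p[i] <- sum(gh$w * apply(stats::pnorm(z), 1L, prod)) / sqrt(pi)
  }
  p / sum(p)
}

# Per-node goal-signal values for one goal cell, used as the navigation
# value function: value[x] is what the goal cell would report with the
# agent at node x. Normalized by the maximum (so epsilon is relative to
# the peak signal) unless the maximum is not positive, in which case the
# raw values are kept and navigation degrades to a noise-driven random
# walk — the honest behavior of an unlearned goal.
goal_values <- function(state, params, goal_row, normalize = TRUE,
                        V = NULL) {
  if (is.null(V)) V <- map_outputs_all(state$M, params)
  val <- as.vector(state$G[goal_row, , drop = FALSE] %*% V)
  if (normalize) {
    m <- max(val)
    if (is.finite(m) && m > 0) val <- val / m
  }
  val
}

#' Navigate to a goal by noisy greedy ascent
#'
#' From `start`, the agent repeatedly evaluates the goal signal it would
#' receive at each neighbor of its current node (one-step lookahead through
#' the learned map), adds independent Gaussian readout noise of standard
#' deviation `epsilon / 2` to each candidate, and moves to the best. The
#' walk ends when the physical `goal` node is reached or after `max_steps`
#' moves. Candidate values are normalized by the maximal goal signal over
#' nodes so that `epsilon` is expressed relative to the peak signal; if the
#' goal cell has learned nothing (no positive signal anywhere) the values
#' are left at zero and the agent performs a random walk.
#'
#' With `habituation = TRUE` each candidate's value is additionally scaled
#' by that node's point-cell sensitivity (recently visited nodes look less
#' attractive), the sensitivities evolving as during patrolling. This
#' rescues navigation at gains too low for the goal signal to cover the
#' whole graph.
#'
#' @param graph An `endo_graph`.
#' @param state An `endo_state` with at least one goal cell.
#' @param start,goal 0-based node ids.
#' @param params An `endo_params` (`epsilon` sets the decision noise).
#' @param goal_row Which goal cell to follow (1-based row of `state$G`);
#'   default: the cell whose `goal_nodes` entry equals `goal`.
#' @param max_steps Step cap; default `20 * n_nodes`.
#' @param seed Optional RNG seed.
#' @param normalize Normalize candidate values by the peak goal signal.
#' @param habituation Scale candidate values by point-cell sensitivity.
#' @return An `endo_route`: list with `nodes` (0-based, visited sequence),
#'   `length` (number of steps), `reached` (logical), `start`, `goal`.
#' @export
navigate <- function(graph, state, start, goal, params, goal_row = NULL,
                     max_steps = NULL, seed = NULL, normalize = TRUE,
                     habituation = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n_nodes
  if (is.null(max_steps)) max_steps <- 20L * n
  if (is.null(goal_row)) {
    goal_row <- match(as.integer(goal), state$goal_nodes)
    if (is.na(goal_row))
      stop(sprintf("no goal cell is tagged to node %d; pass `goal_row`",
                   as.integer(goal)))
  }
  nb <- neighbor_list(graph)
  sat <- params$activation == "saturating"
  val <- goal_values(state, params, goal_row, normalize = normalize)
  h <- state$h
  sd <- params$epsilon / 2
  s <- as.integer(start) + 1L
  goal1 <- as.integer(goal) + 1L
  nodes <- integer(max_steps + 1L)
  nodes[1L] <- s
  t <- 0L
  while (s != goal1 && t < max_steps) {
    cand <- nb[[s]]
    if (length(cand) == 0L) break
    if (habituation) {
      h[s] <- h[s] * exp(-params$beta)
      h <- 1 - (1 - h) * exp(-1 / params$tau)
      if (sat) {
        cv <- vapply(cand, function(j) {
          u <- numeric(n); u[j] <- h[j]
          sum(state$G[goal_row, ] * map_output(u, state$M, params))
        }, 0)
        m <- max(val)  # keep the frozen normalization scale
        if (normalize && is.finite(m) && m > 0) cv <- cv / m
      } else {
        cv <- h[cand] * val[cand]
      }
    } else {
      cv <- val[cand]
    }
    r <- cv + stats::rnorm(length(cand), 0, if (sd > 0) sd else 0)
    best <- which(r == max(r))
    s <- cand[best[sample.int(length(best), 1L)]]
    t <- t + 1L
    nodes[t + 1L] <- s
  }
  structure(
    list(nodes = nodes[seq_len(t + 1L)] - 1L, length = t,
         reached = s == goal1, start = as.integer(start),
         goal = as.integer(goal)),
    class = "endo_route")
}

#' @export
print.endo_route <- function(x, ...) {
  cat(sprintf("<endo_route> %d -> %d: %d steps, %s\n", x$start, x$goal,
              x$length, if (x$reached) "reached" else "NOT reached"))
  invisible(x)
}

# positive-transition digraph reachability helpers (internal, 1-based)
reach_backward <- function(T_, targets) {
  # nodes from which some target is reachable following positive T columns:
  # an edge j -> i exists when T_[i, j] > 0
  n <- nrow(T_)
  seen <- logical(n)
  queue <- targets
  seen[queue] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    preds <- which(T_[i, ] > 0 & !seen)
    seen[preds] <- TRUE
    queue <- c(queue, preds)
  }
  which(seen)
}

#' Exact route-length statistics via an absorbing Markov chain
#'
#' Builds the transition matrix of the noisy greedy walk (column
#' `s` holds the [step_probabilities()] over the neighbors of `s`, with the
#' goal absorbing) and solves for, at every start node, the expected number
#' of steps to absorption and the probability that the realized route has
#' exactly the shortest-path length. No sampling is involved.
#'
#' Starts from which absorption is not certain (the noise-free dynamics can
#' be trapped away from the goal, e.g. on a local maximum cycle of a badly
#' learned signal at `epsilon = 0`) get `expected_steps = Inf`; with
#' `partial = FALSE` such starts raise an error instead.
#'
#' @param graph An `endo_graph`.
#' @param node_values Numeric vector: the goal-signal value of every node
#'   (e.g. a column of [theory_goal_matrix()] or [goal_values] from a
#'   learned state, already normalized as desired).
#' @param goal 0-based goal node.
#' @param epsilon Readout-noise full width.
#' @param partial Return `Inf` for trapped starts instead of erroring.
#' @return An `endo_markov`: list with `T` (n x n column-stochastic),
#'   `expected_steps`, `prob_shortest`, `distance` (graph distance to the
#'   goal) — vectors over 0-based start nodes — and `goal`.
#' @export
expected_route_lengths <- function(graph, node_values, goal, epsilon,
                                   partial = FALSE) {
  n <- graph$n_nodes
  stopifnot(length(node_values) == n)
  goal1 <- as.integer(goal) + 1L
  nb <- neighbor_list(graph)
  T_ <- matrix(0, n, n)
  T_[goal1, goal1] <- 1
  for (s in seq_len(n)) {
    if (s == goal1) next
    cand <- nb[[s]]
    if (length(cand) == 0L) { T_[s, s] <- 1; next }
    p <- step_probabilities(node_values[cand], epsilon)
    # probabilities below quadrature accuracy are numerical noise; zeroing
    # them keeps the linear solve well-posed (an escape probability of
    # 1e-300 would otherwise masquerade as certain absorption)
    p[p < 1e-12] <- 0
    T_[cand, s] <- p / sum(p)
  }
  # a start is doomed if it can reach a state from which the goal is
  # unreachable; for all other starts absorption at the goal is certain
  can_reach_goal <- reach_backward(T_, goal1)
  bad <- setdiff(seq_len(n), can_reach_goal)
  doomed <- if (length(bad)) reach_backward(T_, bad) else integer()
  ok <- setdiff(seq_len(n), doomed)
  if (length(doomed) && !partial)
    stop(sprintf(
      "navigation from node(s) %s cannot reach goal %d (trapped away from the goal); use partial = TRUE",
      paste(sort(doomed) - 1L, collapse = ", "), as.integer(goal)))
  expected <- rep(Inf, n)
  tr <- setdiff(ok, goal1)
  if (length(tr)) {
    Q <- T_[tr, tr, drop = FALSE]
    expected[tr] <- solve(diag(length(tr)) - t(Q), rep(1, length(tr)))
  }
  expected[goal1] <- 0
  # probability the realized route length equals the graph distance:
  # dynamic program over distance layers (a shortest route must decrease
  # the distance by 1 at every step)
  D <- as.vector(shortest_distances(graph, from = goal))
  p_short <- numeric(n)
  p_short[goal1] <- 1
  for (d in sort(unique(D[D > 0]))) {
    for (s in which(D == d)) {
      down <- which(D == d - 1L)
      p_short[s] <- sum(T_[down, s] * p_short[down])
    }
  }
  structure(
    list(T = T_, expected_steps = expected, prob_shortest = p_short,
         distance = D, goal = as.integer(goal)),
    class = "endo_markov")
}

#' @export
print.endo_markov <- function(x, ...) {
  cat(sprintf(
    "<endo_markov> goal %d: %d/%d starts absorb; mean E[steps] = %.3g\n",
    x$goal, sum(is.finite(x$expected_steps)), length(x$expected_steps),
    mean(x$expected_steps[is.finite(x$expected_steps)])))
  invisible(x)
}

#' Expected hitting times of a uniform random walk
#'
#' Expected number of steps for an unbiased random walk (uniform choice
#' among neighbors) to first reach `goal` from every start node — the
#' baseline against which endotaxis navigation is compared.
#'
#' @param graph An `endo_graph` (must be connected).
#' @param goal 0-based goal node.
#' @return Numeric vector over 0-based start nodes (0 at the goal).
#' @export
random_walk_hitting_times <- function(graph, goal) {
  n <- graph$n_nodes
  vals <- numeric(n)  # flat values => uniform step probabilities
  m <- expected_route_lengths(graph, vals, goal, epsilon = 1)
  m$expected_steps
}

#' Route statistics for all start/goal pairs
#'
#' Evaluates navigation between every ordered pair of distinct nodes (or a
#' subset of goals). `method = "markov"` uses the exact absorbing-chain
#' statistics of [expected_route_lengths()]; `method = "montecarlo"` samples
#' `n_routes` noisy walks per pair with [navigate()].
#'
#' @param graph An `endo_graph`.
#' @param state An `endo_state` whose goal cells are tagged to nodes
#'   (`goal_nodes`); typically from [theory_state()] or [learn_walk()] with
#'   [per_node_resources()].
#' @param params An `endo_params`.
#' @param method `"markov"` or `"montecarlo"`.
#' @param goals 0-based goal nodes to include (default: all tagged goals).
#' @param n_routes Walks per pair (montecarlo only).
#' @param seed Optional RNG seed (montecarlo only).
#' @param max_steps Step cap per walk (montecarlo only).
#' @param normalize Normalize each goal's values by its peak signal.
#' @return A data.frame of class `endo_routes` with columns `start`, `goal`
#'   (0-based), `distance`, `expected_steps`, `prob_shortest` and, for
#'   montecarlo, `frac_reached`. One row per ordered pair (montecarlo
#'   statistics are averaged over the `n_routes` walks; `prob_shortest` is
#'   then the observed fraction of shortest routes).
#' @export
all_pairs_navigation <- function(graph, state, params,
                                 method = c("markov", "montecarlo"),
                                 goals = NULL, n_routes = 1L, seed = NULL,
                                 max_steps = NULL, normalize = TRUE) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n_nodes
  if (is.null(goals)) {
    goals <- state$goal_nodes[!is.na(state$goal_nodes)]
    if (length(goals) == 0L) stop("state has no tagged goal cells")
  }
  D_all <- shortest_distances(graph)
  V <- if (method == "markov") map_outputs_all(state$M, params) else NULL
  rows <- vector("list", length(goals))
  for (gi in seq_along(goals)) {
    g <- goals[[gi]]
    grow <- match(as.integer(g), state$goal_nodes)
    starts <- setdiff(0:(n - 1L), g)
    if (method == "markov") {
      vals <- goal_values(state, params, grow, normalize = normalize,
                          V = V)
      mk <- expected_route_lengths(graph, vals, g, params$epsilon,
                                   partial = TRUE)
      rows[[gi]] <- data.frame(
        start = starts, goal = g,
        distance = D_all[starts + 1L, g + 1L],
        expected_steps = mk$expected_steps[starts + 1L],
        prob_shortest = mk$prob_shortest[starts + 1L])
    } else {
      res <- lapply(starts, function(s) {
        L <- integer(n_routes); ok <- logical(n_routes)
        for (r in seq_len(n_routes)) {
          rt <- navigate(graph, state, s, g, params, goal_row = grow,
                         max_steps = max_steps, normalize = normalize)
          L[r] <- rt$length; ok[r] <- rt$reached
        }
        d <- D_all[s + 1L, g + 1L]
        c(mean(L[ok]), mean(ok & L == d), mean(ok))
      })
      res <- do.call(rbind, res)
      rows[[gi]] <- data.frame(
        start = starts, goal = g,
        distance = D_all[starts + 1L, g + 1L],
        expected_steps = res[, 1L], prob_shortest = res[, 2L],
        frac_reached = res[, 3L])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("endo_routes", "data.frame")
  out
}

#' Goal-signal range
#'
#' The range of the goal signal is the largest distance `d` such that for
#' every distance `d' <= d` the mean probability of taking a shortest route
#' (over all pairs at distance `d'`) is at least `threshold`. Equivalently
#' (for threshold 1/2): up to the range, the median route length equals the
#' graph distance.
#'
#' @param routes An `endo_routes` data.frame (see [all_pairs_navigation()]).
#' @param threshold Success threshold on the mean shortest-route
#'   probability.
#' @return Integer range (0 if already the nearest pairs fail).
#' @export
goal_signal_range <- function(routes, threshold = 0.5) {
  frac <- tapply(routes$prob_shortest, routes$distance, mean)
  d <- as.integer(names(frac))
  ord <- order(d)
  d <- d[ord]; frac <- frac[ord]
  rng <- 0L
  for (i in seq_along(d)) {
    if (!is.na(frac[i]) && frac[i] >= threshold) rng <- d[i] else break
  }
  rng
}

#' Summarize routes by distance
#'
#' Per graph distance: number of pairs, mean expected route length, the
#' mean probability of a shortest route, and (montecarlo) the fraction of
#' walks that reached the goal.
#'
#' @param routes An `endo_routes` data.frame.
#' @return A data.frame with one row per distance.
#' @export
summarize_routes <- function(routes) {
  ds <- sort(unique(routes$distance))
  out <- do.call(rbind, lapply(ds, function(d) {
    r <- routes[routes$distance == d, ]
    data.frame(
      distance = d, n_pairs = nrow(r),
      mean_expected_steps = mean(r$expected_steps[is.finite(r$expected_steps)]),
      frac_finite = mean(is.finite(r$expected_steps)),
      mean_prob_shortest = mean(r$prob_shortest),
      frac_reached = if ("frac_reached" %in% names(r))
        mean(r$frac_reached) else NA_real_)
  }))
  out
}

#' Navigation speed-up over a random walk
#'
#' Ratio of the mean random-walk hitting time to the mean endotaxis
#' expected route length, over a set of ordered start/goal pairs. By
#' default all pairs in `routes` are used; `max_distance` restricts to
#' pairs within that graph distance (useful when the goal signal has a
#' finite range), and `pairs` (two-column 0-based matrix) picks explicit
#' pairs.
#'
#' @param graph An `endo_graph`.
#' @param routes An `endo_routes` data.frame from [all_pairs_navigation()].
#' @param max_distance Optional cap on pair distance.
#' @param pairs Optional 2-column matrix (start, goal) of 0-based pairs.
#' @return List with `endotaxis_mean`, `random_walk_mean`, `ratio`.
#' @export
navigation_speedup <- function(graph, routes, max_distance = NULL,
                               pairs = NULL) {
  r <- routes
  if (!is.null(pairs)) {
    key <- paste(r$start, r$goal)
    r <- r[key %in% paste(pairs[, 1L], pairs[, 2L]), ]
  }
  if (!is.null(max_distance)) r <- r[r$distance <= max_distance, ]
  r <- r[is.finite(r$expected_steps), ]
  if (nrow(r) == 0L) stop("no finite pairs selected")
  rw <- numeric(nrow(r))
  for (g in unique(r$goal)) {
    idx <- r$goal == g
    ht <- random_walk_hitting_times(graph, g)
    rw[idx] <- ht[r$start[idx] + 1L]
  }
  list(endotaxis_mean = mean(r$expected_steps),
       random_walk_mean = mean(rw),
       ratio = mean(rw) / mean(r$expected_steps))
}
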