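#' Model parameters
#'
#' Bundles the tunable constants of the endotaxis circuit.
#'
#' * `gamma` — gain of the map units. Must stay below the graph's
#'   [critical_gain()] for the linear network to be stable; larger values
#'   extend the range of the goal signal but risk instability.
#' * `activation` — `"linear"` (`v = gamma * w`) or `"saturating"`
#'   (`v = gamma * min(w, 1)`), which caps a map cell's output at `gamma`
#'   once its input exceeds the point-cell drive.
#' * `theta` — plasticity threshold on pre- and post-synaptic map activity;
#'   a map synapse is potentiated only when both cells exceed it.
#' * `alpha` — learning rate of the goal synapses.
#' * `delta` — forgetting rate; `0` disables synaptic depression.
#' * `epsilon` — full width of the Gaussian readout noise added to each
#'   candidate's goal signal at every navigation decision
#'   (standard deviation `epsilon / 2`), expressed relative to the maximum
#'   of the goal signal.
#' * `beta` — habituation factor of point cells: after a visit the cell's
#'   sensitivity is multiplied by `exp(-beta)`; `0` disables habituation.
#' * `tau` — recovery time constant (in steps) with which sensitivity
#'   relaxes back to 1.
#'
#' @param gamma Positive gain.
#' @param activation `"linear"` or `"saturating"`.
#' @param theta Plasticity threshold in (0, 1).
#' @param alpha Goal learning rate (non-negative).
#' @param delta Forgetting rate (non-negative).
#' @param epsilon Readout-noise full width (non-negative).
#' @param beta Habituation factor (non-negative).
#' @param tau Recovery time constant (positive).
#' @return An object of class `endo_params`.
#' @export
model_params <- function(gamma, activation = c("linear", "saturating"),
                         theta = 0.9 * gamma, alpha = 0.1, delta = 0,
                         epsilon = 0.01, beta = 0, tau = 100) {
  activation <- match.arg(activation)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0,
            theta > 0, alpha >= 0, delta >= 0, epsilon >= 0,
            beta >= 0, tau > 0)
  structure(
    list(gamma = gamma, activation = activation, theta = theta,
         alpha = alpha, delta = delta, epsilon = epsilon,
         beta = beta, tau = tau),
    class = "endo_params")
}

#' @export
print.endo_params <- function(x, ...) {
  cat(sprintf(
    "<endo_params> gamma=%g (%s), theta=%g, alpha=%g, delta=%g, epsilon=%g, beta=%g, tau=%g\n",
    x$gamma, x$activation, x$theta, x$alpha, x$delta, x$epsilon, x$beta,
    x$tau))
  invisible(x)
}

#' Circuit state
#'
#' The mutable state of the endotaxis network: map synapses `M` (n x n,
#' non-negative, zero diagonal; entry `[i, j]` is the synapse from map cell
#' `j` onto map cell `i`, nodes 0-based so cell `i` sits at row `i + 1`),
#' goal synapses `G` (one row per goal cell) and point-cell sensitivities
#' `h` (all 1 unless habituation is active).
#'
#' @param n_nodes Number of nodes / point cells.
#' @param n_goals Number of goal cells.
#' @param goal_nodes Optional integer vector (0-based, `NA` allowed) giving,
#'   for each goal cell, the node its resource sits at. For "a goal at every
#'   node" states this is `0:(n_nodes - 1)`.
#' @return An object of class `endo_state` with fields `M`, `G`, `h`,
#'   `goal_nodes`.
#' @export
circuit_state <- function(n_nodes, n_goals = 0L, goal_nodes = NULL) {
  n <- as.integer(n_nodes)
  k <- as.integer(n_goals)
  if (is.null(goal_nodes)) goal_nodes <- rep(NA_integer_, k)
  stopifnot(length(goal_nodes) == k)
  structure(
    list(M = matrix(0, n, n), G = matrix(0, k, n), h = rep(1, n),
         goal_nodes = as.integer(goal_nodes)),
    class = "endo_state")
}

#' @export
print.endo_state <- function(x, ...) {
  cat(sprintf(
    "<endo_state> %d map cells, %d goal cells; %d map synapses set, min h = %.3g\n",
    nrow(x$M), nrow(x$G), sum(x$M > 0), min(x$h)))
  invisible(x)
}

#' Theory-optimal circuit state
#'
#' The state an ideal learner would reach: map synapses equal to the graph's
#' adjacency matrix and, for each node `y`, a goal cell whose synapses equal
#' the map output `v(y)` with the agent at `y`. Navigating on this state
#' ascends the closed-form goal signal `E`.
#'
#' @param graph An `endo_graph`.
#' @param params An `endo_params` (gain below the critical gain for the
#'   linear activation).
#' @param goals Nodes to dedicate goal cells to (default: every node).
#' @return An `endo_state`.
#' @export
theory_state <- function(graph, params, goals = 0:(graph$n_nodes - 1L)) {
  A <- adjacency_matrix(graph)
  st <- circuit_state(graph$n_nodes, length(goals), goal_nodes = goals)
  st$M <- A
  V <- map_outputs_all(st$M, params)
  st$G <- t(V[, goals + 1L, drop = FALSE])
  st
}

#' Activation function of a map neuron
#'
#' Linear: `f(w) = gamma * w`. Saturating: `f(w) = gamma * w` for `w <= 1`
#' and `gamma` for `w > 1` — the output saturates once the input exceeds the
#' drive a point cell delivers on its own.
#'
#' @param w Input (vectorized).
#' @param params An `endo_params`.
#' @return The neuron output(s).
#' @export
activation <- function(w, params) {
  if (params$activation == "linear") params$gamma * w
  else params$gamma * pmin(w, 1)
}

# spectral radius (internal)
spectral_radius <- function(M) {
  if (all(M == 0)) return(0)
  max(abs(eigen(M, only.values = TRUE)$values))
}

stop_unstable <- function(gamma, rho) {
  stop(sprintf(
    "unstable gain: gamma = %g with map spectral radius %g gives gamma * rho = %g >= 1",
    gamma, rho, gamma * rho), call. = FALSE)
}

#' Steady-state map output
#'
#' Solves the recurrent network `v = f(u + M v)` for the map-cell output
#' vector at one agent position. With the linear activation this is the
#' exact linear solve `v = (I / gamma - M)^{-1} u`; it requires the spectral
#' radius of `gamma * M` to be below 1. With the saturating activation the
#' fixed point is found by direct iteration from `v = gamma * u` to absolute
#' tolerance 1e-10 (cap 10000 iterations).
#'
#' @param u Point-cell output vector (length n).
#' @param M Map synapse matrix.
#' @param params An `endo_params`.
#' @param v_init Optional warm start for the saturating iteration.
#' @return The map output vector `v`.
#' @export
map_output <- function(u, M, params, v_init = NULL) {
  if (params$activation == "linear") {
    rho <- spectral_radius(M)
    if (params$gamma * rho >= 1) stop_unstable(params$gamma, rho)
    solve(diag(nrow(M)) / params$gamma - M, u)
  } else {
    v <- if (is.null(v_init)) params$gamma * u else v_init
    g <- params$gamma
    for (it in seq_len(10000L)) {
      v_new <- g * pmin(u + as.vector(M %*% v), 1)
      if (max(abs(v_new - v)) < 1e-10) return(v_new)
      v <- v_new
    }
    stop(sprintf(
      "saturating map network did not converge at gamma = %g (map spectral radius %g)",
      params$gamma, spectral_radius(M)), call. = FALSE)
  }
}

# map outputs for every possible agent position at once: column j is v with
# the agent at node j-1 (internal; the workhorse behind navigation tables)
map_outputs_all <- function(M, params) {
  n <- nrow(M)
  if (params$activation == "linear") {
    rho <- spectral_radius(M)
    if (params$gamma * rho >= 1) stop_unstable(params$gamma, rho)
    solve(diag(n) / params$gamma - M)
  } else {
    V <- matrix(0, n, n)
    for (j in seq_len(n)) {
      u <- numeric(n); u[j] <- 1
      V[, j] <- map_output(u, M, params)
    }
    V
  }
}

#' Goal-cell signals
#'
#' Each goal cell sums the map output through its synapses: `r = G v`.
#' Deterministic; readout noise enters only at navigation decisions.
#'
#' @param v Map output vector.
#' @param G Goal synapse matrix (k x n).
#' @return Length-k vector of goal signals.
#' @export
goal_signals <- function(v, G) {
  as.vector(G %*% v)
}

#' Resolvent matrix of a graph
#'
#' `Y = (I / gamma - A)^{-1}`, the steady-state map output of the perfectly
#' learned linear network: column `y` is the activity profile with the agent
#' at node `y`. For small gain, `Y[x, y]` decays like `gamma^(1 + D[x, y])`
#' with graph distance.
#'
#' @param graph An `endo_graph`.
#' @param gamma Gain, strictly between 0 and the critical gain.
#' @return n x n matrix with node ids as dimnames.
#' @export
resolvent <- function(graph, gamma) {
  A <- adjacency_matrix(graph)
  rho <- spectral_radius(A)
  if (gamma <= 0) stop("`gamma` must be positive")
  if (gamma * rho >= 1) stop_unstable(gamma, rho)
  Y <- solve(diag(graph$n_nodes) / gamma - A)
  dimnames(Y) <- dimnames(A)
  Y
}

#' Closed-form goal-signal matrix
#'
#' `E = t(Y) %*% Y` with `Y` the [resolvent()]: `E[x, y]` is the signal of a
#' goal cell tuned to node `y` when the agent sits at node `x`, assuming a
#' perfectly learned map. `E` is symmetric positive semidefinite, and for
#' small gain decays like `gamma^(2 + D[x, y])`, so greedy ascent of column
#' `y` follows shortest paths.
#'
#' @inheritParams resolvent
#' @return n x n matrix with node ids as dimnames.
#' @export
theory_goal_matrix <- function(graph, gamma) {
  Y <- resolvent(graph, gamma)
  E <- crossprod(Y)  # t(Y) %*% Y
  dimnames(E) <- dimnames(Y)
  E
}
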