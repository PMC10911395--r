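test_that("presets bundle the reference parameters", {
  p4 <- endotaxis_preset("fig4")
  expect_equal(p4$graph$n_nodes, 14L)
  expect_equal(p4$params$gamma, 0.32)
  expect_equal(p4$params$theta, 0.27)
  expect_equal(p4$params$alpha, 0.3)
  p8 <- endotaxis_preset("fig8")
  expect_equal(p8$params$alpha, 10)
  expect_equal(p8$walk[1], 0L)
  p10 <- endotaxis_preset("fig10")
  expect_equal(p10$params$delta, 0.1)
  expect_error(endotaxis_preset("fig99"), "unknown preset")
})

test_that("ring timeline: goal signal appears, re-routes over new link", {
  tl <- run_ring_timeline(endotaxis_preset("fig4"), seed = 1)
  expect_equal(length(tl$walk), 801L)
  # before the first target appears the goal signal is identically zero
  expect_true(all(tl$goal_profile[1:200, ] == 0))
  # after the second target (and before the chord) the profile has two
  # local peaks, at nodes 4 and 10
  prof <- tl$goal_profile[601, ]
  loc_max <- which(sapply(1:14, function(i) {
    nbv <- prof[c((i - 2) %% 14 + 1, i %% 14 + 1)]
    all(prof[i] > nbv)
  })) - 1L
  expect_equal(loc_max, c(4, 10))
  # the chord (4,11) was learned, shortening 13 -> 4 from 5 to 3 steps
  expect_equal(tl$snapshots$final[5, 12], 1)
  p0 <- model_params(0.32, epsilon = 0)
  rt <- navigate(tl$graph, tl$state, 13, 4, p0, goal_row = 1, seed = 1)
  expect_equal(rt$length, 3)
  expect_equal(shortest_distances(build_ring(14), from = 13)[1, "4"], 5)
})

test_that("forgetting timeline: removed link decays, kept link persists", {
  tl <- run_ring_timeline(endotaxis_preset("fig10"), seed = 2)
  m <- tl$m_trace
  # while present (learned after step 200) the chord synapse reaches 1
  expect_equal(max(m[, "4-11"]), 1)
  # after removal at step 400 it decays; ring synapse 4-5 stays ~ 1
  expect_lt(m[1001, "4-11"], 0.5)
  expect_gt(m[1001, "4-5"], 0.9)
  expect_equal(tl$snapshots$final[5, 12], unname(m[1001, "4-11"]))
})

test_that("homing: partial map suffices to return by the shortest path", {
  hm <- run_homing(seed = 1)
  g <- endotaxis_preset("fig8")$graph
  # goal signal nonzero exactly on the visited nodes
  nz <- which(hm$goal_profile > 1e-12) - 1L
  expect_setequal(nz, hm$visited)
  # monotone increase toward the entrance along the return path
  back <- c(65, 32, 15, 7, 3, 1, 0) + 1L
  expect_true(all(diff(hm$goal_profile[back]) > 0))
  # the route home is the 6-step shortest path avoiding the dead branch
  expect_true(hm$route$reached)
  expect_equal(hm$route$length, 6)
  expect_false(31 %in% hm$route$nodes)
  expect_false(63 %in% hm$route$nodes)
})

test_that("parameter sweep shows the gain/threshold structure", {
  g <- build_ring(20)
  sw <- suppressWarnings(
    run_parameter_sweep(g, gammas = c(0.30, 0.41),
                        thetas = c(0.27, 0.39), seed = 1))
  expect_equal(nrow(sw), 4L)
  # higher usable gain with matched threshold beats low gain
  r_hi <- sw$range[sw$gamma == 0.41 & sw$theta == 0.39]
  r_lo <- sw$range[sw$gamma == 0.30 & sw$theta == 0.27]
  expect_gt(r_hi, r_lo)
  # threshold above gamma: the map cannot be learned, so navigation is a
  # random walk whose range on a ring is at most 2 (at distance 2 half the
  # first steps already go the right way)
  expect_lte(sw$range[sw$gamma == 0.30 & sw$theta == 0.39], 2)
  expect_lt(sw$range[sw$gamma == 0.30 & sw$theta == 0.39], r_lo)
})

test_that("unstable gains in a sweep score range 0 instead of erroring", {
  g <- build_ring(12)  # critical gain 0.5
  sw <- suppressWarnings(
    run_parameter_sweep(g, gammas = c(0.3, 0.55), seed = 1))
  expect_equal(sw$range[sw$gamma == 0.55], 0)
  expect_gt(sw$range[sw$gamma == 0.3], 0)
})

test_that("saturating activation beats linear on a small tree scan", {
  g <- build_binary_tree(4)
  cmp <- run_activation_comparison(
    g, gammas_linear = c(0.32, 0.36), gammas_saturating = c(0.38, 0.42),
    seed = 1)
  expect_gte(cmp$best[["saturating"]], cmp$best[["linear"]])
  expect_equal(nrow(cmp$curves), 4L)
})

test_that("linear activation forms a spurious synapse pair, saturating not", {
  # early exploration of the ring at high gain: the agent has shuttled
  # between nodes 2..5 so those links exist; it then steps 5 -> 6 for the
  # first time. With linear activation the purely recurrently driven cell 4
  # exceeds the maximal usable threshold (0.9 * gamma) while cell 6's input
  # arrives, creating a spurious above-threshold pre/post pair; the
  # saturating activation keeps cell 4 below threshold.
  g <- build_ring(14)
  gam <- 0.49
  M <- matrix(0, 14, 14)
  for (e in list(c(2, 3), c(3, 4), c(4, 5))) {
    M[e[1] + 1, e[2] + 1] <- 1; M[e[2] + 1, e[1] + 1] <- 1
  }
  u <- numeric(14); u[6] <- 1  # agent arrives at node 5
  theta_max <- 0.9 * gam
  v_lin <- map_output(u, M, model_params(gam))
  v_sat <- map_output(u, M, model_params(gam, activation = "saturating"))
  expect_gt(v_lin[5], theta_max)   # cell 4: spurious with linear...
  expect_lt(v_sat[5], theta_max)   # ...but safe with saturation
})

test_that("navigation with habituation works at standard parameters", {
  # learned with habituation on, then navigating with habituated lookahead:
  # performance stays near-perfect at short range
  g <- build_binary_tree(4)
  p <- model_params(0.33, theta = 0.30, alpha = 0.1, beta = 1.2,
                    tau = 100, epsilon = 0.01)
  st <- learn_walk(g, random_walk(g, 25000, seed = 3), p,
                   per_node_resources(g), habituation = TRUE)
  expect_equal(map_recovery_error(st, g), 0)
  # after a pause the sensitivities recover (tau = 100 steps)
  st$h <- rep(1, g$n_nodes)
  D <- shortest_distances(g)
  pairs <- list(c(7, 0), c(9, 12), c(14, 3), c(0, 11), c(13, 6),
                c(21, 2), c(30, 16), c(5, 28), c(18, 25), c(12, 1))
  ok <- 0L
  for (pr in pairs) {
    rt <- navigate(g, st, pr[1], pr[2], p, seed = 5, habituation = TRUE)
    ok <- ok + (rt$reached && rt$length == D[pr[1] + 1, pr[2] + 1])
  }
  expect_gte(ok, 9L)
})
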