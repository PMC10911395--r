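test_that("step_probabilities is an exact noisy-argmax distribution", {
  # two candidates: P(win) = Phi(dv / (sd * sqrt(2))) in closed form
  dv <- 0.3; eps <- 0.4
  p <- step_probabilities(c(0.5, 0.2), eps)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[1], stats::pnorm(dv / (eps / 2 * sqrt(2))),
               tolerance = 1e-8)
  # equal values: uniform
  expect_equal(step_probabilities(c(1, 1, 1), 0.1), rep(1 / 3, 3),
               tolerance = 1e-8)
  # zero noise: deterministic argmax, ties split
  expect_equal(step_probabilities(c(2, 1), 0), c(1, 0))
  expect_equal(step_probabilities(c(1, 1), 0), c(0.5, 0.5))
  # monte-carlo cross-check for three asymmetric candidates
  vals <- c(0.1, 0.25, 0.3); eps <- 0.2
  set.seed(1)
  draws <- replicate(20000, which.max(vals + stats::rnorm(3, 0, eps / 2)))
  emp <- tabulate(draws, 3) / 20000
  expect_equal(step_probabilities(vals, eps), emp, tolerance = 0.02)
})

test_that("noise-free navigation on the theory signal follows shortest paths", {
  g <- build_binary_tree(4)
  p <- model_params(0.3, epsilon = 0)
  st <- theory_state(g, p)
  D <- shortest_distances(g)
  for (pair in list(c(7, 0), c(9, 14), c(3, 12))) {
    rt <- navigate(g, st, pair[1], pair[2], p, seed = 1)
    expect_true(rt$reached)
    expect_equal(rt$length, unname(D[pair[1] + 1, pair[2] + 1]))
  }
})

test_that("expected_route_lengths matches hand-solved chain", {
  # path graph 0-1-2 with goal 2 and zero noise: from 0 exactly 2 steps
  g <- env_graph(3, rbind(c(0, 1), c(1, 2)))
  vals <- c(0.1, 0.5, 1)
  m <- expected_route_lengths(g, vals, goal = 2, epsilon = 0)
  expect_equal(m$expected_steps, c(2, 1, 0))
  expect_equal(m$prob_shortest, c(1, 1, 1))
  expect_equal(colSums(m$T), rep(1, 3), ignore_attr = TRUE)
})

test_that("flat values reduce to random-walk hitting times", {
  g <- build_ring(8)
  h <- random_walk_hitting_times(g, 0)
  # symmetric ring: hitting time of node k is k (n - k)
  expect_equal(h, sapply(0:7, function(k) k * (8 - k)), tolerance = 1e-8)
})

test_that("trapped starts are detected and reported", {
  # local maximum away from the goal at zero noise: values pull toward
  # node 0 but the goal is node 3 on a path graph
  g <- env_graph(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
  vals <- c(1, 0.8, 0.2, 0.9)
  expect_error(expected_route_lengths(g, vals, 3, epsilon = 0), "trapped")
  m <- expected_route_lengths(g, vals, 3, epsilon = 0, partial = TRUE)
  expect_true(all(is.infinite(m$expected_steps[1:2])))
  expect_equal(m$expected_steps[4], 0)
})

test_that("markov and monte-carlo route lengths agree within 3 SE", {
  g <- build_ring(12)
  p <- model_params(0.4, epsilon = 0.05)
  st <- theory_state(g, p)
  goals <- c(0, 5)
  mk <- all_pairs_navigation(g, st, p, "markov", goals = goals)
  n_rep <- 200
  mc <- all_pairs_navigation(g, st, p, "montecarlo", goals = goals,
                             n_routes = n_rep, seed = 11)
  # compare mean navigated length pair by pair
  for (i in seq_len(nrow(mk))) {
    j <- which(mc$start == mk$start[i] & mc$goal == mk$goal[i])
    se <- sqrt(mk$expected_steps[i]) / sqrt(n_rep)  # conservative scale
    expect_lt(abs(mc$expected_steps[j] - mk$expected_steps[i]),
              max(3 * se, 0.75))
  }
})

test_that("goal_signal_range applies the prefix rule", {
  routes <- data.frame(start = 1:6, goal = 0,
                       distance = c(1, 1, 2, 2, 3, 4),
                       expected_steps = 1,
                       prob_shortest = c(1, 1, 0.6, 0.6, 0.2, 0.9))
  class(routes) <- c("endo_routes", "data.frame")
  # distance 3 fails, so range stays 2 even though distance 4 passes
  expect_equal(goal_signal_range(routes), 2L)
  expect_equal(goal_signal_range(routes, threshold = 0.61), 1L)
})

test_that("summarize_routes aggregates by distance", {
  g <- build_ring(10)
  p <- model_params(0.4, epsilon = 0.01)
  st <- theory_state(g, p)
  r <- all_pairs_navigation(g, st, p, "markov")
  s <- summarize_routes(r)
  expect_equal(s$distance, 1:5)
  expect_equal(s$n_pairs, c(20, 20, 20, 20, 10))
  expect_true(all(s$mean_prob_shortest > 0.9))
})

test_that("an unlearned goal degrades to a noise-driven random walk", {
  g <- build_ring(8)
  p <- model_params(0.4, epsilon = 0.01)
  st <- circuit_state(8, 1, goal_nodes = 0L)  # G all zero
  r <- all_pairs_navigation(g, st, p, "markov")
  h <- random_walk_hitting_times(g, 0)
  expect_equal(r$expected_steps, h[r$start + 1], tolerance = 1e-6)
})

test_that("navigation speed-up over random walk is large on the tree", {
  g <- build_binary_tree(5)
  p <- model_params(0.35, epsilon = 0.01)
  st <- theory_state(g, p)
  r <- all_pairs_navigation(g, st, p, "markov")
  sp <- navigation_speedup(g, r)
  expect_gt(sp$ratio, 10)
})

test_that("navigate errors when no goal cell matches", {
  g <- build_ring(6)
  p <- model_params(0.3)
  st <- theory_state(g, p, goals = c(0, 1))
  expect_error(navigate(g, st, 3, 5, p), "goal cell")
})
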