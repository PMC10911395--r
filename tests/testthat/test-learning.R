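test_that("random_walk stays on edges and is reproducible", {
  g <- build_binary_tree(4)
  w <- random_walk(g, 500, start = 0, seed = 42)
  expect_length(w, 501L)
  A <- adjacency_matrix(g)
  steps <- cbind(w[-length(w)], w[-1]) + 1L
  expect_true(all(A[steps] == 1))
  expect_equal(w, random_walk(g, 500, start = 0, seed = 42))
})

test_that("edge_covering_walk traverses every edge enough times", {
  g <- build_ring(20)
  w <- edge_covering_walk(g, visits_per_edge = 3, seed = 1)
  trav <- table(paste(pmin(w[-length(w)], w[-1]), pmax(w[-length(w)], w[-1])))
  expect_equal(length(trav), nrow(g$edges))
  expect_true(all(trav >= 3))
})

test_that("first few steps each add one map synapse, then M = A", {
  g <- build_ring(14)
  p <- model_params(0.32, theta = 0.27, alpha = 0.3)
  walk <- c(0, 1, 2, 3)
  st <- learn_walk(g, walk, p)
  # three steps -> three undirected links, at full strength
  expect_equal(sum(st$M == 1), 6)
  expect_equal(st$M[1 + 1, 0 + 1], 1)
  expect_equal(st$M[2 + 1, 1 + 1], 1)
  expect_equal(st$M, t(st$M))
  # long enough walk recovers the adjacency exactly
  st2 <- learn_walk(g, random_walk(g, 2000, seed = 7), p)
  expect_equal(map_recovery_error(st2, g), 0)
  expect_equal(unname(round(st2$M)), unname(adjacency_matrix(g)))
})

test_that("learning uses the pre-update map output for plasticity", {
  # walking 0-1-2: at the step into 2, cell 1's activity must be computed
  # with the map that already contains link 0-1, and the new link 1-2 must
  # not retroactively change the recorded pre-synaptic activity.
  g <- build_ring(6)
  p <- model_params(0.4, theta = 0.38, alpha = 0.1)
  s0 <- circuit_state(6, 0)
  r1 <- learn_step(s0, NULL, 0, p, matrix(0, 0, 6))
  r2 <- learn_step(r1$state, r1$activity$v, 1, p, matrix(0, 0, 6))
  expect_equal(sum(r2$state$M), 2)  # link 0-1 both directions
  v_expected <- map_output(c(0, 1, 0, 0, 0, 0), r1$state$M, p)
  expect_equal(r2$activity$v, as.vector(v_expected))
})

test_that("goal learning tags resources and converges toward F", {
  g <- build_ring(10)
  p <- model_params(0.4, theta = 0.36, alpha = 0.3)
  res <- resource_field(g, 4)
  st <- learn_walk(g, random_walk(g, 4000, seed = 3), p, res)
  vals <- as.vector(st$G %*% map_outputs_all(st$M, p))
  # signal peaks at the resource node and approaches F = 1 there
  expect_equal(which.max(vals) - 1L, 4L)
  expect_equal(vals[5], 1, tolerance = 0.05)
  # and declines monotonically with ring distance from the target
  d <- pmin(abs(0:9 - 4), 10 - abs(0:9 - 4))
  expect_true(all(diff(vals[order(d)][cumsum(rle(sort(d))$lengths)]) < 0))
})

test_that("goal learning at the walk's first node tags the start", {
  g <- build_binary_tree(3)
  p <- model_params(0.33, theta = 0.30, alpha = 10)
  st <- learn_walk(g, c(0, 1, 3), p, resource_field(g, 0))
  expect_gt(st$G[1, 1], 0)
})

test_that("directed learning potentiates only the traveled direction", {
  g <- build_ring(6)
  p <- model_params(0.4, theta = 0.38)
  st <- learn_walk(g, c(0, 1), p, directed = TRUE)
  expect_equal(st$M[2, 1], 1)  # synapse from cell 0 onto cell 1
  expect_equal(st$M[1, 2], 0)
})

test_that("theta above the usable band learns nothing", {
  g <- build_ring(10)
  p <- model_params(0.3, theta = 0.95)
  expect_warning(
    st <- learn_walk(g, c(0, 1, 2), p),
    "threshold")
  expect_equal(sum(st$M), 0)
})

test_that("forgetting decays an unused link but keeps traveled ones", {
  g0 <- build_ring(14)
  g1 <- add_link(g0, 4, 11)
  p <- model_params(0.32, theta = 0.27, alpha = 0.3, delta = 0.1)
  res <- resource_field(g1, 4)
  # learn the ring plus the chord (recently traveled links sit near 1;
  # each high-pre / low-post event shaves exp(-delta) off)
  w1 <- edge_covering_walk(g1, 5, seed = 2)
  st <- learn_walk(g1, w1, p, res)
  expect_gt(st$M[5, 12], 0.8)
  # then the chord disappears; keep walking the plain ring from where
  # the exploration ended
  w2 <- random_walk(g0, 600, start = w1[length(w1)], seed = 3)
  st2 <- learn_walk(g0, w2, p, res, state = st)
  expect_lt(st2$M[5, 12], 0.5)   # unused chord synapse decays...
  expect_gt(st2$M[5, 6], 0.8)    # ...while ring link 4-5 stays strong
})

test_that("chained walks must continue where the previous one ended", {
  g <- build_ring(10)
  p <- model_params(0.4, theta = 0.36)
  w1 <- random_walk(g, 50, seed = 1)
  st <- learn_walk(g, w1, p)
  expect_error(
    learn_walk(g, c((w1[51] + 5) %% 10, 3), p, state = st),
    "continue from node")
})

test_that("forgetting goal rule decays an over-predicted resource", {
  g <- build_ring(10)
  p <- model_params(0.4, theta = 0.36, alpha = 0.3, delta = 0.1)
  # resource at node 4 first, then it disappears
  w1 <- random_walk(g, 2000, seed = 5)
  st <- learn_walk(g, w1, p, resource_field(g, 4))
  peak0 <- as.vector(st$G %*% map_outputs_all(st$M, p))[5]
  w2 <- random_walk(g, 2000, start = w1[length(w1)], seed = 6)
  st2 <- learn_walk(g, w2, p, matrix(0, 1, 10), state = st)
  peak1 <- as.vector(st2$G %*% map_outputs_all(st2$M, p))[5]
  expect_gt(peak0, 0.5)
  expect_lt(peak1, peak0 / 2)
})

test_that("map recovery also works with the saturating activation", {
  g <- build_ring(14)
  p <- model_params(0.45, activation = "saturating")
  st <- learn_walk(g, random_walk(g, 1500, seed = 4), p)
  expect_equal(map_recovery_error(st, g), 0)
})

test_that("habituation during learning still recovers the map", {
  # habituated point cells deliver a weaker drive, so some traversals miss
  # the plasticity threshold; a long enough walk still completes the map
  # because every edge is eventually crossed with recovered sensitivity
  g <- build_binary_tree(4)
  p <- model_params(0.33, theta = 0.30, alpha = 0.1, beta = 1.2,
                    tau = 100)
  st <- learn_walk(g, random_walk(g, 25000, seed = 8), p,
                   per_node_resources(g), habituation = TRUE)
  expect_equal(map_recovery_error(st, g), 0)
  expect_lt(min(st$h), 1)
})

test_that("learn_walk rejects invalid walks", {
  g <- build_ring(5)
  p <- model_params(0.3)
  expect_error(learn_walk(g, c(0, 7), p), "invalid")
})
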