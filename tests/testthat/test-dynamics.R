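test_that("input aggregation follows the documented activator/inhibitor rule", {
  net <- rnm_network(rbind(edge_df("A", "ACAN", 1),
                           edge_df("B", "ACAN", -1)))
  st <- c(A = 1, B = 0, ACAN = 0.2)
  expect_equal(input_strength(net, "ACAN", st), 1)          # saturated activator
  st2 <- c(A = 1, B = 1, ACAN = 0.2)
  expect_equal(input_strength(net, "ACAN", st2), 0)         # full inhibition
  # one activator (a, alpha) + one inhibitor (b, beta): omega = a * (1 - b)
  st3 <- c(A = 0.6, B = 0.3, ACAN = 0.2)
  expect_equal(input_strength(net, "ACAN", st3), 0.6 * (1 - 0.3))

  # two activators: weighted average (alpha*a + beta*b) / (alpha + beta)
  net2 <- rnm_network(rbind(edge_df("A", "ACAN", 1, 2),
                            edge_df("B", "ACAN", 1, 0.5)))
  st4 <- c(A = 0.8, B = 0.2, ACAN = 0)
  expect_equal(input_strength(net2, "ACAN", st4),
               (2 * 0.8 + 0.5 * 0.2) / 2.5)

  # unregulated generic node: own activation; pure input: 0
  net3 <- make_toy_network("cascade")$network
  st5 <- c(X = 0.7, M = 0.1, ACAN = 0.4)
  expect_equal(input_strength(net3, "X", st5), 0)
  expect_equal(input_strength(make_toy_network("self_activator")$network,
                              "ACAN", c(ACAN = 0.3)), 0.3)
  expect_error(input_strength(net, "NOPE", st), "NOPE")
})

test_that("one dynamics step respects clamps, targets and bounds", {
  net <- make_toy_network("cascade")$network
  p <- dynamics_params()

  # fully clamped: output identical to the clamp vector
  cl <- c(X = 0.3, M = 0.8, ACAN = 0.1)
  s1 <- step_dynamics(net, c(X = 0.9, M = 0.2, ACAN = 0.5), cl, p)
  expect_equal(s1, c(X = 0.3, M = 0.8, ACAN = 0.1))

  # omega held at 0.5 by a clamped regulator -> state converges toward 0.5
  st <- c(X = 0.5, M = 0.9, ACAN = 0.5)
  for (i in 1:500) st <- step_dynamics(net, st, c(X = 0.5), p)
  expect_equal(unname(st[["M"]]), 0.5, tolerance = 1e-6)

  # unclamped pure input decays geometrically: x_k = x_0 * (1 - gamma*step)^k
  st <- c(X = 0.7, M = 0, ACAN = 0)
  for (k in 1:5) {
    st <- step_dynamics(net, st, NULL, p)
    expect_equal(unname(st[["X"]]), 0.7 * (1 - p$decay * p$step)^k,
                 tolerance = 1e-12)
  }
})

test_that("steady-state solver finds the bistable fixed points of a 1-D map", {
  toy <- make_toy_network("self_activator")
  net <- toy$network
  p <- dynamics_params()

  # brute-force enumeration of f(x) = x on a fine 1-D grid (sign changes)
  g <- seq(0, 1, by = 1e-4)
  r <- vapply(g, function(x) {
    unname(oracle_residual(net, c(ACAN = x), p))
  }, 0)
  sign_flips <- g[which(diff(sign(r)) != 0)]
  expect_length(sign_flips, 3)   # 0, 0.5, 1 (0 and 1 are exact roots)

  hi <- solve_steady_state(net, c(ACAN = 1), params = p)
  lo <- solve_steady_state(net, c(ACAN = 0), params = p)
  expect_true(hi$converged && lo$converged)
  expect_equal(unname(hi$state[["ACAN"]]), 1, tolerance = 1e-5)
  expect_equal(unname(lo$state[["ACAN"]]), 0, tolerance = 1e-5)
})

test_that("toggle steady states match the grid oracle and clamps are exact", {
  net <- make_toy_network("toggle")$network
  p <- dynamics_params()
  # off-diagonal grid: the symmetric saddle is reachable only from the
  # measure-zero equal-coordinate manifold
  gs <- grid_steady_states(net, p, grid = 0.05, jitter = TRUE)
  att <- rnmconcord:::dedup_states(gs$states, 1e-3)
  expect_equal(ncol(att), 2)   # exactly two stable states
  roots <- scan_fixed_points(net, p)
  dmax <- max(vapply(seq_len(ncol(att)), function(j) {
    min(vapply(roots, function(z) max(abs(z - att[, j])), 1))
  }, 1))
  expect_lt(dmax, 10 * p$tol)

  ss <- solve_steady_state(net, c(ACAN = 0.2, MMP13 = 0.9),
                           clamps = c(ACAN = 0.75), params = p)
  expect_identical(unname(ss$state[["ACAN"]]), 0.75)

  all_cl <- c(ACAN = 0.3, MMP13 = 0.6)
  ss2 <- solve_steady_state(net, c(ACAN = 0.9, MMP13 = 0.1), all_cl, p)
  expect_equal(ss2$iterations, 1L)
  expect_equal(ss2$state, all_cl)
})

test_that("initial-state sampling is seeded, clamped and uniform", {
  net <- make_benchmark_network()$network
  a <- sample_initial_states(net, c(TNF = 1), n = 100, seed = 42)
  b <- sample_initial_states(net, c(TNF = 1), n = 100, seed = 42)
  expect_identical(a, b)
  expect_true(all(a["TNF", ] == 1))

  one <- make_toy_network("self_activator")$network
  x <- sample_initial_states(one, NULL, n = 10000, seed = 7)
  expect_gt(mean(x), 0.48)
  expect_lt(mean(x), 0.52)
})

test_that("states stay in [0,1] and clamps hold under arbitrary iteration", {
  p <- dynamics_params()
  for (s in 1:8) {
    net <- make_random_network(5, seed = s)
    nodes <- network_nodes(net)
    set.seed(100 + s)
    cl <- stats::setNames(stats::runif(2), sample(nodes, 2))
    st <- stats::setNames(stats::runif(length(nodes)), nodes)
    st[names(cl)] <- cl
    for (k in 1:50) {
      st <- step_dynamics(net, st, cl, p)
      expect_true(all(st >= 0 & st <= 1))
      expect_identical(unname(st[names(cl)]), unname(cl))
    }
  }
})

test_that("trajectories are fully determined by their inputs", {
  net <- make_random_network(6, seed = 3)
  nodes <- network_nodes(net)
  st <- stats::setNames(seq(0.1, 0.9, length.out = length(nodes)), nodes)
  p <- dynamics_params()
  t1 <- t2 <- st
  for (k in 1:30) {
    t1 <- step_dynamics(net, t1, c(N1 = 0.4), p)
    t2 <- step_dynamics(net, t2, c(N1 = 0.4), p)
  }
  expect_identical(t1, t2)
})
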