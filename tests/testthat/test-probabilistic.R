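test_that("per-node switching probabilities follow the noisy threshold rule", {
  p <- noise_params(mu = 2, c = 0.5)
  # closed form away from zero input
  expect_equal(node_on_probability(0.3, 0, p), 1 / (1 + exp(-2 * 2 * 0.3)))
  # saturation without overflow
  expect_equal(node_on_probability(1e6, 0, p), 1)
  expect_equal(node_on_probability(-1e6, 1, p), 0)
  # unregulated nodes retain with probability 1/(1+c)
  expect_equal(node_on_probability(0, 1, p), 1 / 1.5)
  expect_equal(node_on_probability(0, 0, p), 1 - 1 / 1.5)
  # c = 1: a fair coin; c = 0: frozen hold (deterministic limit)
  expect_equal(node_on_probability(0, 1, noise_params(5, 1)), 0.5)
  expect_equal(node_on_probability(0, 1, noise_params(5, 0)), 1)
  expect_error(noise_params(-1, 0), "positive")
})

test_that("transition matrices are column-stochastic", {
  for (seed in 1:4) {
    spec <- random_network(6, edge_density = 0.5, seed = seed)
    TT <- transition_matrix(spec, noise_params(3, 0.2))
    expect_lt(max(abs(colSums(TT) - 1)), 1e-12)
  }
  expect_error(transition_matrix(random_network(20, seed = 1),
                                 noise_params(1)), "heuristic_steady_state")
})

test_that("transition probabilities factor over conditionally independent nodes", {
  spec <- network_spec(c("A", "B"), W = rbind(c(0, -1), c(1, 0)),
                       b = c(0.2, -0.1))
  pars <- noise_params(mu = 1.5, c = 0.3)
  # independent 4x4 oracle computed from the scalar rule
  for (from in 0:3) {
    s <- decode_state(from, 2)[, 1]
    h <- as.vector(spec$W %*% s + spec$b)
    p_on <- ifelse(h != 0, 1 / (1 + exp(-2 * 1.5 * h)),
                   ifelse(s == 1, 1 / 1.3, 1 - 1 / 1.3))
    for (to in 0:3) {
      s2 <- decode_state(to, 2)[, 1]
      oracle <- prod(ifelse(s2 == 1, p_on, 1 - p_on))
      expect_equal(transition_probability(s, s2, spec, pars), oracle)
    }
  }
  # a single unregulated node with c = 1 is a fair coin
  iso <- network_spec("A")
  expect_equal(transition_probability(1, 0, iso, noise_params(5, 1)), 0.5)
  expect_equal(transition_probability(1, 1, iso, noise_params(5, 1)), 0.5)
})

test_that("fixed nodes pin their transition factor to 0/1", {
  spec <- chain_spec()
  spec$fixed["B"] <- 1L
  pars <- noise_params(2, 0.5)
  expect_equal(transition_probability(c(0, 0), c(0, 0), spec, pars), 0)
  TT <- transition_matrix(spec, pars)
  expect_lt(max(abs(colSums(TT) - 1)), 1e-12)
  expect_true(all(TT[c(1, 2), ] == 0))  # states with B = 0 unreachable
})

test_that("master-equation steady state is a fixed point and matches eigen", {
  spec <- random_network(3, edge_density = 0.7, seed = 5)
  pars <- noise_params(2, 0.3)
  ss <- exhaustive_steady_state(spec, pars, tol = 1e-12)
  expect_true(ss$meta$converged)
  expect_equal(sum(ss$p), 1)
  TT <- transition_matrix(spec, pars)
  expect_lt(sum(abs(TT %*% ss$p - ss$p)), 1e-10)  # stationarity
  # independent oracle: dominant eigenvector of the explicit matrix
  ev <- eigen(TT)
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v <- v / sum(v)
  expect_equal(unname(as.numeric(ss$p)), v, tolerance = 1e-8)
})

test_that("heuristic steady state is seed-reproducible and consistent", {
  spec <- random_network(4, edge_density = 0.6, seed = 8)
  pars <- noise_params(1.5, 0.5)
  h1 <- heuristic_steady_state(spec, pars, n_traj = 200, burn_in = 20,
                               steps = 50, seed = 21)
  h2 <- heuristic_steady_state(spec, pars, n_traj = 200, burn_in = 20,
                               steps = 50, seed = 21)
  expect_identical(h1$p, h2$p)

  ex <- exhaustive_steady_state(spec, pars)
  h3 <- heuristic_steady_state(spec, pars, n_traj = 500, burn_in = 50,
                               steps = 400, seed = 22)
  p_hat <- rep(0, 16)
  p_hat[as.integer(names(h3$p)) + 1] <- h3$p
  # total-variation agreement at Monte-Carlo scale
  expect_lt(0.5 * sum(abs(p_hat - as.numeric(ex$p))), 0.05)
})

test_that("large mu recovers the deterministic successor", {
  pars <- noise_params(mu = 500, c = 0.01)
  for (seed in 1:5) {
    spec <- random_network(8, edge_density = 0.4, seed = seed)
    S <- sample_states(8, 40, seed = seed + 50)
    det <- weighted_step(S, spec)
    P <- attractorscape:::on_probability_matrix(S, spec, pars)
    greedy <- (P > 0.5) * 1
    expect_equal(greedy, det)
  }
})

test_that("greedy most-probable paths match deterministic trajectories", {
  spec <- random_network(7, edge_density = 0.4, seed = 31)
  pars <- noise_params(mu = 200, c = 0.01)
  s0 <- sample_states(7, 1, seed = 5)[, 1]
  fa <- find_attractor(s0, spec)
  path <- most_probable_path(s0, spec, pars)
  n_tr <- ncol(fa$trajectory)
  expect_equal(state_code(path[, seq_len(min(n_tr, ncol(path)))]),
               state_code(fa$trajectory[, seq_len(min(n_tr, ncol(path)))]))
})

test_that("distributions export with metadata sidecars", {
  spec <- random_network(3, edge_density = 0.6, seed = 2)
  ss <- exhaustive_steady_state(spec, noise_params(2, 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  export_steady_state(ss, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 8L)
  expect_equal(back$probability, unname(as.numeric(ss$p)))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$mu, 2)
  expect_equal(meta$method, "exhaustive")
})
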