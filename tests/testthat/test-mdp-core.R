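test_that("bellman backup matches direct formula on degenerate models", {
  # one state, one action, single outcome with P = 1, r = 1, gamma = 0
  m0 <- mdp_model(states = matrix(0L), actions = matrix(0L),
                  outcomes = matrix(0L),
                  transition = function(s, a, o) list(reward = 1,
                                                      next_state = 0L),
                  outcome_prob = function(s, a) 1, gamma = 0)
  expect_equal(bellman_backup(0L, 0, m0), 1.0)
  # deterministic transition, r = 2, gamma = 0.5, V(next) = 4 -> 4.0
  m1 <- mdp_model(states = matrix(0:1, ncol = 1), actions = matrix(0L),
                  outcomes = matrix(0L),
                  transition = function(s, a, o) list(reward = 2,
                                                      next_state = 1L),
                  outcome_prob = function(s, a) 1, gamma = 0.5)
  expect_equal(bellman_backup(0L, c(0, 4), m1), 2 + 0.5 * 4)
  expect_error(bellman_backup(7L, c(0, 4), m1), "out of range|unknown")
})

test_that("bellman backup equals the naive triple-loop oracle on the toy MDP", {
  m <- toy_mdp()
  set.seed(42)
  V <- rnorm(3)
  expected <- oracle_backup(m, V)
  got <- vapply(0:2, function(s) bellman_backup(s, V, m), numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("backup rejects models whose probabilities do not normalise", {
  bad <- mdp_model(states = matrix(0L), actions = matrix(0L),
                   outcomes = matrix(0:1, ncol = 1),
                   transition = function(s, a, o) list(reward = 0,
                                                       next_state = 0L),
                   outcome_prob = function(s, a) c(0.5, 0.4), gamma = 0.5)
  expect_error(bellman_backup(0L, 0, bad), "model-validation")
  expect_error(validate_model(bad), "model-validation")
})

test_that("sweep is batch-size invariant and equals the per-state oracle", {
  m <- toy_mdp()
  set.seed(7)
  V <- rnorm(3)
  expected <- oracle_backup(m, V)
  for (bs in c(1, 2, 7, Inf)) {
    got <- sweep_values(V, m, vi_config(batch_size = bs))
    expect_equal(got, expected, tolerance = 1e-12,
                 info = paste("batch_size", bs))
  }
  # multi-device layout contract gives the same answer
  expect_equal(sweep_values(V, m, vi_config(batch_size = 1, n_devices = 2)),
               expected, tolerance = 1e-12)
  # self-loop identity: r = 0 keeps V at 0
  mz <- self_loop_mdp(r = 0, gamma = 0.9)
  expect_identical(sweep_values(0, mz), 0)
})

test_that("sweep is batch-size invariant on a scenario instance", {
  m <- tiny_a()
  set.seed(3)
  V <- rnorm(m$n_states)
  base <- sweep_values(V, m, vi_config(batch_size = 1))
  for (bs in c(7, 50, 1000)) {
    expect_equal(sweep_values(V, m, vi_config(batch_size = bs)), base,
                 tolerance = 1e-12)
  }
})

test_that("state padding follows the (devices, batches, batch size) layout", {
  p <- pad_states(121, batch_size = 50)
  expect_equal(p$n_batches, 3L)
  expect_equal(p$total_slots, 150L)
  expect_equal(p$n_padding, 29L)
  p2 <- pad_states(121, batch_size = 50, n_devices = 2)
  expect_equal(p2$n_batches, 2L)   # per device
  expect_equal(p2$total_slots, 200L)
  # unpadding is the identity on the original order
  real <- p2$slot_state[!is.na(p2$slot_state)]
  expect_identical(real, 1:121)
})

test_that("value iteration recovers closed forms and the enumeration oracle", {
  # geometric series: V* = 1 / (1 - 0.5) = 2
  sol <- value_iteration(self_loop_mdp(r = 1, gamma = 0.5),
                         vi_config(tolerance = 1e-10))
  expect_true(sol$converged)
  expect_equal(sol$values, 2, tolerance = 1e-8)
  # gamma = 0: V* = max_a E[r], one effective iteration
  m0 <- toy_mdp(gamma = 0)
  sol0 <- value_iteration(m0, vi_config(tolerance = 1e-12))
  expect_equal(sol0$values, oracle_backup(m0, rep(0, 3)), tolerance = 1e-12)
  # toy MDP against exhaustive policy enumeration (linear solves)
  m <- toy_mdp(gamma = 0.9)
  oracle <- oracle_policy_enumeration(m)
  sol <- value_iteration(m, vi_config(tolerance = 1e-10))
  expect_true(sol$converged)
  expect_equal(sol$values, oracle$values, tolerance = 1e-6)
  expect_equal(sol$policy$action_index, unname(oracle$policy))
})

test_that("sweeps contract at rate gamma towards the fixed point", {
  m <- toy_mdp(gamma = 0.9)
  Vstar <- oracle_policy_enumeration(m)$values
  V <- rep(0, 3)
  for (i in 1:25) {
    Vnew <- sweep_values(V, m)
    expect_lte(max(abs(Vnew - Vstar)), 0.9 * max(abs(V - Vstar)) + 1e-12)
    V <- Vnew
  }
})

test_that("policy extraction breaks ties toward the smallest action", {
  # two actions identical in effect -> action 1 (ordinal 0) everywhere
  m <- mdp_model(states = matrix(0:1, ncol = 1),
                 actions = matrix(0:1, ncol = 1),
                 outcomes = matrix(0L),
                 transition = function(s, a, o) list(reward = 1,
                                                     next_state = s),
                 outcome_prob = function(s, a) 1, gamma = 0.5)
  pol <- extract_policy(c(5, 5), m)
  expect_true(all(pol$action_index == 1L))
  expect_true(all(pol$actions == 0L))
})

test_that("the policy is stable once the convergence test passes", {
  m <- tiny_a(gamma = 0.9)
  sol <- value_iteration(m, vi_config(tolerance = 1e-5))
  expect_true(sol$converged)
  V_extra <- sweep_values(sol$values, m)
  pol_extra <- extract_policy(V_extra, m)
  expect_identical(pol_extra$action_index, sol$policy$action_index)
})

test_that("sup-norm convergence bound against the oracle fixed point holds", {
  m <- toy_mdp(gamma = 0.9)
  Vstar <- oracle_policy_enumeration(m)$values
  theta <- 1e-4
  V <- rep(0, 3)
  repeat {
    Vnew <- sweep_values(V, m)
    if (convergence_sup_norm(V, Vnew, theta)) { V <- Vnew; break }
    V <- Vnew
  }
  expect_lte(max(abs(V - Vstar)), theta * 0.9 / (1 - 0.9))
})

test_that("asynchronous value iteration reaches the synchronous fixed point", {
  m <- toy_mdp(gamma = 0.9)
  cfg <- vi_config(tolerance = 1e-8)
  sync <- value_iteration(m, cfg)
  async <- value_iteration_async(m, vi_config(tolerance = 1e-8,
                                              batch_size = 1))
  expect_lt(max(abs(sync$values - async$values)), 1e-6)
  expect_identical(sync$policy$action_index, async$policy$action_index)
  expect_lte(async$n_iterations, sync$n_iterations)
  # single state: trajectories coincide exactly
  s1 <- value_iteration(self_loop_mdp(), vi_config(tolerance = 1e-10))
  a1 <- value_iteration_async(self_loop_mdp(), vi_config(tolerance = 1e-10))
  expect_equal(s1$values, a1$values, tolerance = 1e-12)
  expect_identical(s1$n_iterations, a1$n_iterations)
})

test_that("checkpoints are written on the requested schedule", {
  dir <- withr::local_tempdir()
  sol <- value_iteration(self_loop_mdp(),
                         vi_config(tolerance = 1e-6, checkpoint_every = 10,
                                   checkpoint_dir = dir))
  files <- list.files(dir, pattern = "values_iter")
  expect_gt(length(files), 0)
  ck <- utils::read.csv(file.path(dir, files[1]))
  expect_named(ck, c("state", "value"))
})

test_that("non-convergence within the iteration cap is flagged, not hidden", {
  sol <- value_iteration(self_loop_mdp(r = 1, gamma = 0.5),
                         vi_config(max_iterations = 3, tolerance = 1e-12))
  expect_false(sol$converged)
  expect_equal(sol$n_iterations, 3L)
})

test_that("tuple enumeration and indexing are mutually inverse", {
  rad <- c(3L, 2L, 4L)
  g <- enumerate_tuples(rad)
  expect_equal(nrow(g), 24)
  expect_false(anyDuplicated(g) > 0)
  expect_identical(tuple_index(g, rad), 1:24)
  expect_error(tuple_index(c(3, 0, 0), rad), "out of range")
})
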