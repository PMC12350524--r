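test_that("issued-pair distribution factorises when substitution is off", {
  tab <- issued_pmf_table(1.2, 0.8, rho = 0, 4, 4)
  pa <- poisson_min_pmf <- function(mu, I) {
    # pmf of min(Poisson(mu), I): independent oracle by direct mass
    p <- dpois(0:I, mu); p[I + 1] <- 1 - ppois(I - 1, mu); p
  }
  for (I_a in c(0, 2, 4)) {
    for (I_b in c(0, 1, 3)) {
      slice <- tab[seq_len(I_a + 1), seq_len(I_b + 1), I_a + 1, I_b + 1,
                   drop = FALSE][, , 1, 1]
      expected <- outer(poisson_min_pmf(1.2, I_a), poisson_min_pmf(0.8, I_b))
      expect_equal(matrix(slice, I_a + 1, I_b + 1), expected,
                   tolerance = 1e-9)
    }
  }
  # both stocks empty: nothing can be issued
  expect_equal(tab[1, 1, 1, 1], 1)
})

test_that("full substitution matches the exhaustive-enumeration oracle", {
  # one unit of product A, no product B stock, rho = 1:
  # P(h_a = 1) = P(demand_a + demand_b >= 1)
  tab <- issued_pmf_table(1.3, 0.7, rho = 1, 2, 2)
  expect_equal(sum(tab[2, , 2, 1]), 1 - exp(-1.3) * exp(-0.7),
               tolerance = 1e-9)
})

test_that("issued distributions normalise and respect the stock support", {
  m <- tiny_b(rho = 0.6)
  for (i in sample(seq_len(m$n_states), 50)) {
    s <- m$states$states[i, ]
    p <- m$outcome_prob(s, c(0L, 0L))
    expect_equal(sum(p), 1, tolerance = 1e-8)
    sup <- m$outcomes[p > 0, , drop = FALSE]
    expect_true(all(sup[, 1] <= sum(s[1:2])))
    expect_true(all(sup[, 2] <= sum(s[3:4])))
  }
})

test_that("expected product A issues are monotone in the substitution rate", {
  rhos <- c(0, 0.25, 0.5, 0.75, 1)
  eha <- vapply(rhos, function(r) {
    tab <- issued_pmf_table(1.2, 0.8, r, 3, 3)
    sum(tab[, , 3, 2] * (0:3))  # I_a = 2, I_b = 1
  }, numeric(1))
  expect_true(all(diff(eha) >= -1e-12))
  expect_gt(eha[5], eha[1])
})

test_that("two-product transition follows the revenue reward and FIFO ageing", {
  m <- tiny_b()
  p <- m$params
  # no stock, nothing issued, order one of each
  tr <- m$transition(c(0L, 0L, 0L, 0L), c(1L, 1L), c(0L, 0L))
  expect_equal(tr$reward, -p$C_v_a - p$C_v_b)
  expect_equal(unname(tr$next_state), c(0, 1, 0, 1))
  # revenue formula: issued (2,1) at C_r = 1 each, no order
  tr <- m$transition(c(1L, 1L, 1L, 0L), c(0L, 0L), c(2L, 1L))
  expect_equal(tr$reward, 1 * 2 + 1 * 1)
  # infeasible issue refused
  expect_error(m$transition(c(0L, 0L, 0L, 0L), c(0L, 0L), c(1L, 0L)),
               "exceeds|infeasible")
})

test_that("units are conserved on randomised feasible transitions", {
  m <- tiny_b(m = 3, A_max_a = 2, A_max_b = 2)
  set.seed(21)
  ok <- TRUE
  for (k in 1:1000) {
    s <- m$states$states[sample(m$n_states, 1), ]
    h_a <- sample(0:sum(s[1:3]), 1); h_b <- sample(0:sum(s[4:6]), 1)
    a <- c(sample(0:2, 1), sample(0:2, 1))
    tr <- m$transition(s, a, c(h_a, h_b))
    nxt <- tr$next_state
    # closing (excluding the arriving orders) + issued + expired = opening
    expired_a <- max(s[1] - h_a, 0); expired_b <- max(s[4] - h_b, 0)
    ok <- ok &&
      sum(s[1:3]) == sum(nxt[1:2]) + h_a + expired_a &&
      sum(s[4:6]) == sum(nxt[4:5]) + h_b + expired_b &&
      nxt[3] == a[1] && nxt[6] == a[2]
  }
  expect_true(ok)
})

test_that("the initial value is the expected sales revenue", {
  m <- tiny_b()
  p <- m$params
  expect_equal(initial_value_b(c(0L, 0L, 0L, 0L), p), 0)
  # monotone: an extra unit of product A never lowers it
  v1 <- initial_value_b(c(0L, 1L, 0L, 1L), p)
  v2 <- initial_value_b(c(1L, 1L, 0L, 1L), p)
  expect_gte(v2, v1)
  # abundant stock: approaches total expected demand revenue (no substitution
  # occurs because product B demand is fully met)
  mbig <- scenario_b(m = 2, mu_a = 1, mu_b = 0.8, rho = 0.7,
                     A_max_a = 12, A_max_b = 12, max_enumerate = 1)
  v <- initial_value_b(c(12L, 12L, 12L, 12L), mbig$params)
  expect_equal(v, 1 * 1 + 1 * 0.8, tolerance = 1e-6)
})

test_that("the span test stops on uniform value drift", {
  expect_true(convergence_span(c(0, 0), c(7, 7), 1e-4))   # large but uniform
  expect_false(convergence_span(c(0, 0), c(0, 2e-4), 1e-4))
  # aperiodic two-state chain: drift at convergence equals the optimal gain
  m <- mdp_model(
    states = matrix(0:1, ncol = 1), actions = matrix(0:1, ncol = 1),
    outcomes = matrix(0:1, ncol = 1),
    transition = function(s, a, o) {
      list(reward = if (s == 0) 1 + 0.5 * a else 3, next_state = o)
    },
    outcome_prob = function(s, a) c(0.5, 0.5), gamma = 1,
    convergence = function(h, tol) {
      n <- length(h); n >= 2 && convergence_span(h[[n - 1]], h[[n]], tol)
    })
  sol <- value_iteration(m, vi_config(tolerance = 1e-10))
  drift <- sweep_values(sol$values, m) - sol$values
  # optimal policy takes a = 1 in state 0; stationary distribution is
  # (1/2, 1/2), so the gain is (1.5 + 3) / 2
  expect_equal(mean(drift), (1.5 + 3) / 2, tolerance = 1e-8)
})

test_that("space sizes match the closed forms", {
  m <- tiny_b()
  expect_equal(m$n_states, 3^2 * 3^2)
  expect_equal(m$n_actions, 9)
  expect_equal(m$n_outcomes, (2 * 2 + 1)^2)
  sz <- scenario_b_sizes(2, 10, 10)
  expect_equal(sz$n_states, 14641)
  expect_equal(sz$n_actions, 121)
  expect_equal(sz$n_outcomes, 441)
})

test_that("with no substitution the joint problem decomposes exactly", {
  joint <- tiny_b(rho = 0, mu_a = 1, mu_b = 0.8)
  only_a <- scenario_b(m = 2, mu_a = 1, mu_b = 0, rho = 0,
                       A_max_a = 2, A_max_b = 0)
  only_b <- scenario_b(m = 2, mu_a = 0.8, mu_b = 0, rho = 0,
                       A_max_a = 2, A_max_b = 0)
  # iterate the same number of sweeps from the scenario's initial values
  iterate <- function(model, k) {
    V <- model$initial_value(model)
    for (i in seq_len(k)) V <- sweep_values(V, model)
    V
  }
  Vj <- iterate(joint, 10)
  Va <- iterate(only_a, 10)
  Vb <- iterate(only_b, 10)
  # joint state (sa, sb) maps to product states sa and sb
  S <- joint$states$states
  ia <- only_a$states$index_of(cbind(S[, 1], S[, 2], 0L, 0L))
  ib <- only_b$states$index_of(cbind(S[, 3], S[, 4], 0L, 0L))
  expect_equal(Vj, Va[ia] + Vb[ib], tolerance = 1e-9)
})

test_that("the structure-exploiting backend equals the reference backup", {
  m <- tiny_b(rho = 0.6, mu_a = 1.1, mu_b = 0.5)
  set.seed(9)
  V <- rnorm(m$n_states)
  got <- sweep_values(V, m)
  ref <- vapply(seq_len(m$n_states),
                function(i) bellman_backup(m$states$states[i, ], V, m),
                numeric(1))
  expect_equal(got, ref, tolerance = 1e-10)
})
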