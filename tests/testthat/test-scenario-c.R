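test_that("weekday demand pmfs are proper and match direct negative-binomial mass", {
  m <- tiny_c()
  p <- m$params
  for (tau in 0:6) {
    pmf <- demand_pmf_weekday(tau, p)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    size <- p$weekday_demand[tau + 1, 1]; mu <- p$weekday_demand[tau + 1, 2]
    expect_equal(pmf[seq_len(p$D_max)],
                 dnbinom(0:(p$D_max - 1), size = size, mu = mu),
                 tolerance = 1e-12)
    expect_equal(pmf[p$D_max + 1],
                 1 - pnbinom(p$D_max - 1, size = size, mu = mu),
                 tolerance = 1e-12)
  }
  # identical weekday parameters give identical pmfs
  wd <- platelet_weekday_demand(); wd[2, ] <- wd[1, ]
  m2 <- scenario_c(m = 3, A_max = 3, D_max = 6, weekday_demand = wd)
  expect_identical(demand_pmf_weekday(0, m2$params),
                   demand_pmf_weekday(1, m2$params))
  expect_error(demand_pmf_weekday(7, p), "weekday")
})

test_that("arrival-age profiles follow the multinomial law", {
  # nothing ordered: the zero profile is certain
  prof <- perishvi::arrival_profile_pmf(0, c(0.5, 0.3, 0.2))
  expect_equal(sum(prof), 1)
  expect_equal(prof[1], 1)
  # degenerate life pmf: everything arrives at full life
  profs <- rbind(c(0, 0, 4), c(4, 0, 0), c(2, 1, 1))
  p <- arrival_profile_pmf(4, c(0, 0, 1), profs)
  expect_equal(p, c(1, 0, 0))
  # enumeration oracle: three i.i.d. categorical draws
  q <- c(0.5, 0.3, 0.2)
  draws <- expand.grid(1:3, 1:3, 1:3)
  w <- q[draws[, 1]] * q[draws[, 2]] * q[draws[, 3]]
  profs3 <- enumerate_tuples(rep(4L, 3))
  profs3 <- profs3[rowSums(profs3) <= 3, , drop = FALSE]
  expected <- vapply(seq_len(nrow(profs3)), function(i) {
    y <- profs3[i, ]
    if (sum(y) != 3) return(0)
    cnt <- vapply(seq_len(nrow(draws)), function(j) {
      all(tabulate(unlist(draws[j, ]), 3) == y)
    }, logical(1))
    sum(w[cnt])
  }, numeric(1))
  expect_equal(arrival_profile_pmf(3, q, profs3), expected, tolerance = 1e-12)
})

test_that("single-day transition matches a hand-enumerated micro-case", {
  m <- scenario_c(m = 3, A_max = 20, D_max = 20)
  # stock: one unit expiring tonight; order 2 arrives as one life-2 and one
  # life-3 unit; demand 2 is issued OUFO (the life-1 unit, then the life-2)
  tr <- m$transition(c(4L, 1L, 0L), 2L, c(2L, 0L, 1L, 1L))
  # remaining: the life-3 unit only; holding charged on it; fixed order cost
  expect_equal(tr$reward, -(1 * 1 + 10))
  expect_equal(unname(tr$next_state), c(5, 0, 1))
  # empty stock, no order, demand d: shortage only
  tr <- m$transition(c(0L, 0L, 0L), 0L, c(7L, 0L, 0L, 0L))
  expect_equal(tr$reward, -20 * 7)
  expect_equal(unname(tr$next_state), c(1, 0, 0))
  # weekday wraps around the week
  tr <- m$transition(c(6L, 0L, 0L), 0L, c(0L, 0L, 0L, 0L))
  expect_equal(tr$next_state[1], 0)
})

test_that("deliveries breaching the per-age capacity are rejected without cost", {
  m <- tiny_c(A_max = 3)
  full <- c(0L, 3L, 3L)  # every observed age class at capacity
  # arrivals at already-full ages are rejected: identical to an empty profile
  tr_full <- m$transition(full, 3L, c(2L, 2L, 3L, 0L))
  tr_none <- m$transition(full, 3L, c(2L, 0L, 0L, 0L))
  expect_equal(tr_full$reward, tr_none$reward)
  expect_equal(tr_full$next_state, tr_none$next_state)
  # fresh arrivals (life m) are capped at A_max
  tr <- m$transition(c(0L, 0L, 0L), 3L, c(0L, 0L, 0L, 3L))
  expect_equal(unname(tr$next_state), c(1, 0, 3))
})

test_that("units are conserved and holding dominates wastage", {
  m <- tiny_c()
  p <- m$params
  set.seed(13)
  ok_conserve <- TRUE; ok_holding <- TRUE
  for (k in 1:300) {
    s <- m$states$states[sample(m$n_states, 1), ]
    o <- m$outcomes[sample(m$n_outcomes, 1), ]
    a <- sample(0:p$A_max, 1)
    tr <- m$transition(s, a, o)
    stock <- s[-1]; d <- o[1]; y <- o[-1]
    accepted <- sum(pmin(y[1:2], p$A_max - stock)) + min(y[3], p$A_max)
    issued <- min(d, sum(stock) + accepted)
    closing <- sum(tr$next_state[-1])
    expired <- sum(stock) + accepted - issued - closing
    ok_conserve <- ok_conserve &&
      isTRUE(all.equal(sum(stock) + accepted, issued + expired + closing))
    # reward recomputation pins down expiry >= 0 and holding >= wastage
    shortage <- d - issued
    holding_charged <- closing + expired
    rew <- -(p$C_h * holding_charged + p$C_s * shortage + p$C_w * expired +
               p$C_f * (a > 0))
    ok_holding <- ok_holding && isTRUE(all.equal(rew, tr$reward)) &&
      expired >= 0 && holding_charged >= expired
  }
  expect_true(ok_conserve)
  expect_true(ok_holding)
})

test_that("weekday advances by one modulo seven in every transition", {
  m <- tiny_c()
  set.seed(3)
  taus <- vapply(1:50, function(k) {
    s <- m$states$states[sample(m$n_states, 1), ]
    o <- m$outcomes[sample(m$n_outcomes, 1), ]
    tr <- m$transition(s, 0L, o)
    tr$next_state[1] == (s[1] + 1) %% 7
  }, logical(1))
  expect_true(all(taus))
})

test_that("space sizes match the closed forms, including the infeasible m = 8", {
  m <- tiny_c(m = 3, A_max = 3, D_max = 6)
  expect_equal(m$n_states, 7 * 4^2)
  expect_equal(m$n_actions, 4)
  expect_equal(m$n_outcomes, 7 * choose(3 + 3, 3))
  expect_equal(nrow(m$profiles), choose(3 + 3, 3))
  sz3 <- scenario_c_sizes(3); sz5 <- scenario_c_sizes(5); sz8 <- scenario_c_sizes(8)
  expect_equal(sz3$n_states, 3087)
  expect_equal(sz3$n_outcomes, 37191)
  expect_equal(sz5$n_states, 1361367)
  expect_equal(sz5$n_outcomes, 1115730)
  expect_equal(sz8$n_states, 12607619787)
  expect_equal(sz8$n_outcomes, 65270205)
  # m = 8 is count-only: the solver refuses, the simulator still works
  big <- scenario_c(m = 8)
  expect_true(big$count_only)
  expect_error(value_iteration(big), "memory guard")
})

test_that("an endogenous model with a constant pmf equals the exogenous model", {
  q <- c(0.2, 0.3, 0.5)
  exo <- tiny_c(life_on_arrival = q)
  endo <- tiny_c(life_on_arrival = matrix(q, nrow = 4, ncol = 3, byrow = TRUE))
  expect_equal(exo$arrival_pmf, endo$arrival_pmf, tolerance = 1e-14)
  set.seed(4)
  V <- rnorm(exo$n_states)
  expect_equal(sweep_values(V, exo), sweep_values(V, endo), tolerance = 1e-14)
  se <- value_iteration(exo, vi_config(tolerance = 1e-3))
  sn <- value_iteration(endo, vi_config(tolerance = 1e-3))
  expect_identical(se$policy$action_index, sn$policy$action_index)
})

test_that("the periodic span test needs a full week of history", {
  Vs <- lapply(1:7, function(i) rep(i, 3))
  expect_false(convergence_periodic_span(Vs, tol = 10))  # insufficient history
  Vs8 <- c(Vs, list(rep(1, 3) + 5))   # V_8 = V_1 + 5 uniformly
  expect_true(convergence_periodic_span(Vs8, tol = 1e-4))
  Vs8b <- c(Vs, list(c(6, 6, 6 + 2e-4)))
  expect_false(convergence_periodic_span(Vs8b, tol = 1e-4))
})

test_that("the solved weekly policy is stable for a further week of sweeps", {
  m <- tiny_c(m = 3, A_max = 3, D_max = 6)
  sol <- value_iteration(m, vi_config(tolerance = 1e-4))
  expect_true(sol$converged)
  V <- sol$values
  for (i in 1:7) V <- sweep_values(V, m)
  expect_identical(extract_policy(V, m)$action_index,
                   sol$policy$action_index)
})

test_that("the periodic backend equals the reference backup", {
  m <- tiny_c()
  set.seed(8)
  V <- rnorm(m$n_states)
  got <- sweep_values(V, m)
  idx <- sample(m$n_states, 30)
  ref <- vapply(idx, function(i) bellman_backup(m$states$states[i, ], V, m),
                numeric(1))
  expect_equal(got[idx], ref, tolerance = 1e-10)
})

test_that("outcome probabilities normalise for sampled state-action pairs", {
  m <- tiny_c()
  expect_true(validate_model(m, n_check = 500))
})
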