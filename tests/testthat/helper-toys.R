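# Toy MDPs and independent oracles shared across the test files.
# The oracles deliberately use naive loops / linear algebra, independent of
# the solver's compiled paths.

# A fixed 3-state, 2-action, 2-outcome MDP with hand-chosen probabilities,
# rewards and deterministic transitions.
toy_mdp <- function(gamma = 0.9) {
  nxt <- array(c(  # [state, action, outcome] -> next state (1-based)
    2, 3, 1,   3, 1, 2,    # outcome 1, actions 1..2
    1, 1, 2,   2, 3, 3),   # outcome 2
    dim = c(3, 2, 2))
  rew <- array(c(
    1.0, -0.5, 2.0,   0.2, 1.5, -1.0,
    0.5,  0.0, 1.0,  -0.2, 0.8,  2.5),
    dim = c(3, 2, 2))
  p1 <- array(c(  # probability of outcome 1 given (state, action)
    0.3, 0.6, 0.5,
    0.8, 0.1, 0.4), dim = c(3, 2))
  states <- matrix(0:2, ncol = 1)
  mdp_model(
    states = states, actions = matrix(0:1, ncol = 1),
    outcomes = matrix(0:1, ncol = 1),
    transition = function(s, a, o) {
      list(reward = rew[s + 1, a + 1, o + 1],
           next_state = nxt[s + 1, a + 1, o + 1] - 1L)
    },
    outcome_prob = function(s, a) c(p1[s + 1, a + 1], 1 - p1[s + 1, a + 1]),
    gamma = gamma, name = "toy 3x2x2")
}

# Naive triple-loop Bellman backup: the brute-force oracle.
oracle_backup <- function(model, V) {
  out <- numeric(model$n_states)
  for (i in seq_len(model$n_states)) {
    s <- model$states$states[i, ]
    best <- -Inf
    for (a in seq_len(model$n_actions)) {
      act <- model$actions[a, ]
      p <- model$outcome_prob(s, act)
      tot <- 0
      for (o in seq_along(p)) {
        if (p[o] == 0) next
        tr <- model$transition(s, act, model$outcomes[o, ])
        j <- model$states$index_of(tr$next_state)
        tot <- tot + p[o] * (tr$reward + model$gamma * V[j])
      }
      best <- max(best, tot)
    }
    out[i] <- best
  }
  out
}

# Exhaustive policy enumeration: evaluate every deterministic policy by a
# linear solve, return the optimal value function and one optimal policy.
oracle_policy_enumeration <- function(model) {
  nS <- model$n_states; nA <- model$n_actions
  combos <- as.matrix(expand.grid(rep(list(seq_len(nA)), nS)))
  bestV <- rep(-Inf, nS); bestPi <- NULL
  for (k in seq_len(nrow(combos))) {
    pol <- combos[k, ]
    P <- matrix(0, nS, nS); r <- numeric(nS)
    for (i in seq_len(nS)) {
      s <- model$states$states[i, ]
      act <- model$actions[pol[i], ]
      p <- model$outcome_prob(s, act)
      for (o in seq_along(p)) {
        if (p[o] == 0) next
        tr <- model$transition(s, act, model$outcomes[o, ])
        j <- model$states$index_of(tr$next_state)
        P[i, j] <- P[i, j] + p[o]
        r[i] <- r[i] + p[o] * tr$reward
      }
    }
    V <- solve(diag(nS) - model$gamma * P, r)
    if (sum(V) > sum(bestV) + 1e-12) { bestV <- V; bestPi <- pol }
  }
  list(values = bestV, policy = bestPi)
}

# Single absorbing state with reward r each step: V* = r / (1 - gamma).
self_loop_mdp <- function(r = 1, gamma = 0.5) {
  mdp_model(states = matrix(0L), actions = matrix(0L),
            outcomes = matrix(0L),
            transition = function(s, a, o) list(reward = r, next_state = 0L),
            outcome_prob = function(s, a) 1,
            gamma = gamma, name = "self-loop")
}

# Small scenario builders used by several files.
tiny_a <- function(issuing = "fifo", m = 2, L = 1, gamma = 0.9) {
  scenario_a(m = m, L = L, A_max = 3, demand_mean = 1, demand_cv = 0.7,
             D_max = 12, C_h = 1, C_v = 3, C_s = 5, C_w = 7,
             gamma = gamma, issuing = issuing)
}

tiny_b <- function(rho = 0.5, m = 2, A_max_a = 2, A_max_b = 2,
                   mu_a = 1, mu_b = 0.8) {
  scenario_b(m = m, mu_a = mu_a, mu_b = mu_b, rho = rho,
             A_max_a = A_max_a, A_max_b = A_max_b)
}

tiny_c <- function(m = 3, A_max = 3, D_max = 6, ...) {
  scenario_c(m = m, A_max = A_max, D_max = D_max, ...)
}
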