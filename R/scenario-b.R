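## Two substitutable perishable products, Poisson demand, revenue reward.
##
## The stochastic element of a day is the issued-unit pair (h_a, h_b): daily
## demand for each product and the per-customer substitution draws are
## marginalised out, so the transition is deterministic given (state, action,
## issued pair). This keeps the outcome space at (m*A_max_a+1)(m*A_max_b+1)
## instead of a demand-by-demand-by-binomial product.

# Truncated Poisson grid: support 0..k where the cumulative mass first
# exceeds 1 - eps, residual tail lumped into the last cell.
poisson_grid <- function(mu, eps = 1e-10) {
  if (mu == 0) return(1)
  k <- max(1L, as.integer(stats::qpois(1 - eps, mu)))
  p <- stats::dpois(0:k, mu)
  p[k + 1] <- 1 - stats::ppois(k - 1, mu)
  p
}

# P(h_a = j | substitution demand e, total stock I_a) marginalised over d_a:
# h_a = min(d_a, I_a) + min(e, I_a - min(d_a, I_a)).
# Returns M[e + 1, j + 1], e in 0..emax, j in 0..I_a.
issued_a_given_extra <- function(pa, I_a, emax) {
  nd <- length(pa) - 1L
  M <- matrix(0, emax + 1L, I_a + 1L)
  for (e in 0:emax) {
    own <- pmin(0:nd, I_a)
    h <- own + pmin(e, I_a - own)
    M[e + 1L, ] <- vapply(0:I_a, function(j) sum(pa[h == j]), numeric(1))
  }
  M
}

#' Distribution of the issued-unit pair for the two-product model
#'
#' Computes \code{P(h_a, h_b | I_a, I_b)} for every pair of total stock levels:
#' product B demand is filled first from product B stock
#' (\code{h_b = min(d_b, I_b)}); each of the \code{d_b - h_b} customers with
#' unmet product B demand accepts product A instead independently with
#' probability \code{rho}; product A demand is filled from product A stock and
#' the accepted substitution demand is then filled from whatever product A
#' stock remains, all FIFO. Demands are independent Poissons truncated where
#' their cumulative mass reaches \code{1 - tail_eps} (residual lumped at the
#' truncation point). The distribution depends on the state only through the
#' stock totals, not the age split, and not on the order (which arrives
#' overnight).
#'
#' @param mu_a,mu_b mean daily Poisson demand per product.
#' @param rho substitution-acceptance probability in \code{[0, 1]}.
#' @param I_max_a,I_max_b largest total stock to tabulate
#'   (\code{m * A_max_p}).
#' @param tail_eps truncation tail mass for the marginalisation grids.
#' @return a 4-d array \code{P[h_a + 1, h_b + 1, I_a + 1, I_b + 1]}; each
#'   \code{[, , I_a + 1, I_b + 1]} slice sums to one.
#' @export
issued_pmf_table <- function(mu_a, mu_b, rho, I_max_a, I_max_b,
                             tail_eps = 1e-10) {
  stopifnot(rho >= 0, rho <= 1, mu_a >= 0, mu_b >= 0)
  pa <- poisson_grid(mu_a, tail_eps)
  pb <- poisson_grid(mu_b, tail_eps)
  ndb <- length(pb) - 1L
  P <- array(0, dim = c(I_max_a + 1L, I_max_b + 1L,
                        I_max_a + 1L, I_max_b + 1L))
  for (I_a in 0:I_max_a) {
    emax <- max(0L, ndb)  # substitution demand can never exceed total B demand
    M <- issued_a_given_extra(pa, I_a, emax)
    for (I_b in 0:I_max_b) {
      # q_e[k]: P(h_b = I_b and k customers accept substitution)
      db_over <- if (I_b <= ndb) I_b:ndb else integer(0)
      if (length(db_over)) {
        q_e <- vapply(0:emax, function(k) {
          sum(pb[db_over + 1L] * stats::dbinom(k, db_over - I_b, rho))
        }, numeric(1))
      } else q_e <- numeric(emax + 1L)
      # h_b < I_b: exactly d_b = h_b and no substitution demand
      if (I_b > 0) {
        for (j in 0:(I_b - 1L)) {
          if (j <= ndb) P[, j + 1L, I_a + 1L, I_b + 1L] <-
              c(pb[j + 1L] * M[1L, ], rep(0, I_max_a - I_a))
        }
      }
      P[, I_b + 1L, I_a + 1L, I_b + 1L] <-
        c(as.numeric(q_e %*% M), rep(0, I_max_a - I_a))
    }
  }
  P
}

#' Issued-outcome distribution at one state
#'
#' The probability of every \code{(h_a, h_b)} outcome of the two-product model
#' at a given state; a convenience wrapper over [issued_pmf_table()] evaluated
#' at the state's stock totals (the action does not affect the distribution:
#' orders arrive overnight).
#'
#' @param state state tuple (product A stock by remaining life, oldest first,
#'   then product B).
#' @param action order pair (ignored; kept for the solver's uniform interface).
#' @param params parameter list from [scenario_b()] (the model's
#'   \code{$params}).
#' @return numeric matrix \code{[h_a + 1, h_b + 1]} summing to one.
#' @export
issued_pmf <- function(state, action, params) {
  m <- params$m
  I_a <- sum(state[seq_len(m)]); I_b <- sum(state[m + seq_len(m)])
  tab <- issued_pmf_table(params$mu_a, params$mu_b, params$rho,
                          m * params$A_max_a, m * params$A_max_b,
                          params$tail_eps)
  tab[, , I_a + 1L, I_b + 1L]
}

# FIFO deduction of h units from a stock-by-age vector (oldest first).
# Vectorised over rows of `stock`.
deduct_fifo <- function(stock, h) {
  left <- h
  for (k in seq_len(ncol(stock))) {
    take <- pmin(stock[, k], left)
    stock[, k] <- stock[, k] - take
    left <- left - take
  }
  if (any(left > 0)) stop("issued quantity exceeds available stock")
  stock
}

#' Two-product perishable inventory model with substitution
#'
#' Builds the substitution scenario as a solvable MDP: two perishable products
#' with common useful life \code{m}, daily orders \code{(a_a, a_b)} delivered
#' overnight (lead time one), independent Poisson demands, FIFO issuing, and
#' down-substitution: customers with unmet product B demand accept product A
#' with probability \code{rho}. The state is both products' stock split by
#' remaining useful life; the stochastic outcome is the issued pair
#' \code{(h_a, h_b)}. The daily reward is sales revenue minus variable order
#' cost, \code{C_r_a h_a + C_r_b h_b - C_v_a a_a - C_v_b a_b}; the problem is
#' undiscounted, the value function is initialised at the expected one-day
#' sales revenue of the state, and the solver stops on the span test (all
#' state values changing by the same amount per sweep).
#'
#' @param m maximum useful life in periods (>= 2).
#' @param mu_a,mu_b mean daily Poisson demand.
#' @param rho substitution-acceptance probability.
#' @param A_max_a,A_max_b maximum daily order per product.
#' @param C_r_a,C_r_b revenue per unit sold.
#' @param C_v_a,C_v_b variable order cost per unit.
#' @param tail_eps Poisson truncation tail for the outcome marginalisation.
#' @param max_enumerate memory guard on the state count.
#' @return a \code{perish_mdp}.
#' @export
scenario_b <- function(m, mu_a, mu_b, rho, A_max_a, A_max_b,
                       C_r_a = 1, C_r_b = 1, C_v_a = 0.5, C_v_b = 0.5,
                       tail_eps = 1e-10, max_enumerate = 5e6) {
  m <- as.integer(m); A_max_a <- as.integer(A_max_a)
  A_max_b <- as.integer(A_max_b)
  stopifnot(m >= 2, rho >= 0, rho <= 1, A_max_a >= 0, A_max_b >= 0,
            min(C_r_a, C_r_b, C_v_a, C_v_b) >= 0)
  params <- list(m = m, mu_a = mu_a, mu_b = mu_b, rho = rho,
                 A_max_a = A_max_a, A_max_b = A_max_b,
                 C_r_a = C_r_a, C_r_b = C_r_b, C_v_a = C_v_a, C_v_b = C_v_b,
                 tail_eps = tail_eps)
  Ha <- m * A_max_a; Hb <- m * A_max_b
  sizes <- list(n_states = (A_max_a + 1)^m * (A_max_b + 1)^m,
                n_actions = (A_max_a + 1) * (A_max_b + 1),
                n_outcomes = (Ha + 1) * (Hb + 1))
  name <- sprintf("two-product substitution (m=%d, rho=%g)", m, rho)
  ptab <- issued_pmf_table(mu_a, mu_b, rho, Ha, Hb, tail_eps)
  # expected issued units by stock totals (also drives the initial value)
  EHa <- apply(ptab, c(3, 4), function(sl) sum(sl * (0:Ha)))
  EHb <- apply(ptab, c(3, 4), function(sl) {
    sum(t(sl) * (0:Hb))
  })
  exp_revenue <- C_r_a * EHa + C_r_b * EHb  # [I_a + 1, I_b + 1]
  if (sizes$n_states > max_enumerate) {
    return(structure(list(name = name, params = params, sizes = sizes,
                          count_only = TRUE, gamma = 1,
                          scenario = "b", sim = sim_hooks_b(params),
                          heuristic_families = "modified_base_stock",
                          cache = new.env(parent = emptyenv())),
                     class = "perish_mdp"))
  }
  radices <- c(rep(A_max_a + 1L, m), rep(A_max_b + 1L, m))
  states <- enumerate_tuples(radices)
  a_cols <- seq_len(m); b_cols <- m + seq_len(m)
  I_a <- rowSums(states[, a_cols, drop = FALSE])
  I_b <- rowSums(states[, b_cols, drop = FALSE])
  actions <- enumerate_tuples(c(A_max_a + 1L, A_max_b + 1L))
  outcomes <- enumerate_tuples(c(Ha + 1L, Hb + 1L))

  transition <- function(state, action, outcome) {
    h_a <- outcome[1]; h_b <- outcome[2]
    sa <- state[a_cols]; sb <- state[b_cols]
    if (h_a > sum(sa) || h_b > sum(sb)) {
      stop("infeasible issued quantities for this state")
    }
    ra <- deduct_fifo(matrix(sa, 1), h_a)[1, ]
    rb <- deduct_fifo(matrix(sb, 1), h_b)[1, ]
    list(reward = C_r_a * h_a + C_r_b * h_b -
           C_v_a * action[1] - C_v_b * action[2],
         next_state = c(ra[-1], action[1], rb[-1], action[2]))
  }
  outcome_prob <- function(state, action) {
    as.numeric(t(ptab[, , sum(state[a_cols]) + 1L, sum(state[b_cols]) + 1L]))
    # t(): outcomes enumerate h_b fastest, the table has h_a on rows
  }

  backend_builder <- function(model) {
    nS <- model$n_states; nAct <- nrow(actions)
    # value reshaped as [aged-stock block, fresh-arrivals block]: the next
    # state is (aged stock, order pair), so one sparse matrix of aged-stock
    # probabilities serves every action simultaneously.
    base_rad <- c(rep(A_max_a + 1L, m - 1L), rep(A_max_b + 1L, m - 1L))
    nB <- prod(base_rad)
    base_states <- enumerate_tuples(base_rad)
    pvec <- integer(nS)
    for (j in seq_len(nAct)) {
      tup <- cbind(base_states[, seq_len(m - 1L), drop = FALSE],
                   actions[j, 1],
                   base_states[, m - 1L + seq_len(m - 1L), drop = FALSE],
                   actions[j, 2])
      pvec[(j - 1L) * nB + seq_len(nB)] <- tuple_index(tup, radices)
    }
    trip_i <- vector("list", nrow(outcomes))
    trip_j <- vector("list", nrow(outcomes))
    trip_x <- vector("list", nrow(outcomes))
    for (o in seq_len(nrow(outcomes))) {
      h_a <- outcomes[o, 1]; h_b <- outcomes[o, 2]
      keep <- which(I_a >= h_a & I_b >= h_b)
      if (!length(keep)) next
      p <- ptab[cbind(h_a + 1L, h_b + 1L, I_a[keep] + 1L, I_b[keep] + 1L)]
      pos <- p > 0
      keep <- keep[pos]; p <- p[pos]
      if (!length(keep)) next
      ra <- deduct_fifo(states[keep, a_cols, drop = FALSE], h_a)
      rb <- deduct_fifo(states[keep, b_cols, drop = FALSE], h_b)
      aged <- cbind(ra[, -1, drop = FALSE], rb[, -1, drop = FALSE])
      trip_i[[o]] <- keep
      trip_j[[o]] <- tuple_index(aged, base_rad)
      trip_x[[o]] <- p
    }
    G <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(nS, nB))
    esale <- exp_revenue[cbind(I_a + 1L, I_b + 1L)]
    order_cost <- C_v_a * actions[, 1] + C_v_b * actions[, 2]
    list(
      backup_rows = function(V, rows) {
        Vmat <- matrix(V[pvec], nB, nAct)
        EV <- as.matrix(G[rows, , drop = FALSE] %*% Vmat)
        (esale[rows] + EV) - rep(order_cost, each = length(rows))
      }
    )
  }

  mdp_model(
    states = state_space(states, radices), actions = actions,
    outcomes = outcomes, transition = transition,
    outcome_prob = outcome_prob, gamma = 1,
    initial_value = function(model) exp_revenue[cbind(I_a + 1L, I_b + 1L)],
    convergence = function(V_history, tol) {
      n <- length(V_history)
      n >= 2 && convergence_span(V_history[[n - 1]], V_history[[n]], tol)
    },
    backend_builder = backend_builder,
    name = name, params = params, scenario = "b",
    sim = sim_hooks_b(params), heuristic_families = "modified_base_stock"
  )
}

#' Expected one-day sales revenue (two-product initial value)
#'
#' @param state state tuple of a [scenario_b()] model.
#' @param params the model's \code{$params}.
#' @return expected revenue \code{E[C_r_a h_a + C_r_b h_b]} at the state's
#'   stock totals.
#' @export
initial_value_b <- function(state, params) {
  pm <- issued_pmf(state, c(0, 0), params)
  Ha <- params$m * params$A_max_a; Hb <- params$m * params$A_max_b
  params$C_r_a * sum(pm * (0:Ha)) + params$C_r_b * sum(t(pm) * (0:Hb))
}

# Simulator hooks: three uniforms per rollout-day (demand a, demand b,
# substitution), consumed whether or not substitution demand arises so the
# stream is policy-independent (common random numbers across policies).
# Demand is sampled from the same truncated Poisson grids the solver
# marginalises over; inverse-CDF tables keep the per-day cost low.
sim_hooks_b <- function(params) {
  m <- params$m
  radices <- c(rep(params$A_max_a + 1L, m), rep(params$A_max_b + 1L, m))
  cum_a <- cumsum(poisson_grid(params$mu_a, params$tail_eps))
  cum_b <- cumsum(poisson_grid(params$mu_b, params$tail_eps))
  ndb <- length(cum_b) - 1L
  # binomial CDF table over substitution trials: row s+1 holds
  # P(Binom(s, rho) <= j), j = 0..ndb-1
  Fsub <- if (ndb > 0) {
    t(vapply(0:ndb, function(s) stats::pbinom(0:(ndb - 1L), s, params$rho),
             numeric(ndb)))
  } else matrix(1, 1, 1)
  list(
    init = function(n) list(stock_a = matrix(0L, n, m),
                            stock_b = matrix(0L, n, m)),
    draw = function(n) list(u_a = stats::runif(n), u_b = stats::runif(n),
                            u_s = stats::runif(n)),
    step = function(st, action, draws) {
      n <- nrow(st$stock_a)
      a_a <- rep_len(action[, 1], n); a_b <- rep_len(action[, 2], n)
      d_a <- findInterval(draws$u_a, cum_a)
      d_b <- findInterval(draws$u_b, cum_b)
      I_a <- rowSums(st$stock_a); I_b <- rowSums(st$stock_b)
      h_b <- pmin(d_b, I_b)
      unmet_b <- d_b - h_b
      # inverse-CDF lookup: number of CDF thresholds strictly below u
      accept <- if (ndb > 0) {
        rowSums(draws$u_s > Fsub[unmet_b + 1L, , drop = FALSE])
      } else rep(0L, n)
      own_a <- pmin(d_a, I_a)
      h_a <- own_a + pmin(accept, I_a - own_a)
      ra <- deduct_fifo(st$stock_a, h_a)
      rb <- deduct_fifo(st$stock_b, h_b)
      expired <- ra[, 1] + rb[, 1]
      holding <- rowSums(ra) + rowSums(rb) - expired
      reward <- params$C_r_a * h_a + params$C_r_b * h_b -
        params$C_v_a * a_a - params$C_v_b * a_b
      list(state = list(stock_a = cbind(ra[, -1, drop = FALSE], a_a),
                        stock_b = cbind(rb[, -1, drop = FALSE], a_b)),
           reward = reward,
           info = list(demand = d_a + d_b, met = h_a + h_b,
                       expired = expired, received = a_a + a_b,
                       holding = holding, ordered = a_a + a_b))
    },
    features = function(st) list(
      I_a = rowSums(st$stock_a), I_b = rowSums(st$stock_b),
      X1_a = st$stock_a[, 1], X1_b = st$stock_b[, 1],
      mu_a = params$mu_a, mu_b = params$mu_b),
    state_index = function(st) tuple_index(cbind(st$stock_a, st$stock_b),
                                           radices),
    clip_action = function(a) cbind(
      pmax(0L, pmin(as.integer(round(a[, 1])), params$A_max_a)),
      pmax(0L, pmin(as.integer(round(a[, 2])), params$A_max_b)))
  )
}

#' Closed-form space sizes for the two-product scenario
#'
#' @param m,A_max_a,A_max_b scenario dimensions.
#' @return list with state, action and outcome counts.
#' @export
scenario_b_sizes <- function(m, A_max_a, A_max_b) {
  list(n_states = (A_max_a + 1)^m * (A_max_b + 1)^m,
       n_actions = (A_max_a + 1) * (A_max_b + 1),
       n_outcomes = (m * A_max_a + 1) * (m * A_max_b + 1))
}
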