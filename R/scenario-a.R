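#' Integerised truncated gamma demand distribution
#'
#' Daily demand is gamma distributed with mean \code{mean} and coefficient of
#' variation \code{cv} (sd/mean), rounded to the nearest integer and truncated
#' at \code{D_max}. Rounding uses half-open intervals: demand \code{d} collects
#' the gamma mass on \code{[d - 1/2, d + 1/2)}, with \code{d = 0} taking
#' \code{[0, 1/2)} and the entire upper tail beyond \code{D_max - 1/2} lumped
#' into \code{D_max}, so the pmf sums to one exactly. \code{D_max} should be
#' far above \code{mean + 5 sd} so the lump is negligible.
#'
#' @param mean,cv gamma mean (> 0) and coefficient of variation (> 0).
#' @param D_max truncation bound (integer).
#' @return numeric vector of probabilities over demand \code{0..D_max}.
#' @export
#' @examples
#' p <- demand_pmf_gamma(4, 0.5, 100)
#' sum(p)                       # exactly 1
#' sum(p * 0:100)               # close to 4
demand_pmf_gamma <- function(mean, cv, D_max) {
  if (mean <= 0 || cv <= 0) stop("demand mean and cv must be positive")
  D_max <- as.integer(D_max)
  stopifnot(D_max >= 1)
  shape <- 1 / cv^2
  scale <- mean * cv^2
  cuts <- pgamma(seq_len(D_max) - 0.5, shape = shape, scale = scale)
  pmf <- c(cuts[1], diff(cuts), 1 - cuts[D_max])
  pmf
}

# Vectorised one-day dynamics shared by the solver table builder and the
# simulator. stock: [n x m] oldest -> freshest; transit: [n x (L-1)];
# action, demand: length-n (or scalar) order and demand vectors.
step_a <- function(stock, transit, action, demand, params) {
  m <- params$m; L <- params$L
  n <- nrow(stock)
  action <- rep_len(action, n); demand <- rep_len(demand, n)
  issue_order <- if (params$issuing == "fifo") seq_len(m) else rev(seq_len(m))
  rem <- stock
  left <- demand
  for (k in issue_order) {
    take <- pmin(rem[, k], left)
    rem[, k] <- rem[, k] - take
    left <- left - take
  }
  shortage <- left
  expired <- rem[, 1]
  holding <- rowSums(rem) - expired  # survivors only; arrivals not yet charged
  arrive <- if (L == 1L) action else transit[, 1]
  next_stock <- cbind(rem[, -1, drop = FALSE], arrive, deparse.level = 0)
  next_transit <- if (L == 1L) transit else
    cbind(transit[, -1, drop = FALSE], action, deparse.level = 0)
  reward <- -(params$C_h * holding + params$C_v * action +
                params$C_s * shortage + params$C_w * expired)
  list(stock = next_stock, transit = next_transit, reward = reward,
       info = list(demand = demand, met = demand - shortage,
                   expired = expired, received = arrive,
                   holding = holding, ordered = action))
}

#' Single-product perishable inventory model with delivery lead time
#'
#' Builds the lead-time scenario as a solvable MDP: one perishable product
#' with fixed useful life \code{m} periods, periodic (daily) review, orders
#' capped at \code{A_max} and delivered after \code{L} periods (so in-transit
#' stock is part of the state when \code{L > 1}), integerised truncated gamma
#' demand, lost sales, and FIFO or LIFO issuing. The state is the stock on
#' hand split by remaining useful life (oldest to freshest) followed by the
#' in-transit orders (next due first); all components lie in
#' \code{0..A_max}, giving \code{(A_max+1)^(m+L-1)} states. The daily reward is
#' \code{-(C_h * holding + C_v * order + C_s * shortage + C_w * expired)},
#' where holding counts end-of-day surviving stock (expired units and the
#' order arriving overnight are not charged). The solver stops on the standard
#' discounted sup-norm test.
#'
#' @param m maximum useful life in periods (>= 2).
#' @param L delivery lead time in periods (>= 1).
#' @param A_max maximum daily order quantity (also the per-age-class bound).
#' @param demand_mean,demand_cv gamma demand mean and coefficient of variation.
#' @param D_max demand truncation bound; must be well above
#'   \code{mean + 5 sd}.
#' @param C_h,C_v,C_s,C_w per-unit holding, variable order, shortage and
#'   wastage costs (>= 0).
#' @param gamma discount factor in (0, 1).
#' @param issuing \code{"fifo"} (oldest first) or \code{"lifo"} (freshest
#'   first).
#' @param max_enumerate memory guard: if the state count exceeds this the
#'   model is returned in count-only form (sizes and simulator available,
#'   value iteration refused).
#' @return a \code{perish_mdp} (see [mdp_model()]).
#' @seealso [value_iteration()], [simulate_policy()], [base_stock_policy()]
#' @export
scenario_a <- function(m, L, A_max, demand_mean, demand_cv, D_max,
                       C_h, C_v, C_s, C_w, gamma, issuing = c("fifo", "lifo"),
                       max_enumerate = 5e6) {
  issuing <- match.arg(tolower(issuing), c("fifo", "lifo"))
  m <- as.integer(m); L <- as.integer(L); A_max <- as.integer(A_max)
  D_max <- as.integer(D_max)
  stopifnot(m >= 2, L >= 1, A_max >= 1, min(C_h, C_v, C_s, C_w) >= 0,
            gamma > 0, gamma < 1)
  sd <- demand_mean * demand_cv
  if (D_max < demand_mean + 5 * sd) {
    stop("D_max must be at least demand_mean + 5 sd; increase the truncation bound")
  }
  params <- list(m = m, L = L, A_max = A_max, demand_mean = demand_mean,
                 demand_cv = demand_cv, D_max = D_max, C_h = C_h, C_v = C_v,
                 C_s = C_s, C_w = C_w, gamma = gamma, issuing = issuing)
  pmf <- demand_pmf_gamma(demand_mean, demand_cv, D_max)
  k <- m + L - 1L
  radices <- rep(A_max + 1L, k)
  sizes <- list(n_states = (A_max + 1)^k, n_actions = A_max + 1L,
                n_outcomes = D_max + 1L)
  name <- sprintf("perishable inventory, lead time L=%d (m=%d, %s)", L, m,
                  toupper(issuing))
  if (sizes$n_states > max_enumerate) {
    return(structure(list(name = name, params = params, sizes = sizes,
                          demand_pmf = pmf, count_only = TRUE, gamma = gamma,
                          scenario = "a", sim = sim_hooks_a(params, pmf),
                          heuristic_families = "base_stock",
                          cache = new.env(parent = emptyenv())),
                     class = "perish_mdp"))
  }
  states <- enumerate_tuples(radices)
  split_state <- function(s) {
    list(stock = s[seq_len(m)],
         transit = if (L > 1) s[m + seq_len(L - 1L)] else integer(0))
  }
  transition <- function(state, action, outcome) {
    a <- action[1]; d <- outcome[1]
    if (a < 0 || a > A_max) stop("action out of [0, A_max]")
    if (d < 0 || d > D_max) stop("demand out of [0, D_max]")
    p <- split_state(state)
    st <- step_a(matrix(p$stock, 1), matrix(p$transit, 1), a, d, params)
    list(reward = st$reward[1],
         next_state = c(st$stock[1, ], if (L > 1) st$transit[1, ]))
  }
  transition_table <- function(model) {
    nS <- model$n_states
    stock <- states[, seq_len(m), drop = FALSE]
    transit <- states[, m + seq_len(L - 1L), drop = FALSE]
    nA <- A_max + 1L; nO <- D_max + 1L
    cells <- as.numeric(nS) * nA * nO
    nxt <- integer(cells); rew <- numeric(cells)
    for (o in seq_len(nO)) {
      for (a in seq_len(nA)) {
        st <- step_a(stock, transit, a - 1L, o - 1L, params)
        nxt_states <- cbind(st$stock, st$transit)
        # layout: outcome fastest, then action, then state
        pos <- o + (a - 1L) * nO + (seq_len(nS) - 1L) * (nO * nA)
        nxt[pos] <- tuple_index(nxt_states, radices) - 1L
        rew[pos] <- st$reward
      }
    }
    list(nxt = nxt, rew = rew, prob = pmf, prob_mode = 0L)
  }
  mdp_model(
    states = state_space(states, radices),
    actions = matrix(0:A_max, ncol = 1),
    outcomes = matrix(0:D_max, ncol = 1),
    transition = transition,
    outcome_prob = function(state, action) pmf,
    gamma = gamma,
    convergence = function(V_history, tol) {
      n <- length(V_history)
      n >= 2 && convergence_sup_norm(V_history[[n - 1]], V_history[[n]], tol)
    },
    transition_table = transition_table,
    name = name, params = params, scenario = "a", demand_pmf = pmf,
    sim = sim_hooks_a(params, pmf), heuristic_families = "base_stock"
  )
}

# Simulator hooks: one uniform draw per rollout-day (demand).
sim_hooks_a <- function(params, pmf) {
  m <- params$m; L <- params$L
  cum <- cumsum(pmf)
  radices <- rep(params$A_max + 1L, m + L - 1L)
  list(
    n_draws = function(n) n,  # uniforms consumed per day (policy-independent)
    init = function(n) list(stock = matrix(0L, n, m),
                            transit = matrix(0L, n, max(L - 1L, 0L))),
    draw = function(n) list(u = stats::runif(n)),
    step = function(st, action, draws) {
      demand <- findInterval(draws$u, cum)
      out <- step_a(st$stock, st$transit, action, demand, params)
      list(state = list(stock = out$stock, transit = out$transit),
           reward = out$reward, info = out$info)
    },
    features = function(st) list(
      I = rowSums(st$stock) + if (ncol(st$transit)) rowSums(st$transit) else 0,
      X1 = st$stock[, 1], weekday = NULL),
    state_index = function(st) tuple_index(cbind(st$stock, st$transit), radices),
    clip_action = function(a) pmax(0L, pmin(as.integer(round(a)), params$A_max))
  )
}

#' Closed-form space sizes for the lead-time scenario
#'
#' @param m,L,A_max,D_max scenario dimensions (see [scenario_a()]).
#' @return list with \code{n_states = (A_max+1)^(m+L-1)},
#'   \code{n_actions = A_max+1}, \code{n_outcomes = D_max+1}.
#' @export
scenario_a_sizes <- function(m, L, A_max, D_max) {
  list(n_states = (A_max + 1)^(m + L - 1), n_actions = A_max + 1,
       n_outcomes = D_max + 1)
}
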