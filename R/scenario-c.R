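## Hospital platelet bank: weekday-periodic truncated negative-binomial
## demand, instant delivery with a multinomial remaining-shelf-life profile
## (optionally depending on the order quantity), OUFO issuing, a per-age-class
## capacity cap of A_max, and a fixed cost per non-zero order.

#' Weekday demand calibration for the platelet-bank model
#'
#' Negative-binomial (size, mean) pairs for Monday through Sunday used as the
#' default demand calibration of [scenario_c()]: hospital platelet demand is
#' strongly weekday-patterned, with a pronounced Saturday trough.
#'
#' @return a 7 x 2 matrix with columns \code{size} and \code{mean}; row
#'   \code{tau + 1} is weekday \code{tau} (0 = Monday).
#' @export
platelet_weekday_demand <- function() {
  m <- cbind(size = c(3.5, 11.0, 7.2, 11.1, 5.9, 5.5, 2.2),
             mean = c(5.7, 6.9, 6.5, 6.2, 5.8, 3.3, 6.1))
  rownames(m) <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  m
}

#' Default remaining-shelf-life-on-arrival distributions (synthetic)
#'
#' A synthetic calibration of the shelf life of platelet units at delivery,
#' used as the package default when no distribution is supplied. In the
#' exogenous form units arrive mostly fresh (probability of remaining life
#' \code{k} proportional to \code{k^2}); in the endogenous form larger orders
#' are filled with progressively older stock, modelled as a mixture of the
#' exogenous profile and its age-reversed counterpart with mixing weight
#' \code{a / (2 A_max)}. These defaults set a realistic shape, not a fit to
#' any particular blood service's records.
#'
#' @param m maximum useful life in days.
#' @param type \code{"exogenous"} (one pmf) or \code{"endogenous"} (one pmf
#'   per order quantity).
#' @param A_max order cap (rows of the endogenous table are orders
#'   \code{0..A_max}).
#' @return for \code{"exogenous"} a probability vector over remaining life
#'   \code{1..m}; for \code{"endogenous"} an \code{(A_max + 1) x m} matrix.
#' @export
platelet_life_on_arrival <- function(m, type = c("exogenous", "endogenous"),
                                     A_max = 20) {
  type <- match.arg(type)
  fresh <- (seq_len(m))^2 / sum((seq_len(m))^2)
  if (type == "exogenous") return(fresh)
  old <- rev(fresh)
  t(vapply(0:A_max, function(a) {
    lam <- a / (2 * A_max)
    (1 - lam) * fresh + lam * old
  }, numeric(m)))
}

#' Truncated negative-binomial weekday demand pmf
#'
#' @param weekday integer in \code{0..6} (0 = Monday).
#' @param params parameter list of a [scenario_c()] model (the model's
#'   \code{$params}), carrying \code{weekday_demand} and \code{D_max}.
#' @return probabilities over demand \code{0..D_max}: negative-binomial mass
#'   with the upper tail lumped into \code{D_max}, summing to one exactly.
#' @export
demand_pmf_weekday <- function(weekday, params) {
  if (!(weekday %in% 0:6)) stop("weekday must be an integer in 0..6")
  wd <- params$weekday_demand
  D_max <- params$D_max
  size <- wd[weekday + 1L, 1]; mu <- wd[weekday + 1L, 2]
  p <- stats::dnbinom(0:D_max, size = size, mu = mu)
  p[D_max + 1L] <- 1 - stats::pnbinom(D_max - 1L, size = size, mu = mu)
  p
}

# All arrival-age profiles y (y_k = units arriving with k days of remaining
# life) with sum(y) <= A_max: the outcome-space slice of Eq-style enumeration.
enumerate_profiles <- function(m, A_max) {
  g <- enumerate_tuples(rep(A_max + 1L, m))
  g[rowSums(g) <= A_max, , drop = FALSE]
}

#' Multinomial probabilities of arrival-age profiles
#'
#' Probability of each profile \code{y} (rows of \code{profiles}) when
#' \code{action} units are ordered and each unit's remaining life is drawn
#' independently from \code{life_pmf}: multinomial(action, life_pmf) on
#' profiles with \code{sum(y) = action}, zero elsewhere.
#'
#' @param action order quantity.
#' @param life_pmf probability vector over remaining life \code{1..m}.
#' @param profiles integer matrix of profiles (see Details of [scenario_c()]);
#'   defaults to all profiles with \code{sum <= A_max = action}.
#' @return probability vector over the rows of \code{profiles}.
#' @export
arrival_profile_pmf <- function(action, life_pmf, profiles = NULL) {
  m <- length(life_pmf)
  stopifnot(abs(sum(life_pmf) - 1) < 1e-8, all(life_pmf >= 0))
  if (is.null(profiles)) profiles <- enumerate_profiles(m, action)
  tot <- rowSums(profiles)
  lp <- rep(-Inf, nrow(profiles))
  ok <- tot == action
  if (any(ok)) {
    logq <- ifelse(life_pmf > 0, log(life_pmf), -Inf)
    yl <- profiles[ok, , drop = FALSE]
    contrib <- sweep(yl, 2, logq, `*`)
    contrib[yl == 0] <- 0  # 0 * log 0 = 0
    lp[ok] <- lgamma(action + 1) - rowSums(lgamma(yl + 1)) + rowSums(contrib)
  }
  p <- exp(lp)
  p[!ok] <- 0
  p
}

# Vectorised one-day dynamics: stock [n x (m-1)] by remaining life 1..m-1,
# arrivals Y [n x m], demand d (length n). Returns remaining stock after
# OUFO issuing plus the cost components.
step_c_core <- function(stock, Y, d, params) {
  m <- params$m; A_max <- params$A_max
  n <- nrow(stock)
  C <- matrix(0, n, m)
  for (k in seq_len(m - 1L)) {
    C[, k] <- stock[, k] + pmin(Y[, k], A_max - stock[, k])
  }
  C[, m] <- pmin(Y[, m], A_max)
  accepted <- rowSums(C) - rowSums(stock)
  left <- d
  rem <- C
  for (k in seq_len(m)) {  # OUFO: shortest remaining life first
    take <- pmin(rem[, k], left)
    rem[, k] <- rem[, k] - take
    left <- left - take
  }
  shortage <- left
  expired <- rem[, 1]
  holding_charged <- rowSums(rem)      # expiring units are charged holding
  list(rem = rem, accepted = accepted, shortage = shortage,
       expired = expired, holding_charged = holding_charged,
       issued = d - shortage)
}

#' Platelet-bank perishable inventory model
#'
#' Builds the platelet-bank scenario as a solvable MDP: a single product with
#' maximum useful life \code{m} days, instant delivery, an independent
#' truncated negative-binomial demand distribution for each day of the week,
#' and uncertain remaining shelf life on arrival drawn from a multinomial
#' whose parameters may depend on the order quantity (endogenous uncertainty).
#' The state is the day of the week plus stock split by remaining life
#' \code{1..m-1} (end-of-day ageing means nothing observed can have life
#' \code{m}); each age class is capped at \code{A_max}, and delivered units
#' that would breach the cap are not accepted (rejected at no cost). Demand is
#' filled oldest-unit-first-out (OUFO). The daily reward is
#' \code{-(C_h * holding + C_s * shortage + C_w * expired + C_f * [order > 0])},
#' where holding is charged on all end-of-day units including those expiring.
#' The solver stops when the change in value over one full week is uniform
#' across states (periodic span test).
#'
#' @param m maximum useful life in days.
#' @param A_max maximum daily order; also the per-age-class stock capacity.
#' @param D_max demand truncation bound.
#' @param weekday_demand 7 x 2 matrix of negative-binomial \code{(size, mean)}
#'   rows for weekdays 0..6; defaults to [platelet_weekday_demand()].
#' @param life_on_arrival remaining-life-on-arrival distribution: a
#'   probability vector over life \code{1..m} (exogenous), an
#'   \code{(A_max + 1) x m} matrix with one row per order quantity
#'   (endogenous), or a function \code{a -> pmf}. Defaults to
#'   [platelet_life_on_arrival()].
#' @param C_h,C_s,C_w per-unit holding, shortage and wastage costs.
#' @param C_f fixed cost charged whenever a non-zero order is placed.
#' @param gamma discount factor in (0, 1).
#' @param max_enumerate memory guard on state/outcome enumeration; above it
#'   the model is count-only (sizes and simulator available, solve refused).
#' @return a \code{perish_mdp}.
#' @export
scenario_c <- function(m, A_max = 20, D_max = 20,
                       weekday_demand = platelet_weekday_demand(),
                       life_on_arrival = platelet_life_on_arrival(m, A_max = A_max),
                       C_h = 1, C_s = 20, C_w = 5, C_f = 10, gamma = 0.95,
                       max_enumerate = 5e6) {
  m <- as.integer(m); A_max <- as.integer(A_max); D_max <- as.integer(D_max)
  stopifnot(m >= 2, A_max >= 1, D_max >= 1, min(C_h, C_s, C_w, C_f) >= 0,
            gamma > 0, gamma < 1)
  weekday_demand <- as.matrix(weekday_demand)
  stopifnot(nrow(weekday_demand) == 7, ncol(weekday_demand) == 2)
  if (is.character(life_on_arrival)) {
    life_on_arrival <- platelet_life_on_arrival(m, life_on_arrival,
                                                A_max = A_max)
  }
  life_fn <- if (is.function(life_on_arrival)) {
    life_on_arrival
  } else if (is.matrix(life_on_arrival)) {
    stopifnot(nrow(life_on_arrival) == A_max + 1, ncol(life_on_arrival) == m)
    function(a) life_on_arrival[a + 1L, ]
  } else {
    stopifnot(length(life_on_arrival) == m)
    function(a) life_on_arrival
  }
  for (a in 0:A_max) {
    q <- life_fn(a)
    if (length(q) != m || any(q < 0) || abs(sum(q) - 1) > 1e-8) {
      stop("life-on-arrival pmf must be a distribution over remaining life 1..m")
    }
  }
  params <- list(m = m, A_max = A_max, D_max = D_max,
                 weekday_demand = weekday_demand, life_fn = life_fn,
                 C_h = C_h, C_s = C_s, C_w = C_w, C_f = C_f, gamma = gamma)
  pdmat <- vapply(0:6, function(tau) demand_pmf_weekday(tau, params),
                  numeric(D_max + 1L))  # [D_max+1, 7]
  sizes <- list(n_states = 7 * (A_max + 1)^(m - 1),
                n_actions = A_max + 1L,
                n_outcomes = (D_max + 1) * choose(A_max + m, m))
  name <- sprintf("platelet bank (m=%d)", m)
  n_profiles <- choose(A_max + m, m)
  if (sizes$n_states > max_enumerate || n_profiles > max_enumerate) {
    return(structure(list(name = name, params = params, sizes = sizes,
                          count_only = TRUE, gamma = gamma, scenario = "c",
                          sim = sim_hooks_c(params, pdmat),
                          heuristic_families = "weekday_sS",
                          cache = new.env(parent = emptyenv())),
                     class = "perish_mdp"))
  }
  nstock <- (A_max + 1L)^(m - 1L)
  stock_rad <- rep(A_max + 1L, m - 1L)
  radices <- c(7L, stock_rad)
  states <- enumerate_tuples(radices)  # weekday slowest: index = tau*nstock + stock
  profiles <- enumerate_profiles(m, A_max)
  nY <- nrow(profiles)
  nD <- D_max + 1L
  # outcome rows: profile-major, demand fastest (kernel layout)
  outcomes <- cbind(rep(0:D_max, times = nY),
                    profiles[rep(seq_len(nY), each = nD), , drop = FALSE])
  colnames(outcomes) <- c("d", paste0("y", seq_len(m)))
  py <- vapply(0:A_max, function(a) {
    arrival_profile_pmf(a, life_fn(a), profiles)
  }, numeric(nY))  # [nY, A_max+1]

  transition <- function(state, action, outcome) {
    tau <- state[1]; stock <- state[-1]
    d <- outcome[1]; y <- outcome[-1]
    if (action < 0 || action > A_max) stop("action out of [0, A_max]")
    cc <- step_c_core(matrix(stock, 1), matrix(y, 1), d, params)
    reward <- -(C_h * cc$holding_charged + C_s * cc$shortage +
                  C_w * cc$expired + C_f * (action > 0))
    list(reward = reward[1],
         next_state = c((tau + 1L) %% 7L, cc$rem[1, -1]))
  }
  outcome_prob <- function(state, action) {
    as.numeric(outer(pdmat[, state[1] + 1L], py[, action + 1L]))
  }

  backend_builder <- function(model) {
    cells <- as.numeric(nD) * nstock * nY
    if (cells > 2e8) {
      stop(sprintf("memory guard: periodic backup tables need %.3g cells; this instance is simulation-only", cells))
    }
    X <- enumerate_tuples(stock_rad)
    w_idx <- rev(cumprod(rev(c(stock_rad[-1], 1))))  # radix weights, m-1 digits
    Dm <- matrix(0:D_max, nstock, nD, byrow = TRUE)
    IDX <- integer(cells); COSTH <- numeric(cells)
    for (yi in seq_len(nY)) {
      y <- profiles[yi, ]
      C <- matrix(0, nstock, m)
      for (k in seq_len(m - 1L)) C[, k] <- X[, k] + pmin(y[k], A_max - X[, k])
      C[, m] <- min(y[m], A_max)
      ctot <- rowSums(C)
      cumbefore <- cbind(0, t(apply(C, 1, cumsum))[, -m, drop = FALSE])
      holding <- matrix(0, nstock, nD)
      nxt0 <- matrix(0, nstock, nD)
      expired <- NULL
      for (k in seq_len(m)) {
        issued_k <- pmin(C[, k], pmax(Dm - cumbefore[, k], 0))
        rem_k <- C[, k] - issued_k
        holding <- holding + rem_k
        if (k == 1L) expired <- rem_k
        if (k >= 2L) nxt0 <- nxt0 + rem_k * w_idx[k - 1L]
      }
      shortage <- pmax(Dm - ctot, 0)
      cost <- C_h * holding + C_s * shortage + C_w * expired
      span <- (yi - 1L) * nD * nstock + seq_len(nD * nstock)
      IDX[span] <- as.integer(t(nxt0))   # layout [d, stock, y]
      COSTH[span] <- as.numeric(t(cost))
    }
    # expected cost by (stock, action, weekday), excluding the fixed charge
    Cmat <- matrix(COSTH, nrow = nD)  # [nD, nstock*nY]
    Rbar <- vector("list", 7)
    for (tau in 0:6) {
      ec <- matrix(as.numeric(pdmat[, tau + 1L] %*% Cmat), nstock, nY)
      Rbar[[tau + 1L]] <- -(ec %*% py) -
        rep(C_f * (0:A_max > 0), each = nstock)
    }
    list(
      backup_rows = function(V, rows) {
        Q <- matrix(0, length(rows), A_max + 1L)
        tau_of <- (rows - 1L) %/% nstock
        for (tau in unique(tau_of)) {
          sel <- which(tau_of == tau)
          srows <- rows[sel] - tau * nstock  # 1-based stock index
          Vn <- V[((tau + 1L) %% 7L) * nstock + seq_len(nstock)]
          W <- cpp_gather_expect(srows - 1L, IDX, pdmat[, tau + 1L],
                                 nD, nstock, nY, Vn)
          Q[sel, ] <- Rbar[[tau + 1L]][srows, , drop = FALSE] +
            gamma * (W %*% py)
        }
        Q
      }
    )
  }

  mdp_model(
    states = state_space(states, radices),
    actions = matrix(0:A_max, ncol = 1),
    outcomes = outcomes,
    transition = transition, outcome_prob = outcome_prob, gamma = gamma,
    convergence = function(V_history, tol) {
      convergence_periodic_span(V_history, tol, period = 7L)
    },
    convergence_window = 8L,
    backend_builder = backend_builder,
    name = name, params = params, scenario = "c", profiles = profiles,
    weekday_pmf = pdmat, arrival_pmf = py,
    sim = sim_hooks_c(params, pdmat), heuristic_families = "weekday_sS"
  )
}

# Simulator hooks: per rollout-day, one uniform for demand plus A_max uniforms
# for the unit-level shelf-life draws (always consumed, so the stream is
# policy-independent).
sim_hooks_c <- function(params, pdmat) {
  m <- params$m; A_max <- params$A_max
  cum_d <- apply(pdmat, 2, cumsum)
  # unit-level life thresholds per order quantity: cum_life[k, a+1]
  cum_life <- vapply(0:A_max, function(a) cumsum(params$life_fn(a)),
                     numeric(m))
  radices <- c(7L, rep(A_max + 1L, m - 1L))
  list(
    init = function(n) list(weekday = rep(0L, n),
                            stock = matrix(0L, n, m - 1L)),
    draw = function(n) list(u_d = stats::runif(n),
                            U = matrix(stats::runif(n * A_max), n, A_max)),
    step = function(st, action, draws) {
      n <- nrow(st$stock)
      a <- rep_len(as.integer(action), n)
      d <- integer(n)
      for (tau in unique(st$weekday)) {
        sel <- st$weekday == tau
        d[sel] <- findInterval(draws$u_d[sel], cum_d[, tau + 1L])
      }
      # unit-level categorical draws -> arrival profile counts
      Cat <- matrix(1L, n, A_max)
      for (k in seq_len(m - 1L)) {
        thr <- cum_life[k, a + 1L]
        Cat <- Cat + (draws$U > thr)
      }
      inorder <- matrix(seq_len(A_max), n, A_max, byrow = TRUE) <= a
      Y <- matrix(0, n, m)
      for (k in seq_len(m)) Y[, k] <- rowSums((Cat == k) & inorder)
      cc <- step_c_core(st$stock, Y, d, params)
      reward <- -(params$C_h * cc$holding_charged + params$C_s * cc$shortage +
                    params$C_w * cc$expired + params$C_f * (a > 0))
      list(state = list(weekday = (st$weekday + 1L) %% 7L,
                        stock = cc$rem[, -1, drop = FALSE]),
           reward = reward,
           info = list(demand = d, met = cc$issued, expired = cc$expired,
                       received = cc$accepted,
                       holding = cc$holding_charged - cc$expired,
                       ordered = a))
    },
    features = function(st) list(I = rowSums(st$stock), weekday = st$weekday),
    state_index = function(st) tuple_index(cbind(st$weekday, st$stock), radices),
    clip_action = function(a) pmax(0L, pmin(as.integer(round(a)), A_max))
  )
}

#' Closed-form space sizes for the platelet-bank scenario
#'
#' The outcome count multiplies the demand levels by the number of
#' arrival-age profiles with total at most \code{A_max}, i.e.
#' \code{(D_max + 1) * choose(A_max + m, m)}.
#'
#' @param m,A_max,D_max scenario dimensions.
#' @return list with state, action and outcome counts (as doubles: the m = 8
#'   state count exceeds the integer range).
#' @export
scenario_c_sizes <- function(m, A_max = 20, D_max = 20) {
  list(n_states = 7 * (A_max + 1)^(m - 1), n_actions = A_max + 1,
       n_outcomes = (D_max + 1) * choose(A_max + m, m))
}
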