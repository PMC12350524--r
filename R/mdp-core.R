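#' Construct a finite MDP in deterministic-transition / random-outcome form
#'
#' Defines a finite Markov decision process through the factorisation used by
#' the solver: a deterministic transition \code{(s, a, omega) -> (reward, s')}
#' applied to an enumerated set of random outcomes \code{omega}, together with
#' the outcome probabilities \code{P(omega | s, a)}. Any problem whose
#' randomness can be enumerated this way (here: daily demand, issued-unit
#' pairs, demand plus arrival-age profiles) plugs into [value_iteration()]
#' unchanged.
#'
#' @param states a [state_space()], or an integer matrix of unique state tuples.
#' @param actions integer matrix of action tuples, one per row (single column
#'   for one product, two for two products).
#' @param outcomes integer matrix of outcome tuples \code{omega}, one per row.
#' @param transition function \code{(state, action, outcome)} returning
#'   \code{list(reward =, next_state =)}; must be deterministic and must map
#'   into the state space.
#' @param outcome_prob function \code{(state, action)} returning the
#'   probability of every outcome row (non-negative, summing to one within
#'   1e-8).
#' @param gamma discount factor in \code{[0, 1]}.
#' @param initial_value either a numeric vector of length \code{n_states} or a
#'   function of the model returning one; defaults to zero.
#' @param convergence convergence test called between sweeps; a function
#'   \code{(V_history, tol)} where \code{V_history} is a list of the most
#'   recent value vectors (oldest first). Defaults to
#'   [convergence_sup_norm()] applied to the last two iterates.
#' @param convergence_window how many successive iterates the test needs
#'   (2 for the standard and span tests, 8 for the weekday-periodic test).
#' @param transition_table optional vectorised table builder used to compile
#'   the model for the fast solver path; see Details.
#' @param backend_builder optional function of the model returning a custom
#'   backup backend (used by the larger scenario models to exploit structure).
#' @param name label used in printing.
#' @param ... additional fields stored on the model (parameters, simulator
#'   hooks).
#'
#' @details The solver needs, for every state, the expectation of
#' \code{reward + gamma * V(next)} over outcomes, maximised over actions. By
#' default this is evaluated from a compiled table of next-state indices and
#' rewards (built by calling \code{transition} on every \code{(s, a, omega)}
#' triple, or by \code{transition_table} when supplied, which must return
#' \code{list(nxt, rew, prob, prob_mode)} in the layout documented in
#' \code{src/kernels.cpp}). \code{backend_builder} replaces the tabular path
#' entirely with a structure-exploiting backup returning the same numbers.
#'
#' @return an object of class \code{"perish_mdp"}.
#' @seealso [value_iteration()], [scenario_a()], [scenario_b()], [scenario_c()]
#' @export
mdp_model <- function(states, actions, outcomes, transition, outcome_prob,
                      gamma, initial_value = NULL, convergence = NULL,
                      convergence_window = 2L, transition_table = NULL,
                      backend_builder = NULL, name = "finite MDP", ...) {
  if (!inherits(states, "state_space")) states <- state_space(states)
  actions <- as.matrix(actions); storage.mode(actions) <- "integer"
  outcomes <- as.matrix(outcomes); storage.mode(outcomes) <- "integer"
  if (anyDuplicated(actions)) stop("actions must be unique")
  if (anyDuplicated(outcomes)) stop("outcomes must be unique")
  stopifnot(is.function(transition), is.function(outcome_prob),
            gamma >= 0, gamma <= 1)
  model <- structure(
    list(name = name, states = states, actions = actions, outcomes = outcomes,
         n_states = states$n_states, n_actions = nrow(actions),
         n_outcomes = nrow(outcomes), transition = transition,
         outcome_prob = outcome_prob, gamma = gamma,
         initial_value = initial_value, convergence = convergence,
         convergence_window = as.integer(convergence_window),
         transition_table = transition_table,
         backend_builder = backend_builder,
         cache = new.env(parent = emptyenv()), ...),
    class = "perish_mdp"
  )
  model
}

#' @export
print.perish_mdp <- function(x, ...) {
  cat(sprintf("%s\n  |S| = %s states (arity %d), |A| = %s actions, |Omega| = %s outcomes\n  gamma = %g\n",
              x$name, format(x$n_states, big.mark = ","), x$states$state_arity,
              format(x$n_actions, big.mark = ","),
              format(x$n_outcomes, big.mark = ","), x$gamma))
  invisible(x)
}

#' Validate outcome probabilities and transition closure of a model
#'
#' Checks that \code{P(omega | s, a)} is a probability distribution (within
#' \code{tol}) and that the deterministic transition maps into the state
#' space, for all state-action pairs when the model is small or for a seeded
#' sample otherwise.
#'
#' @param model a \code{perish_mdp}.
#' @param n_check maximum number of state-action pairs to check exhaustively.
#' @param tol normalization tolerance.
#' @return \code{TRUE} invisibly; stops with a model-validation error otherwise.
#' @export
validate_model <- function(model, n_check = 2000L, tol = 1e-8) {
  nS <- model$n_states; nA <- model$n_actions
  pairs <- if (nS * nA <= n_check) {
    cbind(rep(seq_len(nS), each = nA), rep(seq_len(nA), nS))
  } else {
    cbind(sample.int(nS, n_check, replace = TRUE),
          sample.int(nA, n_check, replace = TRUE))
  }
  for (k in seq_len(nrow(pairs))) {
    s <- model$states$states[pairs[k, 1], ]
    a <- model$actions[pairs[k, 2], ]
    p <- model$outcome_prob(s, a)
    if (length(p) != model$n_outcomes || any(p < -tol) ||
        abs(sum(p) - 1) > tol) {
      stop(sprintf("model-validation error: P(omega|s,a) is not a probability distribution at state (%s), action (%s); sum = %.12f",
                   paste(s, collapse = ","), paste(a, collapse = ","), sum(p)))
    }
    o <- which(p > 0)[1]
    tr <- model$transition(s, a, model$outcomes[o, ])
    model$states$index_of(tr$next_state)  # errors if outside the space
  }
  invisible(TRUE)
}

#' Solver configuration
#'
#' @param max_iterations iteration cap; runs ending here are flagged as not
#'   converged rather than erroring.
#' @param tolerance tolerance theta handed to the model's convergence test
#'   (sup-norm or span of value changes, depending on the scenario).
#' @param batch_size states updated per batch; \code{Inf} processes all states
#'   in one batch. Results are identical for every batch size (Jacobi sweeps).
#' @param n_devices device count in the padded layout contract (deterministic
#'   same-answer sharding; no physical devices are required).
#' @param checkpoint_every write a values checkpoint every this many
#'   iterations (0 disables).
#' @param checkpoint_dir directory for checkpoints.
#' @param max_table_entries memory guard: refuse to compile a tabular model
#'   with more than this many (state, action, outcome) cells.
#' @param verbose print per-iteration max value change.
#' @return a list of class \code{"vi_config"}.
#' @export
vi_config <- function(max_iterations = 5000L, tolerance = 1e-4,
                      batch_size = Inf, n_devices = 1L,
                      checkpoint_every = 0L, checkpoint_dir = NULL,
                      max_table_entries = 2e8, verbose = FALSE) {
  stopifnot(max_iterations >= 1, tolerance > 0, batch_size >= 1, n_devices >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, batch_size = batch_size,
                 n_devices = as.integer(n_devices),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir,
                 max_table_entries = max_table_entries, verbose = verbose),
            class = "vi_config")
}

## ---- convergence tests ----------------------------------------------------

#' Convergence tests for value iteration
#'
#' Three stopping rules, matching the three problem classes handled by the
#' scenario models:
#' \describe{
#'   \item{\code{convergence_sup_norm}}{standard discounted test: stop when
#'     \code{max_s |V_next(s) - V_prev(s)| < tol}.}
#'   \item{\code{convergence_span}}{undiscounted (relative-value) test: stop
#'     when the per-state change is uniform, i.e.
#'     \code{max_s d(s) - min_s d(s) < tol} with \code{d = V_next - V_prev};
#'     the common change estimates the gain.}
#'   \item{\code{convergence_periodic_span}}{periodic variant: the span test
#'     applied to the change over one full period (7 days),
#'     \code{d7 = V_i - V_{i-7}}.}
#' }
#'
#' @param V_prev,V_next value vectors from successive sweeps.
#' @param tol tolerance theta.
#' @return logical.
#' @export
convergence_sup_norm <- function(V_prev, V_next, tol) {
  stopifnot(length(V_prev) == length(V_next))
  max(abs(V_next - V_prev)) < tol
}

#' @rdname convergence_sup_norm
#' @export
convergence_span <- function(V_prev, V_next, tol) {
  stopifnot(length(V_prev) == length(V_next))
  d <- V_next - V_prev
  (max(d) - min(d)) < tol
}

#' @rdname convergence_sup_norm
#' @param V_history list of successive value vectors, oldest first.
#' @param period period length in sweeps (7 for weekday-periodic demand).
#' @export
convergence_periodic_span <- function(V_history, tol, period = 7L) {
  n <- length(V_history)
  if (n < period + 1L) return(FALSE)  # insufficient history: not converged
  d <- V_history[[n]] - V_history[[n - period]]
  (max(d) - min(d)) < tol
}

## ---- backends -------------------------------------------------------------

# Compile the model into a backup backend: list(backup_rows(V, rows) -> Q).
# Cached on the model's cache environment.
compile_backend <- function(model, config = vi_config()) {
  if (!is.null(model$cache$backend)) return(model$cache$backend)
  backend <- if (!is.null(model$backend_builder)) {
    model$backend_builder(model)
  } else {
    tab <- if (!is.null(model$transition_table)) {
      model$transition_table(model)
    } else {
      build_tabular(model, config)
    }
    tabular_backend(tab, model)
  }
  model$cache$backend <- backend
  backend
}

# Generic (loop-based) tabular compilation; intended for small/toy models.
# Zero-probability outcomes are skipped entirely: a scenario may declare them
# infeasible and refuse to transition on them.
build_tabular <- function(model, config = vi_config()) {
  nS <- model$n_states; nA <- model$n_actions; nO <- model$n_outcomes
  cells <- as.numeric(nS) * nA * nO
  if (cells > config$max_table_entries) {
    stop(sprintf("memory guard: tabular compilation needs %.3g cells (> max_table_entries = %.3g); supply a transition_table or backend_builder",
                 cells, config$max_table_entries))
  }
  nxt <- integer(cells); rew <- numeric(cells); prob <- numeric(cells)
  S <- model$states$states
  for (s in seq_len(nS)) {
    st <- S[s, ]
    for (a in seq_len(nA)) {
      act <- model$actions[a, ]
      p <- model$outcome_prob(st, act)
      if (abs(sum(p) - 1) > 1e-8 || any(p < -1e-8)) {
        stop("model-validation error: outcome probabilities do not sum to 1")
      }
      # layout: outcome fastest, then action, then state
      base <- (a - 1L) * nO + (s - 1L) * nO * nA
      prob[base + seq_len(nO)] <- p
      for (o in which(p > 0)) {
        tr <- model$transition(st, act, model$outcomes[o, ])
        nxt[base + o] <- model$states$index_of(tr$next_state) - 1L
        rew[base + o] <- tr$reward
      }
    }
  }
  list(nxt = nxt, rew = rew, prob = prob, prob_mode = 2L)
}

tabular_backend <- function(tab, model) {
  nS <- model$n_states; nA <- model$n_actions; nO <- model$n_outcomes
  gamma <- model$gamma
  force(tab)
  list(
    backup_rows = function(V, rows) {
      cpp_backup_tabular(rows - 1L, tab$nxt, tab$rew, tab$prob,
                         tab$prob_mode, nS, nA, nO, V, gamma)
    }
  )
}

## ---- core operations ------------------------------------------------------

#' One-state Bellman optimality backup (reference path)
#'
#' Evaluates \code{max_a sum_omega P(omega|s,a) [r_omega + gamma V(s'_omega)]}
#' directly from the model's transition and probability functions, without the
#' compiled tables. This is the readable reference the fast paths are tested
#' against.
#'
#' @param state a state tuple (member of the model's state space).
#' @param prev_values value vector from the previous sweep.
#' @param model a \code{perish_mdp}.
#' @return the backed-up value, a scalar.
#' @export
bellman_backup <- function(state, prev_values, model) {
  model$states$index_of(state)  # index-lookup error for unknown states
  stopifnot(length(prev_values) == model$n_states, all(is.finite(prev_values)))
  best <- -Inf
  for (a in seq_len(model$n_actions)) {
    act <- model$actions[a, ]
    p <- model$outcome_prob(state, act)
    if (abs(sum(p) - 1) > 1e-8 || any(p < -1e-8)) {
      stop("model-validation error: outcome probabilities do not sum to 1")
    }
    acc <- 0
    for (o in which(p > 0)) {
      tr <- model$transition(state, act, model$outcomes[o, ])
      acc <- acc + p[o] * (tr$reward +
                             model$gamma * prev_values[model$states$index_of(tr$next_state)])
    }
    if (acc > best) best <- acc
  }
  best
}

#' One Jacobi sweep of the Bellman backup over all states
#'
#' Applies the Bellman optimality backup to every state against the same
#' previous value vector (no within-sweep visibility of updates), processing
#' states in the padded \code{(device, batch, slot)} layout of [pad_states()].
#' The result is identical for every \code{batch_size}/\code{n_devices}
#' combination; padding slots never influence real states.
#'
#' @param prev_values value vector of length \code{n_states}.
#' @param model a \code{perish_mdp}.
#' @param config a [vi_config()].
#' @return the updated value vector.
#' @export
sweep_values <- function(prev_values, model, config = vi_config()) {
  stopifnot(length(prev_values) == model$n_states)
  backend <- compile_backend(model, config)
  layout <- pad_states(model$n_states, config$batch_size, config$n_devices)
  out <- numeric(model$n_states)
  per_dev <- layout$n_batches * layout$batch_size
  for (dev in seq_len(layout$n_devices)) {
    for (b in seq_len(layout$n_batches)) {
      lo <- (dev - 1L) * per_dev + (b - 1L) * layout$batch_size + 1L
      hi <- min(lo + layout$batch_size - 1L, layout$total_slots)
      rows <- layout$slot_state[lo:hi]
      rows <- rows[!is.na(rows)]
      if (!length(rows)) next
      Q <- backend$backup_rows(prev_values, rows)
      out[rows] <- Q[cbind(seq_len(nrow(Q)), max.col(Q, ties.method = "first"))]
    }
  }
  out
}

initial_values <- function(model) {
  v <- model$initial_value
  if (is.null(v)) return(numeric(model$n_states))
  if (is.function(v)) v <- v(model)
  stopifnot(length(v) == model$n_states)
  as.numeric(v)
}

model_convergence <- function(model) {
  if (!is.null(model$convergence)) return(model$convergence)
  function(V_history, tol) {
    n <- length(V_history)
    if (n < 2) return(FALSE)
    convergence_sup_norm(V_history[[n - 1]], V_history[[n]], tol)
  }
}

write_checkpoint <- function(values, iter, config) {
  dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(state = seq_along(values) - 1L, value = values),
                   file.path(config$checkpoint_dir,
                             sprintf("values_iter%06d.csv", iter)),
                   row.names = FALSE)
  jsonlite::write_json(list(iteration = iter, time = format(Sys.time())),
                       file.path(config$checkpoint_dir,
                                 sprintf("meta_iter%06d.json", iter)),
                       auto_unbox = TRUE)
}

run_vi_engine <- function(model, config, asynchronous) {
  V <- initial_values(model)
  conv_fn <- model_convergence(model)
  window <- max(2L, model$convergence_window)
  history <- list(V)
  layout <- pad_states(model$n_states, config$batch_size, config$n_devices)
  backend <- compile_backend(model, config)
  converged <- FALSE
  deltas <- numeric(0)
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    if (asynchronous) {
      Vnew <- V
      per_dev <- layout$n_batches * layout$batch_size
      for (dev in seq_len(layout$n_devices)) {
        for (b in seq_len(layout$n_batches)) {
          lo <- (dev - 1L) * per_dev + (b - 1L) * layout$batch_size + 1L
          hi <- min(lo + layout$batch_size - 1L, layout$total_slots)
          rows <- layout$slot_state[lo:hi]
          rows <- rows[!is.na(rows)]
          if (!length(rows)) next
          # Gauss-Seidel: this batch sees the updates of earlier batches
          Q <- backend$backup_rows(Vnew, rows)
          Vnew[rows] <- Q[cbind(seq_len(nrow(Q)),
                                max.col(Q, ties.method = "first"))]
        }
      }
    } else {
      Vnew <- sweep_values(V, model, config)
    }
    if (!all(is.finite(Vnew))) {
      stop(sprintf("numerical failure: non-finite values at iteration %d", iter))
    }
    deltas[iter] <- max(abs(Vnew - V))
    if (config$verbose) {
      message(sprintf("iteration %d: max |dV| = %.6g", iter, deltas[iter]))
    }
    history <- c(history, list(Vnew))
    if (length(history) > window) history <- history[-1]
    V <- Vnew
    if (config$checkpoint_every > 0 && !is.null(config$checkpoint_dir) &&
        iter %% config$checkpoint_every == 0) {
      write_checkpoint(V, iter, config)
    }
    if (conv_fn(history, config$tolerance)) { converged <- TRUE; break }
  }
  list(values = V, n_iterations = iter, converged = converged, deltas = deltas)
}

#' Solve a finite MDP by (batched) value iteration
#'
#' Iterates the Bellman optimality backup from the model's initial value
#' estimate until the model's convergence test passes (or \code{max_iterations}
#' is hit, in which case the solution is flagged as not converged), then
#' extracts the greedy policy by a one-step lookahead. All value arithmetic is
#' in 64-bit floating point.
#'
#' @param model a \code{perish_mdp} (a scenario model or [mdp_model()]).
#' @param config a [vi_config()].
#' @param asynchronous if \code{TRUE}, runs the Gauss-Seidel variant: within an
#'   iteration, later state batches use the already-updated values of earlier
#'   batches (ascending state order, \code{batch_size} blocks). Converges to
#'   the same fixed point as the standard Jacobi sweeps.
#' @return an object of class \code{"vi_solution"}: \code{values} (the value
#'   function), \code{policy} (see [extract_policy()]), \code{n_iterations},
#'   \code{converged}, \code{deltas} (per-iteration max value change), plus the
#'   model and config.
#' @export
#' @examples
#' m <- scenario_a(m = 2, L = 1, A_max = 2, demand_mean = 1, demand_cv = 0.7,
#'                 D_max = 10, C_h = 1, C_v = 3, C_s = 5, C_w = 7,
#'                 gamma = 0.9, issuing = "fifo")
#' sol <- value_iteration(m, vi_config(tolerance = 1e-6))
#' sol
value_iteration <- function(model, config = vi_config(), asynchronous = FALSE) {
  stopifnot(inherits(model, "perish_mdp"))
  if (isTRUE(model$count_only)) {
    stop("memory guard: this model was built with enumerate = FALSE (state space above the enumeration cap); value iteration refused")
  }
  res <- run_vi_engine(model, config, asynchronous)
  policy <- extract_policy(res$values, model)
  structure(list(values = res$values, policy = policy,
                 n_iterations = res$n_iterations, converged = res$converged,
                 deltas = res$deltas, model = model, config = config,
                 asynchronous = asynchronous),
            class = "vi_solution")
}

#' @rdname value_iteration
#' @export
value_iteration_async <- function(model, config = vi_config()) {
  value_iteration(model, config, asynchronous = TRUE)
}

#' Extract the greedy policy from a value function
#'
#' One-step lookahead: \code{pi(s) = argmax_a sum_omega P(omega|s,a)
#' [r_omega + gamma V(s'_omega)]}, with ties broken by the smallest action
#' ordinal (the smallest order quantity; lexicographic for two products).
#'
#' @param values a value vector of length \code{n_states}.
#' @param model the \code{perish_mdp} it belongs to.
#' @return an object of class \code{"mdp_policy"}: \code{action_index}
#'   (1-based ordinal into the action list, per state) and \code{actions} (the
#'   corresponding action tuples, one row per state).
#' @export
extract_policy <- function(values, model) {
  stopifnot(all(is.finite(values)), length(values) == model$n_states)
  backend <- compile_backend(model)
  idx <- integer(model$n_states)
  # moderate fixed blocks keep the Q matrix small for large state spaces
  block <- 65536L
  for (lo in seq(1L, model$n_states, by = block)) {
    rows <- lo:min(lo + block - 1L, model$n_states)
    Q <- backend$backup_rows(values, rows)
    idx[rows] <- max.col(Q, ties.method = "first")
  }
  structure(list(action_index = idx,
                 actions = model$actions[idx, , drop = FALSE],
                 n_actions = model$n_actions),
            class = "mdp_policy")
}

#' @export
print.mdp_policy <- function(x, ...) {
  cat(sprintf("Deterministic policy over %s states (%d actions); order quantities %s..%s\n",
              format(length(x$action_index), big.mark = ","), x$n_actions,
              min(x$actions), max(x$actions)))
  invisible(x)
}
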