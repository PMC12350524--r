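#' Rollout configuration
#'
#' @param warmup_days days simulated before scoring starts (their rewards are
#'   discarded; the warm-up erases the empty-inventory initialisation).
#' @param horizon_days scored days per rollout.
#' @param n_rollouts number of independent rollouts.
#' @param seed integer seed for the rollout random streams.
#' @return a list of class \code{"rollout_config"}.
#' @export
rollout_config <- function(warmup_days = 100L, horizon_days = 365L,
                           n_rollouts = 10000L, seed = 1L) {
  stopifnot(warmup_days >= 0, horizon_days >= 1, n_rollouts >= 1)
  structure(list(warmup_days = as.integer(warmup_days),
                 horizon_days = as.integer(horizon_days),
                 n_rollouts = as.integer(n_rollouts), seed = as.integer(seed)),
            class = "rollout_config")
}

#' One simulator step (single state)
#'
#' Advances the scenario simulator by one day from a single state. With a
#' forced \code{outcome} this is exactly the model's deterministic transition
#' (the simulator and the solver share the dynamics code); without one, an
#' outcome is drawn from \code{P(omega | s, a)}.
#'
#' @param model a \code{perish_mdp}.
#' @param state a state tuple.
#' @param action an action tuple.
#' @param outcome optional outcome tuple to force.
#' @return list with \code{next_state}, \code{reward} and \code{outcome}.
#' @export
env_step <- function(model, state, action, outcome = NULL) {
  if (is.null(outcome)) outcome <- sample_outcome(model, state, action)
  tr <- model$transition(state, action, outcome)
  list(next_state = tr$next_state, reward = tr$reward, outcome = outcome)
}

#' @rdname env_step
#' @export
sample_outcome <- function(model, state, action) {
  p <- model$outcome_prob(state, action)
  model$outcomes[sample.int(length(p), 1L, prob = p), ]
}

resolve_policy_actions <- function(policy, model, st, n) {
  if (inherits(policy, "vi_solution")) policy <- policy$policy
  if (inherits(policy, "mdp_policy")) {
    idx <- model$sim$state_index(st)
    bad <- is.na(idx)
    if (any(bad)) stop("policy undefined on a reached state")
    acts <- model$actions[policy$action_index[idx], , drop = FALSE]
    return(acts)
  }
  if (inherits(policy, "heuristic_policy")) {
    a <- heuristic_actions(policy, model$sim$features(st))
    if (is.null(dim(a))) a <- matrix(a, ncol = 1)
    return(model$sim$clip_action(a))
  }
  if (is.function(policy)) {
    a <- policy(model$sim$features(st))
    if (is.null(dim(a))) a <- matrix(a, ncol = 1)
    return(model$sim$clip_action(a))
  }
  stop("unsupported policy object")
}

#' Simulate a policy and report return and KPIs
#'
#' Runs seeded stochastic rollouts of the scenario under a fixed policy:
#' \code{warmup_days} unscored days from empty inventory (weekday 0 where
#' applicable), then \code{horizon_days} scored days. The per-rollout return
#' is the discounted sum of rewards over the scored horizon,
#' \code{sum_k gamma^k R(warmup + k + 1)}, using the scenario's own discount
#' factor. KPIs over the scored horizon: service level (% of demand met),
#' wastage (% of received units that expired; 0 when nothing was received),
#' and holding (mean end-of-day units in stock). Service level with zero
#' total demand reports 100%.
#'
#' All rollouts consume a fixed, policy-independent number of random draws
#' per day, so running two policies from the same seed uses common random
#' numbers.
#'
#' @param model a \code{perish_mdp} (count-only models can be simulated too).
#' @param policy a [value_iteration()] solution, an [extract_policy()] policy,
#'   a heuristic policy ([base_stock_policy()] and friends), or a function of
#'   the simulator features returning orders.
#' @param config a [rollout_config()].
#' @return an object of class \code{"kpi_report"}: per-rollout vectors
#'   \code{returns}, \code{service_level}, \code{wastage}, \code{holding} and
#'   a \code{summary} data frame of means and across-rollout standard
#'   deviations.
#' @export
simulate_policy <- function(model, policy, config = rollout_config()) {
  stopifnot(inherits(model, "perish_mdp"))
  sim <- model$sim
  n <- config$n_rollouts
  gamma <- model$gamma
  set.seed(config$seed)
  st <- sim$init(n)
  ret <- numeric(n)
  demand <- numeric(n); met <- numeric(n)
  received <- numeric(n); expired <- numeric(n); holding <- numeric(n)
  total <- config$warmup_days + config$horizon_days
  for (day in seq_len(total)) {
    a <- resolve_policy_actions(policy, model, st, n)
    draws <- sim$draw(n)
    out <- sim$step(st, a, draws)
    st <- out$state
    if (day > config$warmup_days) {
      k <- day - config$warmup_days - 1L
      ret <- ret + gamma^k * out$reward
      demand <- demand + out$info$demand
      met <- met + out$info$met
      received <- received + out$info$received
      expired <- expired + out$info$expired
      holding <- holding + out$info$holding
    }
  }
  service <- ifelse(demand > 0, 100 * met / demand, 100)
  wastage <- ifelse(received > 0, 100 * expired / received, 0)
  hold <- holding / config$horizon_days
  summ <- data.frame(
    metric = c("return", "service_level", "wastage", "holding"),
    mean = c(mean(ret), mean(service), mean(wastage), mean(hold)),
    sd = c(sd(ret), sd(service), sd(wastage), sd(hold)))
  structure(list(returns = ret, service_level = service, wastage = wastage,
                 holding = hold, summary = summ, config = config),
            class = "kpi_report")
}

#' @export
print.kpi_report <- function(x, ...) {
  cat(sprintf("KPI report over %d rollouts (%d-day horizon, %d-day warm-up)\n",
              x$config$n_rollouts, x$config$horizon_days,
              x$config$warmup_days))
  s <- x$summary
  cat(sprintf("  return        %10.1f +/- %.1f\n", s$mean[1], s$sd[1]))
  cat(sprintf("  service level %9.1f%% +/- %.1f\n", s$mean[2], s$sd[2]))
  cat(sprintf("  wastage       %9.1f%% +/- %.1f\n", s$mean[3], s$sd[3]))
  cat(sprintf("  holding       %10.1f +/- %.1f\n", s$mean[4], s$sd[4]))
  invisible(x)
}

#' Compare policies on common random numbers
#'
#' Evaluates each policy on the same seeded rollout set (common random
#' numbers: every policy sees identical demand and shelf-life draws) and
#' reports the mean/sd of the return and KPIs, plus each policy's optimality
#' gap relative to the first (reference) policy:
#' \code{gap = 100 (return_ref - return) / |return_ref|}, positive when the
#' policy underperforms the reference, for cost (negative-return) and revenue
#' (positive-return) problems alike.
#'
#' @param model a \code{perish_mdp}.
#' @param policies named list of policies (see [simulate_policy()]); the
#'   first entry is the reference (typically the value-iteration policy).
#' @param config a [rollout_config()].
#' @return an object of class \code{"policy_comparison"}: a \code{table} data
#'   frame and the per-policy \code{reports}.
#' @export
evaluate_policies <- function(model, policies, config = rollout_config()) {
  stopifnot(length(policies) >= 1)
  if (is.null(names(policies))) {
    names(policies) <- paste0("policy_", seq_along(policies))
  }
  reports <- lapply(policies, function(p) simulate_policy(model, p, config))
  means <- vapply(reports, function(r) r$summary$mean[1], numeric(1))
  sds <- vapply(reports, function(r) r$summary$sd[1], numeric(1))
  ref <- means[1]
  gap <- 100 * (ref - means) / abs(ref)
  tab <- data.frame(
    policy = names(policies),
    return_mean = means, return_sd = sds,
    service_level = vapply(reports, function(r) r$summary$mean[2], numeric(1)),
    wastage = vapply(reports, function(r) r$summary$mean[3], numeric(1)),
    holding = vapply(reports, function(r) r$summary$mean[4], numeric(1)),
    gap_pct = gap, row.names = NULL)
  structure(list(table = tab, reports = reports, config = config),
            class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  cat(sprintf("Policy comparison on %d shared rollouts\n",
              x$config$n_rollouts))
  tab <- x$table
  tab$return_mean <- round(tab$return_mean, 1)
  tab$return_sd <- round(tab$return_sd, 1)
  tab$service_level <- round(tab$service_level, 1)
  tab$wastage <- round(tab$wastage, 1)
  tab$holding <- round(tab$holding, 1)
  tab$gap_pct <- round(tab$gap_pct, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
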