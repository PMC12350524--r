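#' Heuristic replenishment policies
#'
#' Three parametric policy families from the perishable inventory literature,
#' matched to the three scenario models:
#' \describe{
#'   \item{base-stock (order-up-to)}{order \code{[S - I]+} where \code{I} is
#'     total stock on hand and in transit; one parameter \code{S}.}
#'   \item{waste-adjusted (modified) base-stock}{per product,
#'     \code{[S - I + [X1 - mu]+]+}: the order-up-to shortfall plus the stock
#'     expected to be wasted today (units expiring tonight, \code{X1}, in
#'     excess of mean daily demand \code{mu}).}
#'   \item{weekday (s, S)}{one reorder-point/order-up-to pair per day of the
#'     week: order \code{[S_tau - I]+} when \code{I <= s_tau}, else nothing;
#'     a pair violating the hard constraint \code{s_tau < S_tau} never
#'     orders.}
#' }
#' Orders are clipped to the scenario's \code{A_max} by the simulator.
#'
#' @param S,S_a,S_b order-up-to levels.
#' @param s,S_tau for the weekday policy: length-7 integer vectors of reorder
#'   points and order-up-to levels (weekday 0 first).
#' @return a policy object usable with [simulate_policy()].
#' @name heuristic_policies
NULL

#' @rdname heuristic_policies
#' @export
base_stock_policy <- function(S) {
  stopifnot(length(S) == 1, S >= 0)
  structure(list(S = as.integer(S), params = c(S = as.integer(S))),
            class = c("base_stock", "heuristic_policy"))
}

#' @rdname heuristic_policies
#' @export
modified_base_stock_policy <- function(S_a, S_b) {
  stopifnot(S_a >= 0, S_b >= 0)
  structure(list(S_a = as.integer(S_a), S_b = as.integer(S_b),
                 params = c(S_a = as.integer(S_a), S_b = as.integer(S_b))),
            class = c("modified_base_stock", "heuristic_policy"))
}

#' @rdname heuristic_policies
#' @export
weekday_sS_policy <- function(s, S_tau) {
  stopifnot(length(s) == 7, length(S_tau) == 7, all(s >= 0), all(S_tau >= 0))
  p <- c(as.integer(s), as.integer(S_tau))
  names(p) <- c(paste0("s", 0:6), paste0("S", 0:6))
  structure(list(s = as.integer(s), S = as.integer(S_tau), params = p),
            class = c("weekday_sS", "heuristic_policy"))
}

#' @export
print.heuristic_policy <- function(x, ...) {
  cat(class(x)[1], "policy:", paste(names(x$params), x$params, sep = "=",
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Heuristic order rules
#'
#' The action rules of the policy families in [heuristic_policies], exposed
#' directly (vectorised over states/rollouts).
#'
#' @param S,s order-up-to level(s) and reorder point(s).
#' @param I total stock on hand and in transit.
#' @param X1 stock expiring at the end of the current period.
#' @param mu mean daily demand.
#' @param weekday integer(s) in 0..6.
#' @return order quantities (not yet clipped to \code{A_max}).
#' @export
act_base_stock <- function(S, I) pmax(S - I, 0)

#' @rdname act_base_stock
#' @export
act_modified_base_stock <- function(S, I, X1, mu) {
  pmax(S - I + pmax(X1 - mu, 0), 0)
}

#' @rdname act_base_stock
#' @export
act_weekday_sS <- function(s, S, weekday, I) {
  s_t <- s[weekday + 1L]; S_t <- S[weekday + 1L]
  ifelse(s_t < S_t & I <= s_t, pmax(S_t - I, 0), 0)
}

# Dispatch a heuristic policy on the simulator's feature list.
heuristic_actions <- function(policy, feats) UseMethod("heuristic_actions")

#' @export
heuristic_actions.base_stock <- function(policy, feats) {
  act_base_stock(policy$S, feats$I)
}

#' @export
heuristic_actions.modified_base_stock <- function(policy, feats) {
  cbind(act_modified_base_stock(policy$S_a, feats$I_a, feats$X1_a, feats$mu_a),
        act_modified_base_stock(policy$S_b, feats$I_b, feats$X1_b, feats$mu_b))
}

#' @export
heuristic_actions.weekday_sS <- function(policy, feats) {
  act_weekday_sS(policy$s, policy$S, feats$weekday, feats$I)
}

## ---- simulation optimization ----------------------------------------------

#' Simulation-optimization search configuration
#'
#' @param sampler \code{"auto"} picks a full grid for one-parameter families
#'   and the generational evolutionary search otherwise.
#' @param population candidate parameter sets evaluated per generation.
#' @param rollouts_per_candidate seeded rollouts scoring each candidate; all
#'   candidates share the same rollout set (common random numbers).
#' @param warmup_days,horizon_days rollout shape (see [rollout_config()]).
#' @param stall_generations stop when the incumbent best-ever candidate has
#'   not changed for this many generations.
#' @param max_generations generation cap.
#' @param seed seed for both the search and the shared evaluation rollouts.
#' @return a list of class \code{"search_config"}.
#' @export
search_config <- function(sampler = c("auto", "grid", "nsga2"),
                          population = 50L, rollouts_per_candidate = 4000L,
                          warmup_days = 100L, horizon_days = 365L,
                          stall_generations = 5L, max_generations = 100L,
                          seed = 1L) {
  sampler <- match.arg(sampler)
  structure(list(sampler = sampler, population = as.integer(population),
                 rollouts_per_candidate = as.integer(rollouts_per_candidate),
                 warmup_days = as.integer(warmup_days),
                 horizon_days = as.integer(horizon_days),
                 stall_generations = as.integer(stall_generations),
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed)),
            class = "search_config")
}

heuristic_space <- function(model, family) {
  p <- model$params
  switch(family,
    base_stock = list(
      lower = 0L, upper = p$A_max,
      build = function(x) base_stock_policy(x[1])),
    modified_base_stock = list(
      lower = c(0L, 0L), upper = c(2L * p$A_max_a, 2L * p$A_max_b),
      build = function(x) modified_base_stock_policy(x[1], x[2])),
    weekday_sS = list(
      lower = rep(0L, 14), upper = rep(p$A_max, 14),
      build = function(x) weekday_sS_policy(x[1:7], x[8:14])),
    stop("unknown heuristic family: ", family))
}

#' Size of a heuristic family's parameter space
#'
#' @param model a scenario model.
#' @param family one of \code{"base_stock"}, \code{"modified_base_stock"},
#'   \code{"weekday_sS"} (defaults to the scenario's natural family).
#' @return the number of parameter combinations, as a double (the weekday
#'   (s,S) space is \code{(A_max+1)^14}, far beyond integer range).
#' @export
heuristic_search_space_size <- function(model,
                                        family = model$heuristic_families[1]) {
  sp <- heuristic_space(model, family)
  prod(as.numeric(sp$upper) - as.numeric(sp$lower) + 1)
}

candidate_key <- function(x) paste(x, collapse = ",")

# lexicographic "smaller parameter vector" tie-break
lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

#' Fit a heuristic policy by simulation optimization
#'
#' Searches the parameter space of a heuristic family for the parameters with
#' the highest mean return, estimated on a shared set of seeded rollouts
#' (common random numbers across candidates). One-parameter families are
#' searched exhaustively over the full grid; multi-parameter families use a
#' seeded generational evolutionary search (integer genomes, population
#' \code{population}, elitist survival, tournament selection, uniform
#' crossover, per-gene reset mutation), terminating when the incumbent
#' best-ever candidate has been unchanged for \code{stall_generations}
#' generations or at \code{max_generations}. Ties in mean return go to the
#' lexicographically smallest parameter vector.
#'
#' @param model a scenario model.
#' @param family heuristic family (defaults to the scenario's natural one).
#' @param search a [search_config()].
#' @return an object of class \code{"heuristic_fit"}: \code{policy} (the best
#'   policy), \code{params}, \code{mean_return}, \code{history} (per
#'   generation: incumbent parameters and score; for grid search, the full
#'   score table), \code{n_evaluations}.
#' @export
fit_heuristic <- function(model, family = model$heuristic_families[1],
                          search = search_config()) {
  sp <- heuristic_space(model, family)
  k <- length(sp$lower)
  eval_cfg <- rollout_config(warmup_days = search$warmup_days,
                             horizon_days = search$horizon_days,
                             n_rollouts = search$rollouts_per_candidate,
                             seed = search$seed + 1L)
  score <- function(x) {
    rep <- simulate_policy(model, sp$build(x), eval_cfg)
    mean(rep$returns)
  }
  sampler <- search$sampler
  if (sampler == "auto") sampler <- if (k == 1) "grid" else "nsga2"
  if (sampler == "grid") {
    if (k != 1) stop("grid search supports one-parameter families only")
    values <- sp$lower:sp$upper
    means <- vapply(values, function(v) score(v), numeric(1))
    best <- values[which.max(means)]  # which.max: first max = smallest value
    fit <- list(policy = sp$build(best), params = stats::setNames(best, "S"),
                mean_return = max(means),
                history = data.frame(S = values, mean_return = means),
                n_evaluations = length(values), sampler = "grid")
    return(structure(fit, class = "heuristic_fit"))
  }
  ## generational evolutionary search
  set.seed(search$seed)
  pop_n <- search$population
  rand_cand <- function() {
    vapply(seq_len(k), function(j) {
      sample(sp$lower[j]:sp$upper[j], 1L)
    }, integer(1))
  }
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  score_cached <- function(x) {
    key <- candidate_key(x)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- score(x)
      cache[[key]] <- v
      evals <<- evals + 1L
    }
    v
  }
  pop <- lapply(seq_len(pop_n), function(i) rand_cand())
  fit_v <- vapply(pop, score_cached, numeric(1))
  best_x <- NULL; best_f <- -Inf
  update_best <- function() {
    for (i in seq_along(pop)) {
      if (fit_v[i] > best_f ||
          (fit_v[i] == best_f && lex_less(pop[[i]], best_x))) {
        best_f <<- fit_v[i]; best_x <<- pop[[i]]
      }
    }
  }
  update_best()
  stall <- 0L
  history <- data.frame(generation = 1L, best_mean = best_f,
                        best_params = candidate_key(best_x))
  gen <- 1L
  while (gen < search$max_generations && stall < search$stall_generations) {
    gen <- gen + 1L
    rank_ord <- order(fit_v, decreasing = TRUE)
    tournament <- function() {
      i <- sample.int(pop_n, 2L)
      pop[[if (fit_v[i[1]] >= fit_v[i[2]]) i[1] else i[2]]]
    }
    offspring <- lapply(seq_len(pop_n), function(i) {
      p1 <- tournament(); p2 <- tournament()
      child <- ifelse(stats::runif(k) < 0.5, p1, p2)
      mut <- stats::runif(k) < 1 / k
      if (any(mut)) {
        child[mut] <- vapply(which(mut), function(j) {
          sample(sp$lower[j]:sp$upper[j], 1L)
        }, integer(1))
      }
      as.integer(child)
    })
    off_f <- vapply(offspring, score_cached, numeric(1))
    # elitist survival: best `pop_n` of parents + offspring
    all_pop <- c(pop, offspring); all_f <- c(fit_v, off_f)
    keep <- order(all_f, decreasing = TRUE)[seq_len(pop_n)]
    pop <- all_pop[keep]; fit_v <- all_f[keep]
    prev_best <- best_x
    update_best()
    stall <- if (identical(best_x, prev_best)) stall + 1L else 0L
    history <- rbind(history,
                     data.frame(generation = gen, best_mean = best_f,
                                best_params = candidate_key(best_x)))
  }
  structure(list(policy = sp$build(best_x),
                 params = stats::setNames(best_x, names(sp$build(best_x)$params)),
                 mean_return = best_f, history = history,
                 n_evaluations = evals, n_generations = gen,
                 sampler = "nsga2"),
            class = "heuristic_fit")
}

#' @export
print.heuristic_fit <- function(x, ...) {
  cat(sprintf("Heuristic fit (%s sampler): best %s; mean return %.1f over %d evaluations\n",
              x$sampler,
              paste(names(x$params), x$params, sep = "=", collapse = ", "),
              x$mean_return, x$n_evaluations))
  invisible(x)
}
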