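#' @export
print.vi_solution <- function(x, ...) {
  cat(sprintf("Value iteration solution: %s\n", x$model$name))
  cat(sprintf("  %s states; %d iterations (%s)%s\n",
              format(x$model$n_states, big.mark = ","), x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$asynchronous) "; asynchronous (Gauss-Seidel) sweeps" else ""))
  cat(sprintf("  final max |dV| = %.3g; value range [%.4g, %.4g]\n",
              x$deltas[x$n_iterations], min(x$values), max(x$values)))
  invisible(x)
}

#' @export
summary.vi_solution <- function(object, ...) {
  acts <- object$policy$actions
  cat(sprintf("%s\nIterations: %d (%s), tolerance %g\n", object$model$name,
              object$n_iterations,
              if (object$converged) "converged" else "not converged",
              object$config$tolerance))
  cat("Value function quantiles:\n")
  print(round(quantile(object$values), 3))
  cat("Order quantity distribution over states:\n")
  if (ncol(acts) == 1) {
    print(table(order = acts[, 1]))
  } else {
    print(table(product_a = acts[, 1], product_b = acts[, 2]))
  }
  invisible(object)
}

#' Greedy actions at given states
#'
#' @param object a \code{vi_solution}.
#' @param newdata integer matrix of state tuples (one per row); defaults to
#'   every state.
#' @param ... unused.
#' @return matrix of action tuples, one row per input state.
#' @export
predict.vi_solution <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$policy$actions)
  idx <- object$model$states$index_of(as.matrix(newdata))
  object$policy$actions[idx, , drop = FALSE]
}

#' @export
coef.vi_solution <- function(object, ...) object$policy$actions

#' Plot a solved replenishment policy
#'
#' For models whose state has two components (for instance the single-product
#' model with \code{m = 2, L = 1}: stock expiring tonight vs fresh stock) the
#' policy is drawn as an order-quantity image over the state grid; otherwise
#' the value function is drawn against total stock on hand.
#'
#' @param x a \code{vi_solution}.
#' @param ... passed to the underlying plot call.
#' @export
plot.vi_solution <- function(x, ...) {
  S <- x$model$states$states
  if (ncol(S) == 2) {
    xs <- sort(unique(S[, 1])); ys <- sort(unique(S[, 2]))
    z <- matrix(NA_real_, length(xs), length(ys))
    z[cbind(match(S[, 1], xs), match(S[, 2], ys))] <- x$policy$actions[, 1]
    graphics::image(xs, ys, z, xlab = "oldest stock", ylab = "freshest stock",
                    main = "order quantity", col = grDevices::hcl.colors(
                      max(z, na.rm = TRUE) + 1, "viridis"), ...)
  } else {
    graphics::plot(rowSums(S), x$values, pch = ".",
                   xlab = "total units in state", ylab = "value", ...)
  }
  invisible(x)
}

#' Simulate rollouts of a solved policy
#'
#' [stats::simulate()] method: runs \code{nsim} seeded rollouts of the
#' greedy policy on the matched scenario simulator.
#'
#' @param object a \code{vi_solution}.
#' @param nsim number of rollouts.
#' @param seed seed passed to the rollout engine.
#' @param warmup_days,horizon_days rollout shape.
#' @param ... unused.
#' @return data frame with one row per rollout: return, service level,
#'   wastage, holding.
#' @export
simulate.vi_solution <- function(object, nsim = 1000, seed = 1,
                                 warmup_days = 100, horizon_days = 365, ...) {
  rep <- simulate_policy(object$model, object,
                         rollout_config(warmup_days, horizon_days, nsim, seed))
  data.frame(return = rep$returns, service_level = rep$service_level,
             wastage = rep$wastage, holding = rep$holding)
}

#' Write / read a policy as CSV
#'
#' One row per state: the state components followed by the order
#' quantity(ies). The solver's output and the simulator's policy input use
#' the same format, so files round-trip unchanged.
#'
#' @param solution a \code{vi_solution} (or an \code{mdp_policy} plus its
#'   model).
#' @param path CSV path.
#' @param model the model a read policy belongs to.
#' @return \code{read_policy_csv} returns an \code{mdp_policy}.
#' @export
write_policy_csv <- function(solution, path) {
  model <- solution$model
  pol <- solution$policy
  S <- model$states$states
  acts <- pol$actions
  colnames(acts) <- if (ncol(acts) == 1) "order" else
    paste0("order_", letters[seq_len(ncol(acts))])
  df <- data.frame(S, acts, check.names = FALSE)
  colnames(df)[seq_len(ncol(S))] <- paste0("s", seq_len(ncol(S)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_policy_csv
#' @export
read_policy_csv <- function(path, model) {
  df <- utils::read.csv(path)
  k <- model$states$state_arity
  idx <- model$states$index_of(as.matrix(df[, seq_len(k)]))
  acts <- as.matrix(df[, -seq_len(k), drop = FALSE])
  action_index <- integer(model$n_states)
  action_index[idx] <- tuple_index(acts,
                                   apply(model$actions, 2, max) + 1)
  structure(list(action_index = action_index,
                 actions = model$actions[action_index, , drop = FALSE],
                 n_actions = model$n_actions),
            class = "mdp_policy")
}
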