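#' Experiment specification
#'
#' Bundles everything needed to reproduce one experiment: the scenario and
#' its parameters, the solver configuration, the heuristic search
#' configuration and the evaluation rollout configuration. A spec plus a
#' seed fully determines a run.
#'
#' @param scenario \code{"a"}, \code{"b"} or \code{"c"}.
#' @param params named list of scenario parameters (the arguments of
#'   [scenario_a()], [scenario_b()] or [scenario_c()]).
#' @param vi named list of [vi_config()] overrides.
#' @param search named list of [search_config()] overrides.
#' @param rollout named list of [rollout_config()] overrides.
#' @param name experiment label.
#' @return a list of class \code{"experiment_spec"}.
#' @export
experiment_spec <- function(scenario, params, vi = list(), search = list(),
                            rollout = list(), name = NULL) {
  scenario <- match.arg(scenario, c("a", "b", "c"))
  if (is.null(name)) name <- paste0("scenario_", scenario)
  structure(list(scenario = scenario, params = params, vi = vi,
                 search = search, rollout = rollout, name = name),
            class = "experiment_spec")
}

#' Read an experiment specification from a YAML config file
#'
#' The file carries blocks \code{scenario}, \code{params}, and optional
#' \code{vi}, \code{search}, \code{rollout} and \code{name}; every
#' experiment reported by the package ships as one such file under
#' \code{inst/extdata/configs/}.
#'
#' @param path YAML file path.
#' @return an [experiment_spec()].
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario) || is.null(cfg$params)) {
    stop("config must contain 'scenario' and 'params' blocks")
  }
  experiment_spec(cfg$scenario, cfg$params,
                  vi = cfg$vi %||% list(), search = cfg$search %||% list(),
                  rollout = cfg$rollout %||% list(),
                  name = cfg$name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the scenario model of a spec
#'
#' @param spec an [experiment_spec()].
#' @return a \code{perish_mdp}.
#' @export
build_scenario <- function(spec) {
  builder <- switch(spec$scenario, a = scenario_a, b = scenario_b,
                    c = scenario_c)
  do.call(builder, spec$params)
}

#' Run one experiment end to end
#'
#' Builds the scenario, solves it by value iteration (unless the state space
#' is above the model's enumeration/solve caps, in which case the solve is
#' recorded as not run), fits the scenario's heuristic policy by simulation
#' optimization, evaluates the available policies on a shared rollout set,
#' and returns one results row. With \code{out_dir} set, the policy and value
#' function (CSV), run metadata (JSON) and the results row (CSV) are written
#' there.
#'
#' @param spec an [experiment_spec()].
#' @param seed master seed; the solver is deterministic, the search and
#'   evaluation streams are derived from it.
#' @param out_dir optional output directory.
#' @param verbose print progress.
#' @return a list of class \code{"experiment_result"} with the results
#'   \code{row} (data frame) and the underlying objects.
#' @export
run_experiment <- function(spec, seed = 1L, out_dir = NULL, verbose = FALSE) {
  model <- build_scenario(spec)
  sizes <- if (isTRUE(model$count_only)) model$sizes else
    list(n_states = model$n_states, n_actions = model$n_actions,
         n_outcomes = model$n_outcomes)
  vi_cfg <- do.call(vi_config, spec$vi)
  search_cfg <- do.call(search_config, utils::modifyList(list(seed = seed),
                                                         spec$search))
  roll <- utils::modifyList(list(warmup_days = 100L, horizon_days = 365L,
                                 n_rollouts = 10000L, seed = seed + 1000L),
                            spec$rollout)
  roll_cfg <- do.call(rollout_config, roll)
  solution <- NULL
  solve_error <- NULL
  if (isTRUE(model$count_only)) {
    solve_error <- "not run: state space above the enumeration cap"
  } else {
    solution <- tryCatch(value_iteration(model, vi_cfg),
                         error = function(e) {
                           solve_error <<- conditionMessage(e); NULL
                         })
  }
  if (verbose && !is.null(solve_error)) message("solver: ", solve_error)
  fit <- fit_heuristic(model, search = search_cfg)
  policies <- list()
  if (!is.null(solution)) policies$value_iteration <- solution
  policies$heuristic <- fit$policy
  comp <- evaluate_policies(model, policies, roll_cfg)
  tab <- comp$table
  vi_row <- tab[tab$policy == "value_iteration", ]
  h_row <- tab[tab$policy == "heuristic", ]
  row <- data.frame(
    experiment = spec$name, scenario = spec$scenario,
    n_states = sizes$n_states, n_actions = sizes$n_actions,
    n_outcomes = sizes$n_outcomes,
    vi_iterations = if (!is.null(solution)) solution$n_iterations else NA,
    vi_converged = if (!is.null(solution)) solution$converged else NA,
    vi_return = if (nrow(vi_row)) vi_row$return_mean else NA,
    vi_return_sd = if (nrow(vi_row)) vi_row$return_sd else NA,
    heuristic_params = paste(names(fit$params), fit$params, sep = "=",
                             collapse = " "),
    heuristic_return = h_row$return_mean, heuristic_return_sd = h_row$return_sd,
    optimality_gap_pct = if (nrow(vi_row)) h_row$gap_pct else NA)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(solution)) {
      write_policy_csv(solution, file.path(out_dir, "policy.csv"))
      utils::write.csv(data.frame(state = seq_len(model$n_states) - 1L,
                                  value = solution$values),
                       file.path(out_dir, "values.csv"), row.names = FALSE)
    }
    utils::write.csv(row, file.path(out_dir, "results.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(experiment = spec$name, seed = seed,
           iterations = if (!is.null(solution)) solution$n_iterations else NULL,
           converged = if (!is.null(solution)) solution$converged else NULL,
           tolerance = vi_cfg$tolerance, solve_error = solve_error,
           heuristic = as.list(fit$params)),
      file.path(out_dir, "run.json"), auto_unbox = TRUE)
  }
  structure(list(row = row, model = model, solution = solution, fit = fit,
                 comparison = comp, solve_error = solve_error),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  print(x$row, row.names = FALSE)
  invisible(x)
}

#' Bundled experiment configuration files
#'
#' Lists (or resolves) the YAML configs shipped with the package, one per
#' reported experiment.
#'
#' @param name optional config name (with or without \code{.yaml}).
#' @return file path(s).
#' @export
experiment_config_file <- function(name = NULL) {
  dir <- system.file("extdata", "configs", package = "perishvi")
  if (is.null(name)) return(list.files(dir, recursive = TRUE,
                                       pattern = "[.]yaml$", full.names = TRUE))
  if (!grepl("[.]yaml$", name)) name <- paste0(name, ".yaml")
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no bundled config named ", name)
  path
}
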