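#' Read and validate a run configuration
#'
#' A run configuration is a YAML (or JSON) mapping with fields:
#' `model` (`"fisheries"` or `"cancer"`), `params` (named parameter
#' overrides for the model constructor), `m_min`/`m_max`/`m_step` (action
#' grid), `strategy`, `out_dir`, `seed` and `tol`.  Unknown model
#' parameters are rejected with the list of valid names.
#'
#' @param path path to a YAML/JSON configuration file, or a named list.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must name a 'model'")
  cfg$model <- match.arg(cfg$model, c("fisheries", "cancer"))
  ctor <- switch(cfg$model, fisheries = fisheries_model,
                 cancer = cancer_model)
  valid <- names(formals(ctor))
  cfg$params <- cfg$params %||% list()
  bad <- setdiff(names(cfg$params), valid)
  if (length(bad))
    stop("unknown parameter(s) for model '", cfg$model, "': ",
         paste(bad, collapse = ", "), "; valid names are: ",
         paste(valid, collapse = ", "))
  cfg$m_min <- cfg$m_min %||% 0
  cfg$m_max <- cfg$m_max %||% 1
  cfg$m_step <- cfg$m_step %||% 0.01
  stopifnot(cfg$m_min < cfg$m_max, cfg$m_step > 0)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "run_config")
}

build_game <- function(config) {
  ctor <- switch(config$model, fisheries = fisheries_model,
                 cancer = cancer_model)
  do.call(ctor, config$params)
}

config_m_grid <- function(config)
  seq(config$m_min, config$m_max, by = config$m_step)

write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(model = config$model, params = config$params,
                     m_min = config$m_min, m_max = config$m_max,
                     m_step = config$m_step, seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("segsolve"))),
                extra)
  jsonlite::write_json(sort_keys(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Run an ESS bifurcation scan and write its outputs
#'
#' Builds the configured model, traces the ESS branch diagram over the
#' configured action grid, and writes `branches.csv`, `bifurcations.csv`
#' and a JSON run manifest into the output directory.  Reruns with an
#' identical configuration are bitwise identical.
#'
#' @param config a [read_run_config()] result, a path, or a named list.
#' @return The [ess_branch_diagram()], invisibly.
#' @export
run_bifurcate <- function(config) {
  config <- if (inherits(config, "run_config")) config
  else read_run_config(config)
  set.seed(config$seed)
  game <- build_game(config)
  diagram <- ess_branch_diagram(game$model, config_m_grid(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_branch_csv(diagram,
                   file.path(config$out_dir, "branches.csv"),
                   file.path(config$out_dir, "bifurcations.csv"))
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 list(command = "bifurcate"))
  message("bifurcate: ", nrow(diagram$branches), " branch rows, ",
          nrow(diagram$bifurcations), " bifurcation(s) -> ",
          config$out_dir)
  invisible(diagram)
}

#' Solve the configured game and write the solution
#'
#' Computes the requested leader strategy (or all three) for the
#' configured model and writes `solution.csv`, `solution.json` and a run
#' manifest into the output directory.
#'
#' @param config a [read_run_config()] result, a path, or a named list.
#' @param strategy one of `"all"`, `"naive"`, `"nash"`, `"stackelberg"`.
#' @return For `"all"` a [seg_solve()] result; otherwise the single
#'   strategy record.  Invisibly.
#' @export
run_solve <- function(config, strategy = c("all", "naive", "nash",
                                           "stackelberg")) {
  strategy <- match.arg(strategy)
  config <- if (inherits(config, "run_config")) config
  else read_run_config(config)
  set.seed(config$seed)
  game <- build_game(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sol <- switch(strategy,
                all = seg_solve(game$problem, game$model),
                naive = naive_strategy(game$problem, game$model),
                nash = nash_solve(game$problem, game$model),
                stackelberg = stackelberg_solve(game$problem, game$model))
  if (strategy == "all") {
    write_seg_solution(sol, file.path(config$out_dir, "solution.csv"),
                       file.path(config$out_dir, "solution.json"))
    if (!isTRUE(sol$nash$converged))
      stop(structure(class = c("segsolve_convergence_error", "error",
                               "condition"),
                     list(message = "Nash iteration did not converge",
                          call = NULL)))
  } else {
    df <- data.frame(strategy = sol$strategy, m = sol$m,
                     u = paste(signif(sol$u, 10), collapse = ";"),
                     x = paste(signif(sol$x, 10), collapse = ";"),
                     Q = sol$Q, outcome = sol$outcome %||% NA_character_)
    write.csv(df, file.path(config$out_dir, "solution.csv"),
              row.names = FALSE)
    jsonlite::write_json(sort_keys(sol[setdiff(names(sol),
                                               c("history", "diagram"))]),
                         file.path(config$out_dir, "solution.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    if (!isTRUE(sol$converged %||% TRUE))
      stop(structure(class = c("segsolve_convergence_error", "error",
                               "condition"),
                     list(message = "solver did not converge",
                          call = NULL)))
  }
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 list(command = "solve", strategy = strategy))
  invisible(sol)
}
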