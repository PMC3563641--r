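#' Read and validate a run configuration
#'
#' Run configurations are YAML files (human-diffable key/value trees)
#' describing a complete discrimination setup: the rival models, parameter
#' values and boxes, the initial design and design space, the noise model,
#' the objective settings and the robustification settings. All referential
#' integrity violations are collected and reported at once.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  errors <- character(0)
  need <- function(field) {
    if (is.null(cfg[[field]])) errors <<- c(errors, paste0("missing field: ", field))
  }
  need("models"); need("design")
  models <- list()
  for (side in c("A", "B")) {
    nm <- cfg$models[[side]]
    if (is.null(nm)) { errors <- c(errors, paste0("models.", side, " missing")); next }
    m <- try(get_model(nm), silent = TRUE)
    if (inherits(m, "try-error"))
      errors <- c(errors, sprintf("models.%s: unknown model '%s'", side, nm))
    else models[[side]] <- m
  }
  for (side in c("A", "B")) {
    if (is.null(cfg$params[[side]]))
      errors <- c(errors, paste0("params.", side, " missing"))
  }
  for (side in names(models)) {
    m <- models[[side]]
    p <- cfg$params[[side]]
    if (!is.null(p)) {
      bad <- setdiff(names(p), m$parameters)
      if (length(bad))
        errors <- c(errors, sprintf("params.%s: unknown labels %s", side,
                                    paste(bad, collapse = ", ")))
      missing <- setdiff(m$parameters, names(p))
      if (length(missing))
        errors <- c(errors, sprintf("params.%s: missing labels %s", side,
                                    paste(missing, collapse = ", ")))
    }
    b <- cfg$boxes[[side]]
    if (!is.null(b)) {
      bad <- union(setdiff(names(b$lower), m$parameters),
                   setdiff(names(b$upper), m$parameters))
      if (length(bad))
        errors <- c(errors, sprintf("boxes.%s: unknown labels %s", side,
                                    paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$design) && length(models)) {
    sp <- unique(unlist(lapply(models, function(m) m$species)))
    bad <- setdiff(names(cfg$design$x0), sp)
    if (length(bad))
      errors <- c(errors, sprintf("design.x0: unknown species %s",
                                  paste(bad, collapse = ", ")))
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

config_design <- function(cfg) {
  d <- cfg$design
  intervals <- if (!is.null(d$intervals)) as.numeric(d$intervals)
               else rep(d$spacing, d$n_t)
  pert <- lapply(d$perturbations, function(p) unlist(p))
  experimental_design(intervals = intervals,
                      x0 = unlist(d$x0),
                      horizon = d$horizon %||% sum(intervals),
                      perturbations = pert %||% list(),
                      input_profile = d$input_profile,
                      design_x0 = d$design_x0 %||% character())
}

config_space <- function(cfg, design) {
  s <- cfg$space
  if (is.null(s)) stop("configuration has no 'space' section")
  design_space(
    n_t = s$n_t %||% length(design$intervals),
    x0_bounds = lapply(s$x0_bounds, as.numeric),
    interval_bounds = if (!is.null(s$interval_bounds))
      as.numeric(s$interval_bounds) else NULL,
    perturbation_bounds = lapply(s$perturbation_bounds, as.numeric),
    allowed_perturbation_indices = s$allowed_perturbation_indices %||% integer(),
    input_bounds = lapply(s$input_bounds, as.numeric))
}

config_objective <- function(cfg) {
  o <- cfg$objective %||% list()
  sv <- cfg$solver %||% list()
  step_from <- function(x, default) {
    if (is.null(x)) default
    else step_config(x$width, x$center, x$steepness %||% 10)
  }
  objective_config(
    variance = variance_model("homoscedastic", o$sigma %||% 1),
    step_dt = step_from(o$step_dt, step_config(1, 0.5)),
    step_p = step_from(o$step_p, step_config(0.1, 0.05)),
    symmetric = isTRUE(o$symmetric),
    settings = solver_settings(rel_tol = sv$rel_tol %||% 1e-8,
                               abs_tol = sv$abs_tol %||% 1e-10,
                               method = sv$method %||% "lsoda"))
}

config_boxes <- function(cfg) {
  out <- list()
  for (side in c("A", "B")) {
    b <- cfg$boxes[[side]]
    if (!is.null(b))
      out[[side]] <- parameter_box(unlist(b$lower), unlist(b$upper))
  }
  out
}

#' Execute a pipeline stage described by a run configuration
#'
#' Dispatches one of the named subcommands on a validated configuration and
#' writes its artifacts (JSON results, delimited matrices, a log line per
#' robust iteration) into `out_dir`. Every result records the seed and a
#' hash of the configuration for exact re-execution.
#'
#' @param config A `run_config` (or a path to one).
#' @param subcommand One of "simulate", "fit", "evaluate", "worstcase",
#'   "design", "robust", "histogram", "loftest".
#' @param out_dir Output directory (created if needed).
#' @param data_paths Optional character vector of dataset files (delimited
#'   text) for `fit` and `loftest`.
#' @return The computed result object, invisibly; artifacts on disk.
#' @export
run <- function(config, subcommand = c("simulate", "fit", "evaluate",
                                       "worstcase", "design", "robust",
                                       "histogram", "loftest"),
                out_dir = ".", data_paths = character()) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  modelA <- get_model(config$models$A)
  modelB <- get_model(config$models$B)
  pA <- unlist(config$params$A); pB <- unlist(config$params$B)
  design <- config_design(config)
  cfg <- config_objective(config)
  rob <- config$robust %||% list()
  seed <- rob$seed %||% 0
  provenance <- list(seed = seed,
                     config_hash = config_hash(config),
                     package_version = as.character(utils::packageVersion("discrimod")))
  out_json <- function(name, payload) {
    payload$provenance <- provenance
    jsonlite::write_json(payload, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result <- switch(
    subcommand,
    simulate = {
      traj <- simulate_design(modelA, pA, design, cfg$settings)
      write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
      write_trajectory_json(traj, file.path(out_dir, "trajectory.json"))
      out_json("simulate", list(model = modelA$name,
                                times = traj$times,
                                species = rownames(traj$values)))
      traj
    },
    evaluate = {
      J <- evaluate_design(modelA, modelB, pA, pB, design, cfg, details = TRUE)
      out_json("evaluate", list(objective = as.numeric(J),
                                weights = attr(J, "weights"),
                                per_point = attr(J, "per_point")))
      J
    },
    fit = {
      datasets <- lapply(data_paths, read_dataset)
      if (!length(datasets)) stop("fit requires data_paths")
      fit <- least_squares_fit(modelA, datasets, design, pA,
                               box = config_boxes(config)$A)
      out_json("fit", list(params = as.list(coef(fit)), ssr = fit$ssr,
                           converged = fit$converged,
                           n_points = fit$n_points))
      fit
    },
    worstcase = {
      wc <- worst_case_params(modelA, modelB, design, config_boxes(config),
                              pA, pB, cfg, n_starts = rob$n_starts %||% 5,
                              seed = seed)
      out_json("worstcase", list(objective = wc$objective,
                                 params_A = as.list(wc$params1),
                                 params_B = as.list(wc$params2),
                                 starts = wc$starts,
                                 all_start_values = wc$all_start_values))
      wc
    },
    design = {
      space <- config_space(config, design)
      opt <- optimal_design(modelA, modelB,
                            list(list(A = pA, B = pB)), space, design, cfg)
      export_design(opt$design, file.path(out_dir, "design"))
      out_json("design", list(objective = opt$value,
                              initial_objective = opt$initial_value,
                              omitted = opt$omitted))
      opt
    },
    robust = {
      space <- config_space(config, design)
      hm <- rob$homotopy %||% list()
      state <- robust_design(
        modelA, modelB, space, config_boxes(config), pA, pB, design, cfg,
        eps_stop = rob$eps_stop %||% 1e-3,
        max_iter = rob$max_iter %||% 50,
        homotopy = homotopy_config(isTRUE(hm$enabled), hm$n_steps %||% 3,
                                   hm$trigger_gap %||% 0.1),
        n_starts = rob$n_starts %||% 5, seed = seed, verbose = TRUE)
      robust_traces(state, file.path(out_dir, "robust_traces.tsv"))
      export_design(state$design, file.path(out_dir, "robust_design"))
      out_json("robust", list(iterations = state$iterations,
                              converged = state$stopped,
                              reason = state$reason,
                              J_design = state$J_design,
                              J_worst = state$J_worst,
                              gaps = state$gaps))
      state
    },
    histogram = {
      h <- kl_histogram(modelA, modelB, design, config_boxes(config), pA, pB,
                        cfg, n_draws = rob$n_draws %||% 1000,
                        n_bins = rob$n_bins %||% 100, seed = seed)
      write_histogram(h, file.path(out_dir, "histogram.tsv"))
      out_json("histogram", list(draws = h$draws,
                                 min_objective = h$min_objective,
                                 n_failed = h$n_failed))
      h
    },
    loftest = {
      datasets <- lapply(data_paths, read_dataset)
      if (length(datasets) < 2) stop("loftest requires >= 2 dataset paths")
      lof <- lack_of_fit_test(modelA, pA, datasets, design,
                              alpha = config$alpha %||% 0.05)
      out_json("loftest", list(f_statistic = as.list(lof$f_statistic),
                               df = c(lof$df_lof, lof$df_pure),
                               critical = lof$critical_value,
                               reject = as.list(lof$reject)))
      lof
    })
  invisible(result)
}

config_hash <- function(cfg) {
  raw <- serialize(unclass(cfg), NULL)
  # small stable checksum without extra dependencies
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% 4294967291)
}

#' Export / import an experimental design
#'
#' Writes both a lossless JSON representation (`<prefix>.json`) and a
#' human-readable plain-text dump in bracketed matrix notation
#' (`<prefix>.txt`) with one line per design component. `import_design` reads
#' the JSON back; the round trip is exact.
#'
#' @param design An [experimental_design()].
#' @param prefix Output path prefix.
#' @return `export_design` returns the prefix invisibly; `import_design`
#'   returns the design.
#' @export
export_design <- function(design, prefix) {
  jsonlite::write_json(
    list(intervals = design$intervals, x0 = as.list(design$x0),
         horizon = design$horizon,
         perturbations = lapply(design$perturbations, as.list),
         input_profile = design$input_profile,
         design_x0 = design$design_x0),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  fmt <- function(x) paste0("[", paste(format(x, digits = 15), collapse = ", "), "]")
  lines <- c(
    paste0("measurement_times = ", fmt(measurement_times(design)), ";"),
    paste0("intervals = ", fmt(design$intervals), ";"),
    paste0("x0 = ", fmt(unname(design$x0)), ";  % ",
           paste(names(design$x0), collapse = ", ")))
  for (nm in names(design$perturbations)) {
    p <- design$perturbations[[nm]]
    lines <- c(lines, paste0("perturbation_", nm, " = ", fmt(unname(p)),
                             ";  % ", paste(names(p), collapse = ", ")))
  }
  for (lab in names(design$input_profile)) {
    prof <- design$input_profile[[lab]]
    vals <- c(prof$initial, vapply(prof$changes, function(ch) ch$value, 0))
    lines <- c(lines, paste0("input_", lab, " = ", fmt(vals), ";"))
  }
  writeLines(lines, paste0(prefix, ".txt"))
  invisible(prefix)
}

#' @rdname export_design
#' @export
import_design <- function(prefix) {
  x <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = FALSE)
  pert <- lapply(x$perturbations, function(p) unlist(p))
  profile <- lapply(x$input_profile, function(prof) {
    list(initial = prof$initial,
         changes = lapply(prof$changes, function(ch)
           list(index = as.integer(ch$index), value = ch$value)))
  })
  experimental_design(intervals = unlist(x$intervals),
                      x0 = unlist(x$x0),
                      horizon = x$horizon,
                      perturbations = pert,
                      input_profile = if (length(profile)) profile else NULL,
                      design_x0 = as.character(unlist(x$design_x0)))
}
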