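#' Solver settings for the initial value problems
#'
#' @param rel_tol,abs_tol Relative and absolute integration tolerances, both
#'   in (0, 1).
#' @param sensitivity_method Either "finite_difference" (central differences
#'   of the simulated responses, the default) or "forward_ode" (forward
#'   sensitivity equations integrated alongside the states).
#' @param max_step Optional maximum integrator step size.
#' @param method deSolve integration method; "lsoda" switches automatically
#'   to a BDF scheme on stiff intervals.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                            sensitivity_method = c("finite_difference",
                                                   "forward_ode"),
                            max_step = NULL, method = "lsoda") {
  stopifnot(rel_tol > 0, rel_tol < 1, abs_tol > 0, abs_tol < 1)
  sensitivity_method <- match.arg(sensitivity_method)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 sensitivity_method = sensitivity_method,
                 max_step = max_step, method = method),
            class = "solver_settings")
}

# Current input values at (just after) measurement index i (0 = from t=0).
input_values_at <- function(design, model, after_index) {
  u <- stats::setNames(rep(NA_real_, length(model$inputs)), model$inputs)
  for (lab in model$inputs) {
    prof <- design$input_profile[[lab]]
    if (is.null(prof)) stop(sprintf("design provides no profile for input '%s'", lab))
    val <- prof$initial
    for (ch in prof$changes) if (ch$index <= after_index) val <- ch$value
    u[[lab]] <- val
  }
  # additive input step changes scheduled as perturbations
  for (key in names(design$perturbations)) {
    if (as.integer(key) > after_index) next
    p <- design$perturbations[[key]]
    for (tg in intersect(names(p), model$inputs)) u[[tg]] <- u[[tg]] + p[[tg]]
  }
  u
}

#' Simulate a model under an experimental design
#'
#' Integrates the model ODEs piecewise between event times. At each
#' measurement time the state is recorded; if a perturbation is scheduled at
#' the same index, the measurement is taken before the impulse is applied.
#' Species impulses increment the named state components; input entries in the
#' perturbation schedule shift the corresponding piecewise-constant input, and
#' `input_profile` changes switch the input to a new value from that
#' measurement time onwards.
#'
#' @param model A [kinetic_model()].
#' @param params Named parameter vector.
#' @param design An [experimental_design()]; `design$x0` must cover all model
#'   species.
#' @param settings A [solver_settings()].
#' @return A `trajectory_set`: list with `times`, `values` (matrix observed
#'   species x times), `states` (all species x times) and `meta`.
#' @export
simulate_design <- function(model, params, design,
                            settings = solver_settings()) {
  params <- check_params(model, params)
  if (!all(model$species %in% names(design$x0)))
    stop("design x0 must provide an initial value for every model species")
  x <- design$x0[model$species]
  times <- measurement_times(design)
  if (any(diff(times) < 0)) stop("measurement times must be nondecreasing")
  n <- length(times)
  states <- matrix(NA_real_, nrow = length(model$species), ncol = n,
                   dimnames = list(model$species, NULL))
  warn <- character(0)
  t_prev <- 0
  for (i in seq_len(n)) {
    u <- input_values_at(design, model, i - 1L)
    derivs <- function(t, y, parms) list(model$rhs(t, y, params, u))
    if (times[i] > t_prev + 1e-14) {
      args <- list(y = x, times = c(t_prev, times[i]), func = derivs,
                   parms = NULL, method = settings$method,
                   rtol = settings$rel_tol, atol = settings$abs_tol)
      if (!is.null(settings$max_step)) args$hmax <- settings$max_step
      sol <- try(do.call(deSolve::ode, args), silent = TRUE)
      if (inherits(sol, "try-error") ||
          any(!is.finite(sol[nrow(sol), -1])))
        stop(sprintf(
          "integration of model '%s' failed on interval [%g, %g]",
          model$name, t_prev, times[i]))
      x <- sol[nrow(sol), -1]
    }
    neg <- x < 0
    if (any(x < -10 * settings$abs_tol - 1e-12))
      warn <- c(warn, sprintf(
        "negative concentration beyond tolerance at t=%g (min %g)",
        times[i], min(x)))
    states[, i] <- x
    # measurement before impulse at coincident times
    pert <- design$perturbations[[as.character(i)]]
    if (!is.null(pert)) {
      for (sp in intersect(names(pert), model$species))
        x[[sp]] <- x[[sp]] + pert[[sp]]
    }
    t_prev <- times[i]
  }
  structure(list(times = times,
                 values = states[model$observed, , drop = FALSE],
                 states = states,
                 meta = list(model = model$name, params = params,
                             warnings = warn)),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: model '%s', %d species x %d times on [%g, %g]\n",
              x$meta$model, nrow(x$values), length(x$times),
              min(x$times), max(x$times)))
  if (length(x$meta$warnings))
    cat("  warnings:", paste(x$meta$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Convert a trajectory set to a data frame (time + one column per species)
#'
#' @param x A `trajectory_set`.
#' @param ... Unused.
#' @return A data.frame with a `time` column and one column per observed
#'   species.
#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  data.frame(time = x$times, t(x$values), check.names = FALSE)
}

#' Write / read a trajectory set as delimited text
#'
#' Plain tab-separated text: first column time, one column per observed
#' species.
#'
#' @param traj A `trajectory_set`.
#' @param path File path.
#' @return `write_trajectory` returns the path invisibly; `read_timeseries`
#'   returns a data.frame.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_timeseries <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Write a trajectory set as JSON
#'
#' Lossless JSON form: times, per-species value vectors, and the meta block
#' (model name, parameters, warnings).
#'
#' @param traj A `trajectory_set`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_trajectory_json <- function(traj, path) {
  vals <- lapply(rownames(traj$values), function(sp)
    as.vector(traj$values[sp, ]))
  names(vals) <- rownames(traj$values)
  jsonlite::write_json(
    list(times = traj$times, values = vals,
         meta = list(model = traj$meta$model,
                     params = as.list(traj$meta$params),
                     warnings = traj$meta$warnings)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sensitivities of the simulated responses
#'
#' Derivatives of the observed trajectories with respect to parameters and/or
#' initial values. The default central finite differences perturb each
#' variable by `h = eps * max(1, |v|)` and re-simulate; the forward-ODE
#' method integrates the sensitivity equations ds/dt = (df/dx) s + df/dv
#' alongside the states, with the local Jacobians evaluated by central
#' differences of the right-hand side.
#'
#' @param model A [kinetic_model()].
#' @param params Named parameter vector.
#' @param design An [experimental_design()].
#' @param settings A [solver_settings()]; `sensitivity_method` selects the
#'   scheme.
#' @param wrt Character vector of parameter labels and/or `"x0:<species>"`
#'   entries.
#' @param eps Relative finite-difference step.
#' @return 3-d array (observed species x times x variables).
#' @export
trajectory_sensitivities <- function(model, params, design,
                                     settings = solver_settings(),
                                     wrt = model$parameters, eps = 1e-6) {
  params <- check_params(model, params)
  is_x0 <- startsWith(wrt, "x0:")
  bad <- wrt[!is_x0 & !(wrt %in% model$parameters)]
  bad <- c(bad, wrt[is_x0][!sub("^x0:", "", wrt[is_x0]) %in% model$species])
  if (length(bad)) stop("unknown sensitivity variables: ",
                        paste(bad, collapse = ", "))
  if (settings$sensitivity_method == "forward_ode")
    return(forward_sensitivities(model, params, design, settings, wrt))
  base <- simulate_design(model, params, design, settings)
  out <- array(NA_real_, dim = c(nrow(base$values), ncol(base$values),
                                 length(wrt)),
               dimnames = list(rownames(base$values), NULL, wrt))
  for (j in seq_along(wrt)) {
    v <- wrt[j]
    bump <- function(delta) {
      p <- params; d <- design
      if (is_x0[j]) {
        sp <- sub("^x0:", "", v); d$x0[[sp]] <- d$x0[[sp]] + delta
      } else p[[v]] <- p[[v]] + delta
      simulate_design(model, p, d, settings)$values
    }
    v0 <- if (is_x0[j]) design$x0[[sub("^x0:", "", v)]] else params[[v]]
    h <- eps * max(1, abs(v0))
    out[, , j] <- (bump(h) - bump(-h)) / (2 * h)
  }
  out
}

# Forward sensitivity equations: augment the state with one sensitivity
# column per requested variable; Jacobian-vector products via central
# differences of the rhs (the rhs is cheap relative to integration).
forward_sensitivities <- function(model, params, design, settings, wrt) {
  ns <- length(model$species)
  nv <- length(wrt)
  is_x0 <- startsWith(wrt, "x0:")
  times <- measurement_times(design)
  x <- design$x0[model$species]
  S <- matrix(0, ns, nv)
  for (j in which(is_x0))
    S[match(sub("^x0:", "", wrt[j]), model$species), j] <- 1
  out <- array(NA_real_, dim = c(ns, length(times), nv),
               dimnames = list(model$species, NULL, wrt))
  t_prev <- 0
  hx <- 1e-7
  for (i in seq_along(times)) {
    u <- input_values_at(design, model, i - 1L)
    aug_rhs <- function(t, y, parms) {
      xx <- y[1:ns]
      SS <- matrix(y[-(1:ns)], ns, nv)
      f0 <- model$rhs(t, xx, params, u)
      dS <- matrix(0, ns, nv)
      for (j in seq_len(nv)) {
        s <- SS[, j]
        sn <- sqrt(sum(s^2))
        jvp <- if (sn > 0) {
          h <- hx * max(1, sqrt(sum(xx^2))) / sn
          (model$rhs(t, xx + h * s, params, u) -
             model$rhs(t, xx - h * s, params, u)) / (2 * h)
        } else rep(0, ns)
        fp <- if (is_x0[j]) rep(0, ns) else {
          v <- wrt[j]
          hp <- hx * max(1, abs(params[[v]]))
          p1 <- params; p1[[v]] <- p1[[v]] + hp
          p2 <- params; p2[[v]] <- p2[[v]] - hp
          (model$rhs(t, xx, p1, u) - model$rhs(t, xx, p2, u)) / (2 * hp)
        }
        dS[, j] <- jvp + fp
      }
      list(c(f0, as.vector(dS)))
    }
    if (times[i] > t_prev + 1e-14) {
      sol <- deSolve::ode(y = c(x, as.vector(S)), times = c(t_prev, times[i]),
                          func = aug_rhs, parms = NULL,
                          method = settings$method,
                          rtol = settings$rel_tol,
                          atol = settings$abs_tol)
      y <- sol[nrow(sol), -1]
      x <- stats::setNames(y[1:ns], model$species)
      S <- matrix(y[-(1:ns)], ns, nv)
    }
    out[, i, ] <- S
    pert <- design$perturbations[[as.character(i)]]
    if (!is.null(pert))
      for (sp in intersect(names(pert), model$species))
        x[[sp]] <- x[[sp]] + pert[[sp]]
    t_prev <- times[i]
  }
  out[model$observed, , , drop = FALSE]
}
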