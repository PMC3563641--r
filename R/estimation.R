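#' Box constraints for model parameters
#'
#' @param lower,upper Named numeric vectors (same names); elementwise
#'   `lower <= upper`.
#' @return An object of class `parameter_box`.
#' @export
parameter_box <- function(lower, upper) {
  if (is.null(names(lower)) || !identical(sort(names(lower)), sort(names(upper))))
    stop("lower and upper must be named identically")
  upper <- upper[names(lower)]
  if (any(lower > upper)) stop("lower must not exceed upper")
  structure(list(lower = lower, upper = upper), class = "parameter_box")
}

box_midpoint <- function(box) (box$lower + box$upper) / 2

box_draw <- function(box) {
  stats::setNames(stats::runif(length(box$lower), box$lower, box$upper),
                  names(box$lower))
}

#' Least-squares fit of a kinetic model to replicated datasets
#'
#' Minimizes the summed squared residuals (data minus simulated response)
#' over all datasets simultaneously, subject to box constraints, with a
#' Levenberg-Marquardt local optimizer. Residuals can optionally be weighted
#' by 1/(sigma |value|) for relative-error data.
#'
#' @param model A [kinetic_model()].
#' @param datasets List of datasets (see [generate_data()]); each needs
#'   `times`, `species` and a values matrix (species x times).
#' @param design The [experimental_design()] under which the data were (or
#'   are assumed to have been) collected; supplies initial values, inputs and
#'   perturbations for the simulation.
#' @param init Named initial parameter vector.
#' @param box Optional [parameter_box()] (defaults to `[0, Inf)` per
#'   parameter).
#' @param fixed Character vector of parameter labels held at their `init`
#'   values.
#' @param weighting "none" (homoscedastic, the default) or "relative"
#'   (residuals scaled by 1/(sigma |data|), for relative-error noise).
#' @param sigma Noise scale used by the relative weighting.
#' @param settings [solver_settings()].
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `kinetic_fit` with components `params`, `ssr`,
#'   `n_points`, `converged`, `per_dataset_residuals`, and supporting
#'   metadata; methods: `coef`, `print`, `summary`, `residuals`, `predict`,
#'   `simulate`.
#' @export
least_squares_fit <- function(model, datasets, design, init, box = NULL,
                              fixed = character(), weighting = c("none", "relative"),
                              sigma = 1, settings = solver_settings(),
                              control = minpack.lm::nls.lm.control(maxiter = 200)) {
  weighting <- match.arg(weighting)
  init <- check_params(model, init)
  if (is.null(box))
    box <- parameter_box(
      stats::setNames(rep(0, length(model$parameters)), model$parameters),
      stats::setNames(rep(Inf, length(model$parameters)), model$parameters))
  free <- setdiff(model$parameters, fixed)
  if (!length(free)) stop("no free parameters to fit")
  if (any(init[free] < box$lower[free] - 1e-12) ||
      any(init[free] > box$upper[free] + 1e-12))
    stop("init must lie inside the box")
  for (d in datasets) {
    if (!all(d$species %in% model$observed))
      stop("dataset species must be observed species of the model")
  }
  resid_fn <- function(theta_free) {
    p <- init
    p[free] <- theta_free
    res <- lapply(datasets, function(d) {
      sim <- simulate_design(model, p, design, settings)
      pred <- sim$values[d$species, , drop = FALSE]
      if (!isTRUE(all.equal(sim$times, d$times, tolerance = 1e-8)))
        stop("dataset time grid does not match the design")
      r <- d$values - pred
      if (weighting == "relative")
        r <- r / (sigma * pmax(abs(d$values), 1e-12))
      r
    })
    unlist(res, use.names = FALSE)
  }
  fit <- try(minpack.lm::nls.lm(par = init[free], fn = resid_fn,
                                lower = box$lower[free],
                                upper = box$upper[free],
                                control = control),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    params <- init
    converged <- FALSE
    ssr <- sum(resid_fn(init[free])^2)
    info <- NA_integer_
  } else {
    params <- init
    params[free] <- fit$par
    converged <- fit$info %in% 1:4
    ssr <- fit$deviance
    info <- fit$info
  }
  per_ds <- lapply(datasets, function(d) {
    sim <- simulate_design(model, params, design, settings)
    d$values - sim$values[d$species, , drop = FALSE]
  })
  structure(list(params = params, ssr = ssr,
                 n_points = sum(vapply(datasets, function(d) length(d$values), 0L)),
                 converged = converged, info = info,
                 per_dataset_residuals = per_ds,
                 free = free, fixed = fixed, box = box,
                 model = model, design = design, datasets = datasets,
                 weighting = weighting, sigma = sigma, settings = settings),
            class = "kinetic_fit")
}

#' @export
coef.kinetic_fit <- function(object, ...) object$params

#' @export
residuals.kinetic_fit <- function(object, ...) object$per_dataset_residuals

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Least-squares fit of model '%s' (%d datasets, %d points)\n",
              x$model$name, length(x$datasets), x$n_points))
  cat(sprintf("  ssr = %.6g, converged = %s\n", x$ssr, x$converged))
  cat("  estimates:\n")
  print(signif(x$params, 5))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  res <- unlist(object$per_dataset_residuals)
  structure(list(fit = object,
                 sigma_hat = sqrt(object$ssr /
                                    max(1, object$n_points - length(object$free))),
                 residual_range = range(res)),
            class = "summary.kinetic_fit")
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd (ssr-based): %.5g\n", x$sigma_hat))
  cat(sprintf("  residual range: [%.5g, %.5g]\n",
              x$residual_range[1], x$residual_range[2]))
  invisible(x)
}

#' @export
predict.kinetic_fit <- function(object, design = object$design, ...) {
  simulate_design(object$model, object$params, design, object$settings)
}

#' Simulate new replicate datasets from a fitted model
#'
#' @param object A `kinetic_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed RNG seed.
#' @param noise A [noise_model()]; defaults to additive noise at the fit's
#'   residual standard deviation.
#' @param ... Unused.
#' @return A list of datasets (see [generate_data()]).
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = 0, noise = NULL, ...) {
  if (is.null(noise)) {
    s <- summary(object)$sigma_hat
    noise <- noise_model("additive", sigma = max(s, .Machine$double.eps))
  }
  generate_data(object$model, object$params, object$design, noise,
                n_datasets = nsim, seed = seed, settings = object$settings)
}

#' Worst-case (discrimination-minimizing) parameter estimation
#'
#' For a fixed design, finds parameters of the free model(s), inside their
#' boxes, that minimize the discrimination objective, i.e. produce the most
#' similar model responses. Multistart local optimization (L-BFGS-B): the
#' first start is the supplied `init` (or the box midpoint), the remaining
#' starts are uniform draws inside the boxes under the given seed.
#'
#' @param modelA,modelB [kinetic_model()]s.
#' @param design An [experimental_design()].
#' @param boxes List with entries `A` and/or `B`, each a [parameter_box()]
#'   over the free parameters of that model.
#' @param paramsA,paramsB Full named parameter vectors (fixed values; entries
#'   covered by a box are overwritten by the optimizer).
#' @param objective_cfg An [objective_config()].
#' @param n_starts Number of multistarts (>= 1).
#' @param seed RNG seed for the random starts.
#' @param init Optional named list `A`/`B` of start values for the free
#'   parameters.
#' @return An object of class `worst_case`: `params1`, `params2`, `objective`,
#'   `starts`, `all_start_values`.
#' @export
worst_case_params <- function(modelA, modelB, design, boxes, paramsA, paramsB,
                              objective_cfg = objective_config(),
                              n_starts = 5, seed = 0, init = NULL) {
  stopifnot(n_starts >= 1)
  freeA <- if (!is.null(boxes$A)) names(boxes$A$lower) else character()
  freeB <- if (!is.null(boxes$B)) names(boxes$B$lower) else character()
  if (!length(freeA) && !length(freeB))
    stop("at least one model needs a parameter box")
  lower <- c(if (length(freeA)) boxes$A$lower, if (length(freeB)) boxes$B$lower)
  upper <- c(if (length(freeA)) boxes$A$upper, if (length(freeB)) boxes$B$upper)
  nA <- length(freeA)
  obj <- function(theta) {
    pA <- paramsA; pB <- paramsB
    if (nA) pA[freeA] <- theta[seq_len(nA)]
    if (length(freeB)) pB[freeB] <- theta[(nA + 1):length(theta)]
    val <- try(evaluate_design(modelA, modelB, pA, pB, design, objective_cfg),
               silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e12 else val
  }
  set.seed(seed)
  start0 <- if (!is.null(init)) {
    c(if (nA) init$A[freeA], if (length(freeB)) init$B[freeB])
  } else (lower + upper) / 2
  starts <- list(pmin(pmax(start0, lower), upper))
  if (n_starts > 1)
    for (s in 2:n_starts)
      starts[[s]] <- stats::setNames(stats::runif(length(lower), lower, upper),
                                     names(lower))
  degenerate <- all(upper - lower < 1e-14)
  results <- lapply(starts, function(th0) {
    if (degenerate) return(list(par = th0, value = obj(th0), ok = TRUE))
    fit <- try(stats::optim(th0, obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 300)),
               silent = TRUE)
    if (inherits(fit, "try-error")) list(par = th0, value = obj(th0), ok = FALSE)
    else list(par = fit$par, value = fit$value, ok = TRUE)
  })
  if (!any(vapply(results, function(r) r$ok, TRUE)))
    stop("all worst-case starts failed")
  vals <- vapply(results, function(r) r$value, 0)
  best <- results[[which.min(vals)]]
  pA <- paramsA; pB <- paramsB
  if (nA) pA[freeA] <- best$par[seq_len(nA)]
  if (length(freeB)) pB[freeB] <- best$par[(nA + 1):length(best$par)]
  structure(list(params1 = pA, params2 = pB, objective = best$value,
                 starts = n_starts, all_start_values = vals,
                 free = list(A = freeA, B = freeB), seed = seed),
            class = "worst_case")
}

#' @export
print.worst_case <- function(x, ...) {
  cat(sprintf("Worst-case parameters (best of %d starts): objective = %.6g\n",
              x$starts, x$objective))
  if (length(x$free$A)) {
    cat("  model A:\n"); print(signif(x$params1[x$free$A], 5))
  }
  if (length(x$free$B)) {
    cat("  model B:\n"); print(signif(x$params2[x$free$B], 5))
  }
  invisible(x)
}
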