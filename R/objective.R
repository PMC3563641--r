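#' Smooth step (tanh-approximated Heaviside) configuration
#'
#' The discrimination objective weights each measurement point with smooth
#' Heaviside approximations: a rising step in the preceding time interval
#' suppresses measurements closer together than a minimum interval, and a
#' falling step in the perturbation magnitude suppresses measuring while
#' perturbing. The exact Heaviside is approximated by
#' 1/2 (1 + tanh(steepness (x - center) / width)), which tends to the exact
#' step as the steepness grows.
#'
#' @param width Positive scale of the transition region (time units for the
#'   interval step, perturbation units for the perturbation step).
#' @param center Location of the half-height point.
#' @param steepness Positive dimensionless tanh scale (default 10).
#' @return An object of class `step_config`.
#' @export
step_config <- function(width, center, steepness = 10) {
  stopifnot(width > 0, steepness > 0)
  structure(list(width = width, center = center, steepness = steepness),
            class = "step_config")
}

#' Smooth rising step
#'
#' @param x Numeric vector.
#' @param cfg A [step_config()].
#' @return Values in (0, 1); 0.5 at `x == cfg$center`, monotone nondecreasing.
#' @export
smooth_step <- function(x, cfg) {
  0.5 * (1 + tanh(cfg$steepness * (x - cfg$center) / cfg$width))
}

#' Measurement weight of a single time point
#'
#' Product of a rising smooth step in the preceding time interval (disabling
#' intervals below the minimum measurement spacing) and a falling smooth step
#' in the perturbation magnitude (disabling simultaneous measurement and
#' perturbation).
#'
#' @param dt_interval Nonnegative time interval preceding the measurement.
#' @param pert_magnitudes Numeric vector of perturbation magnitudes scheduled
#'   at the measurement (possibly empty).
#' @param cfg_dt [step_config()] for the interval step.
#' @param cfg_p [step_config()] for the perturbation step.
#' @return Weight in [0, 1].
#' @export
measurement_weight <- function(dt_interval, pert_magnitudes, cfg_dt, cfg_p) {
  p <- sqrt(sum(pert_magnitudes^2))
  smooth_step(dt_interval, cfg_dt) * (1 - smooth_step(p, cfg_p))
}

#' Variance model of the measurement noise
#'
#' @param kind "homoscedastic" (single sigma for both models) or "per_model"
#'   (two variance functions of time).
#' @param sigma Positive standard deviation (homoscedastic).
#' @param var1,var2 Functions of time returning the variances of model 1 and
#'   model 2 (per_model).
#' @return An object of class `variance_model`.
#' @export
variance_model <- function(kind = c("homoscedastic", "per_model"),
                           sigma = 1, var1 = NULL, var2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "homoscedastic") {
    stopifnot(sigma > 0)
  } else {
    stopifnot(is.function(var1), is.function(var2))
  }
  structure(list(kind = kind, sigma = sigma, var1 = var1, var2 = var2),
            class = "variance_model")
}

#' Bundle the objective settings
#'
#' @param variance A [variance_model()].
#' @param step_dt [step_config()] for the minimum-interval weight.
#' @param step_p [step_config()] for the perturbation weight.
#' @param symmetric Use the symmetrized criterion (sum of both directed
#'   divergences)?
#' @param settings [solver_settings()] used when the objective has to
#'   simulate.
#' @param custom Optional function `(design, paramsA, paramsB) -> numeric`
#'   replacing the simulate-and-compare objective entirely; an extension hook
#'   used for closed-form test problems and research variants.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(variance = variance_model("homoscedastic", 1),
                             step_dt = step_config(width = 1, center = 0.5),
                             step_p = step_config(width = 0.1, center = 0.05),
                             symmetric = FALSE,
                             settings = solver_settings(),
                             custom = NULL) {
  structure(list(variance = variance, step_dt = step_dt, step_p = step_p,
                 symmetric = symmetric, settings = settings, custom = custom),
            class = "objective_config")
}

kl_terms <- function(eta1, eta2, var, times) {
  if (var$kind == "homoscedastic") {
    (eta1 - eta2)^2 / (2 * var$sigma^2)
  } else {
    v1 <- outer(rep(1, nrow(eta1)), vapply(times, var$var1, 0))
    v2 <- outer(rep(1, nrow(eta1)), vapply(times, var$var2, 0))
    if (any(v1 <= 0) || any(v2 <= 0)) stop("variances must be positive")
    0.5 * (log(v2 / v1) + v1 / v2 + (eta1 - eta2)^2 / v2 - 1)
  }
}

#' KL-divergence discrimination objective for two trajectory sets
#'
#' Sum over species and measurement points of the pointwise Gaussian
#' Kullback-Leibler term, each time point weighted by the product of the
#' minimum-interval step and the perturbation step. In the homoscedastic case
#' the term reduces to the squared model difference over twice the variance,
#' so the criterion is the (scaled) sum of squared differences; in the
#' per-model case the directed Gaussian KL term
#' 1/2 (log(v2/v1) + v1/v2 + (eta1 - eta2)^2 / v2 - 1) is used, which is
#' non-symmetric in the model ordering.
#'
#' @param traj1,traj2 `trajectory_set`s sharing times and observed species
#'   (model 1 is the divergence's first argument).
#' @param design The [experimental_design()] that produced them (supplies the
#'   intervals and the perturbation schedule for the weights).
#' @param var A [variance_model()].
#' @param steps List with elements `dt` and `p`, each a [step_config()].
#' @param details Return the per-point breakdown as attributes?
#' @return Nonnegative scalar (homoscedastic case; the per-model directed KL
#'   term is nonnegative as well).
#' @export
discrimination_objective <- function(traj1, traj2, design, var, steps,
                                     details = FALSE) {
  if (length(traj1$times) != length(traj2$times) ||
      any(abs(traj1$times - traj2$times) > 1e-9))
    stop("trajectory sets must share the measurement time grid")
  if (!identical(rownames(traj1$values), rownames(traj2$values)))
    stop("trajectory sets must share the observed species")
  pnorm_ <- perturbation_norms(design)
  w <- vapply(seq_along(design$intervals), function(i)
    measurement_weight(design$intervals[i], pnorm_[i], steps$dt, steps$p), 0)
  terms <- kl_terms(traj1$values, traj2$values, var, traj1$times)
  per_point <- colSums(terms)
  J <- sum(w * per_point)
  if (details) {
    attr(J, "weights") <- w
    attr(J, "per_point") <- per_point
  }
  J
}

#' Symmetrized discrimination objective
#'
#' Sum of the two directed criteria, invariant under swapping the models; in
#' the homoscedastic case it equals twice the directed value.
#'
#' @inheritParams discrimination_objective
#' @return Nonnegative scalar.
#' @export
symmetric_objective <- function(traj1, traj2, design, var, steps) {
  var_swapped <- var
  if (var$kind == "per_model") {
    var_swapped$var1 <- var$var2
    var_swapped$var2 <- var$var1
  }
  discrimination_objective(traj1, traj2, design, var, steps) +
    discrimination_objective(traj2, traj1, design, var_swapped, steps)
}

#' Evaluate the discrimination objective for a model pair under a design
#'
#' Simulates both models and applies the configured (possibly symmetrized)
#' criterion; the single funnel used by the worst-case estimator, the design
#' optimizer and the robust loop. If `cfg$custom` is set it is called instead
#' with `(design, paramsA, paramsB)`.
#'
#' @param modelA,modelB [kinetic_model()]s.
#' @param paramsA,paramsB Named parameter vectors.
#' @param design An [experimental_design()].
#' @param cfg An [objective_config()].
#' @param details Passed to [discrimination_objective()] (ignored when
#'   symmetric or custom).
#' @return Scalar objective value.
#' @export
evaluate_design <- function(modelA, modelB, paramsA, paramsB, design, cfg,
                            details = FALSE) {
  if (!is.null(cfg$custom)) return(cfg$custom(design, paramsA, paramsB))
  t1 <- simulate_design(modelA, paramsA, design, cfg$settings)
  t2 <- simulate_design(modelB, paramsB, design, cfg$settings)
  steps <- list(dt = cfg$step_dt, p = cfg$step_p)
  if (cfg$symmetric)
    symmetric_objective(t1, t2, design, cfg$variance, steps)
  else
    discrimination_objective(t1, t2, design, cfg$variance, steps,
                             details = details)
}
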