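#' The hysteretic-enzyme data-generation design
#'
#' Twenty-six measurement points at ten-time-unit spacing (duration 260),
#' no perturbations. The default substrate and enzyme initial concentrations
#' were chosen once by a Fisher-information scan over candidate initials:
#' they produce clearly sigmoidal substrate and product curves, keep the
#' active-branch binding/catalysis crossover (substrate passing the effective
#' Michaelis constant of the active conformation) inside the observation
#' window, and give the most balanced attainable information about the two
#' dominant rate constants.
#'
#' @param S0 Initial substrate concentration.
#' @param E0 Initial (inactive) enzyme concentration.
#' @param n_points Number of measurement points.
#' @param spacing Time between measurements.
#' @return An [experimental_design()].
#' @export
hysteretic_design <- function(S0 = 1, E0 = 0.02, n_points = 26, spacing = 10) {
  experimental_design(
    intervals = rep(spacing, n_points),
    x0 = c(S = S0, Ei = E0, Ea = 0, EiS = 0, EaS = 0, P = 0))
}

#' Low-noise parameter recovery experiment for the hysteretic enzyme
#'
#' Generates five replicate datasets from the hysteretic model at its true
#' rate constants under the sigmoid-producing design (additive Gaussian noise
#' with a standard deviation of 1 percent of the overall signal range of the
#' observed species),
#' then refits all ten parameters by box-constrained least squares from a
#' start perturbed uniformly by up to 20 percent around the truth.
#'
#' @param seed RNG seed controlling both the noise and the start perturbation.
#' @param sigma_frac Noise standard deviation as a fraction of the overall
#'   signal range of the observed species.
#' @param n_datasets Number of replicates.
#' @param init_spread Relative half-width of the uniform start perturbation.
#' @param design The data-generation design.
#' @return List: `fit` (a `kinetic_fit`), `truth`, `estimates`, `datasets`,
#'   `sigma`, `design`.
#' @export
recovery_experiment <- function(seed = 0, sigma_frac = 0.01, n_datasets = 5,
                                init_spread = 0.2,
                                design = hysteretic_design()) {
  model <- get_model("hysteretic_enzyme")
  truth <- hysteretic_true_params()
  clean <- simulate_design(model, truth, design)
  sigma <- sigma_frac * diff(range(clean$values))
  datasets <- generate_data(model, truth, design,
                            noise_model("additive", sigma),
                            n_datasets = n_datasets, seed = seed)
  set.seed(seed + 1L)
  init <- truth * stats::runif(length(truth), 1 - init_spread, 1 + init_spread)
  box <- parameter_box(
    stats::setNames(rep(0, length(truth)), names(truth)),
    stats::setNames(rep(Inf, length(truth)), names(truth)))
  fit <- least_squares_fit(model, datasets, design, init, box)
  list(fit = fit, truth = truth, estimates = coef(fit), datasets = datasets,
       sigma = sigma, design = design, init = init)
}

#' A closed-form saddle problem for exercising the robust loop
#'
#' Builds a one-variable design problem with the custom objective
#' J(xi, theta) = (xi - theta)^2 + xi on xi, theta in [0, 1]: the inner
#' minimum over theta is at theta = xi with value xi, so the max-min optimum
#' is xi* = 1 with J* = 1. Returns the models, boxes, space, nominal
#' parameters, initial design and objective configuration ready to pass to
#' [robust_design()], [worst_case_params()] or [optimal_design()].
#'
#' @param xi0 Initial design variable value.
#' @return List with components `modelA`, `modelB`, `space`, `boxes`,
#'   `paramsA`, `paramsB`, `init_design`, `cfg`.
#' @export
saddle_problem <- function(xi0 = 0.2) {
  dummy <- kinetic_model(
    name = "saddle_dummy", species = "x", parameters = "theta",
    rhs = function(t, x, p, u) 0)
  init <- experimental_design(intervals = c(0.5, 0.5),
                              x0 = c(x = xi0), design_x0 = "x")
  space <- design_space(n_t = 2, x0_bounds = list(x = c(0, 1)))
  cfg <- objective_config(custom = function(design, pA, pB) {
    xi <- design$x0[["x"]]
    (xi - pA[["theta"]])^2 + xi
  })
  list(modelA = dummy, modelB = dummy, space = space,
       boxes = list(A = parameter_box(c(theta = 0), c(theta = 1))),
       paramsA = c(theta = 0.5), paramsB = c(theta = 0.5),
       init_design = init, cfg = cfg)
}
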