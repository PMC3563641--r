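#' Epigraph reformulation of the finite max-min design problem
#'
#' Maximizing the minimum of finitely many objectives is equivalent to
#' maximizing an auxiliary level s subject to J(design; pair_j) >= s for
#' every pair j. This helper builds that problem: `eval_all` returns the
#' vector of per-pair objectives at a design, `eval_min` their minimum (the
#' epigraph optimum's level by construction), and `weights` allows a homotopy
#' blend that introduces new pairs gradually.
#'
#' @param modelA,modelB [kinetic_model()]s.
#' @param param_pairs Nonempty list of `list(A = paramsA, B = paramsB)` pairs.
#' @param objective_cfg An [objective_config()].
#' @param weights Optional blend weights in [0, 1], one per pair; a pair with
#'   weight w contributes w * J_pair + (1 - w) * (min over fully weighted
#'   pairs), so w = 0 leaves it inert and w = 1 enforces it fully.
#' @return An object of class `epigraph_problem`.
#' @export
epigraph_reformulation <- function(modelA, modelB, param_pairs,
                                   objective_cfg = objective_config(),
                                   weights = NULL) {
  stopifnot(length(param_pairs) >= 1)
  if (is.null(weights)) weights <- rep(1, length(param_pairs))
  stopifnot(length(weights) == length(param_pairs),
            all(weights >= 0), all(weights <= 1))
  eval_all <- function(design) {
    vapply(param_pairs, function(pr)
      evaluate_design(modelA, modelB, pr$A, pr$B, design, objective_cfg), 0)
  }
  eval_min <- function(design) {
    J <- eval_all(design)
    full <- weights >= 1 - 1e-12
    base <- if (any(full)) min(J[full]) else max(J)
    min(base, if (any(!full)) min(weights[!full] * J[!full] +
                                    (1 - weights[!full]) * base) else Inf)
  }
  structure(list(eval_all = eval_all, eval_min = eval_min,
                 n_pairs = length(param_pairs), weights = weights),
            class = "epigraph_problem")
}

#' Optimal experimental design for model discrimination
#'
#' Phase-two maximization: finds a feasible design that locally maximizes the
#' minimum, over the supplied parameter pairs, of the discrimination
#' objective, subject to the fixed-horizon equality on the measurement
#' intervals and the box constraints of the design space. For a single pair
#' this is plain maximization of the criterion. Free design variables are
#' optimized with L-BFGS-B on their boxes; the interval equality is enforced
#' by smooth rescaling onto the simplex sum(dt) = horizon.
#'
#' @param modelA,modelB [kinetic_model()]s.
#' @param param_pairs List of `list(A=, B=)` parameter pairs (nonempty).
#' @param space A [design_space()].
#' @param init A feasible [experimental_design()] start.
#' @param objective_cfg An [objective_config()].
#' @param solver_opts List: `maxit` (default 200), `factr`-style convergence is
#'   left to `optim` defaults.
#' @param weights Optional homotopy blend weights, one per pair (see
#'   [epigraph_reformulation()]).
#' @return List with `design` (feasible local maximizer), `value` (the min
#'   over pairs at that design), `initial_value`, and `omitted` (indices of
#'   measurement points whose weight fell below 0.01, reported as omitted
#'   measurements).
#' @export
optimal_design <- function(modelA, modelB, param_pairs, space, init,
                           objective_cfg = objective_config(),
                           solver_opts = list(maxit = 200),
                           weights = NULL) {
  stopifnot(length(param_pairs) >= 1)
  feas <- design_feasible(init, space)
  if (!isTRUE(feas))
    stop("initial design infeasible: ", paste(feas, collapse = "; "))
  prob <- epigraph_reformulation(modelA, modelB, param_pairs, objective_cfg,
                                 weights)
  layout <- design_layout(init, space)
  J0 <- prob$eval_min(init)
  if (layout$n == 0L)
    return(finish_design(init, J0, J0, prob, objective_cfg))
  vec <- design_to_vector(init, space, layout)
  tight <- vec$upper - vec$lower < 1e-14
  if (all(tight))
    return(finish_design(init, J0, J0, prob, objective_cfg))
  obj <- function(v) {
    d <- vector_to_design(v, init, space, layout)
    val <- try(prob$eval_min(d), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) return(1e12)
    -val
  }
  fit <- try(stats::optim(vec$v, obj, method = "L-BFGS-B",
                          lower = vec$lower, upper = vec$upper,
                          control = list(
                            maxit = solver_opts$maxit %||% 200,
                            parscale = pmax(abs(vec$v),
                                            (vec$upper - vec$lower) / 10,
                                            1e-8))),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    warning("design optimization failed; returning the initial design")
    return(finish_design(init, J0, J0, prob, objective_cfg))
  }
  cand <- vector_to_design(fit$par, init, space, layout)
  Jc <- prob$eval_min(cand)
  # monotone safeguard: never return a design worse than the feasible start
  if (!is.finite(Jc) || Jc < J0) {
    cand <- init; Jc <- J0
  }
  finish_design(cand, Jc, J0, prob, objective_cfg)
}

finish_design <- function(design, value, initial_value, prob, cfg) {
  pn <- perturbation_norms(design)
  w <- vapply(seq_along(design$intervals), function(i)
    measurement_weight(design$intervals[i], pn[i], cfg$step_dt, cfg$step_p), 0)
  list(design = design, value = value, initial_value = initial_value,
       per_pair = try(prob$eval_all(design), silent = TRUE),
       weights = w, omitted = which(w < 0.01))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
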