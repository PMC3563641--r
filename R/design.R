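#' Construct an experimental design
#'
#' An experimental design collects everything the experimenter controls: the
#' initial concentrations, the measurement time intervals (the i-th
#' measurement is taken at the cumulative sum of the first i intervals; time 0
#' is not a measurement point), an impulsive perturbation schedule tied to
#' measurement indices, and piecewise-constant external-input profiles whose
#' switch times ride on the measurement grid. The experimental duration
#' (horizon) is fixed: the intervals must sum to it.
#'
#' @param intervals Numeric vector of nonnegative time intervals between
#'   consecutive measurement points.
#' @param x0 Named numeric vector of initial concentrations for all species.
#' @param horizon Total experimental duration; defaults to `sum(intervals)`.
#' @param perturbations Named list: names are measurement indices (as
#'   character), values are named numeric vectors mapping species labels to
#'   impulsive concentration increments and/or input labels to additive step
#'   changes applied at that measurement time (after the measurement is
#'   recorded).
#' @param input_profile Named list: one entry per external input, each a list
#'   with `initial` (value from time 0) and optionally `changes`, a list of
#'   `list(index =, value =)` giving the new value that takes effect at the
#'   time of that measurement index.
#' @param design_x0 Character vector naming the species whose initial value is
#'   a design variable (the rest are fixed).
#'
#' @return An object of class `experimental_design`.
#' @export
experimental_design <- function(intervals, x0, horizon = sum(intervals),
                                perturbations = list(),
                                input_profile = NULL,
                                design_x0 = character()) {
  intervals <- as.numeric(intervals)
  if (any(intervals < 0)) stop("intervals must be nonnegative")
  if (abs(sum(intervals) - horizon) > 1e-9 * max(1, horizon))
    stop("intervals must sum to the fixed horizon")
  if (is.null(names(x0)) || any(!nzchar(names(x0))))
    stop("x0 must be a fully named vector")
  if (any(x0 < 0)) stop("initial concentrations must be nonnegative")
  n_t <- length(intervals)
  if (length(perturbations)) {
    idx <- as.integer(names(perturbations))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_t))
      stop("perturbation indices must name valid measurement indices")
  }
  if (!all(design_x0 %in% names(x0)))
    stop("design_x0 must name entries of x0")
  structure(list(intervals = intervals, x0 = x0, horizon = horizon,
                 perturbations = perturbations,
                 input_profile = input_profile,
                 design_x0 = design_x0),
            class = "experimental_design")
}

#' @export
print.experimental_design <- function(x, ...) {
  cat("Experimental design\n")
  cat(sprintf("  %d measurement points over horizon %g\n",
              length(x$intervals), x$horizon))
  cat("  initial state:",
      paste(sprintf("%s=%g", names(x$x0), x$x0), collapse = ", "), "\n")
  if (length(x$design_x0))
    cat("  designed initials:", paste(x$design_x0, collapse = ", "), "\n")
  if (length(x$perturbations))
    cat("  perturbations at indices:",
        paste(names(x$perturbations), collapse = ", "), "\n")
  if (length(x$input_profile))
    cat("  inputs:", paste(names(x$input_profile), collapse = ", "), "\n")
  invisible(x)
}

#' Measurement times of a design
#'
#' Cumulative sums of the design intervals. Time 0 is not a measurement
#' point: the first measurement is at the first interval.
#'
#' @param design An [experimental_design()].
#' @return Numeric vector of measurement times.
#' @export
measurement_times <- function(design) cumsum(design$intervals)

#' Number of measurement points of a design
#'
#' @param design An [experimental_design()].
#' @return Integer count.
#' @export
n_measurements <- function(design) length(design$intervals)

#' Perturbation magnitude vector at each measurement index
#'
#' For each measurement point, collects the scheduled species impulses and
#' input step changes and returns their Euclidean norm; used by the
#' measurement weight that suppresses measuring while perturbing.
#'
#' @param design An [experimental_design()].
#' @return Numeric vector, one norm per measurement point.
#' @export
perturbation_norms <- function(design) {
  n <- n_measurements(design)
  out <- numeric(n)
  for (nm in names(design$perturbations)) {
    out[as.integer(nm)] <- sqrt(sum(design$perturbations[[nm]]^2))
  }
  if (length(design$input_profile)) {
    for (lab in names(design$input_profile)) {
      prof <- design$input_profile[[lab]]
      prev <- prof$initial
      for (ch in prof$changes) {
        i <- ch$index
        out[i] <- sqrt(out[i]^2 + (ch$value - prev)^2)
        prev <- ch$value
      }
    }
  }
  out
}

#' Describe the feasible design space
#'
#' @param n_t Number of measurement points (at least 2).
#' @param x0_bounds Named list of `c(lower, upper)` per designed species.
#' @param interval_bounds `c(lower, upper)` box for every interval, or `NULL`
#'   to keep the measurement grid fixed. Defaults to `c(0, horizon)` behavior
#'   when intervals are optimized.
#' @param perturbation_bounds Named list of `c(lower, upper)` per perturbation
#'   target (species or input label).
#' @param allowed_perturbation_indices Integer vector of measurement indices at
#'   which perturbations may be placed.
#' @param input_bounds Named list of `c(lower, upper)` per external input,
#'   bounding every value of its piecewise-constant profile.
#'
#' @return An object of class `design_space`.
#' @export
design_space <- function(n_t, x0_bounds = list(), interval_bounds = NULL,
                         perturbation_bounds = list(),
                         allowed_perturbation_indices = integer(),
                         input_bounds = list()) {
  stopifnot(n_t >= 2)
  chk <- function(lst, what) {
    for (nm in names(lst)) {
      b <- lst[[nm]]
      if (length(b) != 2 || b[1] > b[2])
        stop(sprintf("%s bounds for '%s' must be an ordered pair", what, nm))
    }
  }
  chk(x0_bounds, "x0"); chk(perturbation_bounds, "perturbation")
  chk(input_bounds, "input")
  if (!is.null(interval_bounds) &&
      (length(interval_bounds) != 2 || interval_bounds[1] > interval_bounds[2]))
    stop("interval_bounds must be an ordered pair")
  structure(list(n_t = as.integer(n_t), x0_bounds = x0_bounds,
                 interval_bounds = interval_bounds,
                 perturbation_bounds = perturbation_bounds,
                 allowed_perturbation_indices =
                   as.integer(allowed_perturbation_indices),
                 input_bounds = input_bounds),
            class = "design_space")
}

## ---------------------------------------------------------------------------
## Vectorization of designs over a design space (used by the optimizer)
## ---------------------------------------------------------------------------

# Layout of the free-variable vector:
#   [x0 for designed species][intervals][pert magnitudes][input values]
# Intervals are re-projected onto the simplex sum(dt) = horizon after each
# optimizer step; all other components carry plain box bounds.
design_layout <- function(design, space) {
  x0_names <- names(space$x0_bounds)
  opt_intervals <- !is.null(space$interval_bounds)
  pert <- list()
  for (i in space$allowed_perturbation_indices)
    for (tg in names(space$perturbation_bounds))
      pert[[length(pert) + 1L]] <- list(index = i, target = tg)
  inputs <- list()
  for (lab in names(space$input_bounds)) {
    prof <- design$input_profile[[lab]]
    if (is.null(prof)) next
    inputs[[length(inputs) + 1L]] <- list(label = lab, slot = "initial")
    for (j in seq_along(prof$changes))
      inputs[[length(inputs) + 1L]] <- list(label = lab, slot = j)
  }
  list(x0_names = x0_names, opt_intervals = opt_intervals,
       pert = pert, inputs = inputs,
       n = length(x0_names) + (if (opt_intervals) space$n_t else 0L) +
         length(pert) + length(inputs))
}

design_to_vector <- function(design, space, layout = design_layout(design, space)) {
  v <- numeric(0); lo <- numeric(0); hi <- numeric(0)
  for (nm in layout$x0_names) {
    v <- c(v, design$x0[[nm]])
    lo <- c(lo, space$x0_bounds[[nm]][1]); hi <- c(hi, space$x0_bounds[[nm]][2])
  }
  if (layout$opt_intervals) {
    v <- c(v, design$intervals)
    lo <- c(lo, rep(space$interval_bounds[1], space$n_t))
    hi <- c(hi, rep(min(space$interval_bounds[2], design$horizon), space$n_t))
  }
  for (pp in layout$pert) {
    cur <- design$perturbations[[as.character(pp$index)]]
    val <- if (!is.null(cur) && pp$target %in% names(cur)) cur[[pp$target]] else 0
    b <- space$perturbation_bounds[[pp$target]]
    v <- c(v, val); lo <- c(lo, b[1]); hi <- c(hi, b[2])
  }
  for (ii in layout$inputs) {
    prof <- design$input_profile[[ii$label]]
    val <- if (identical(ii$slot, "initial")) prof$initial
           else prof$changes[[ii$slot]]$value
    b <- space$input_bounds[[ii$label]]
    v <- c(v, val); lo <- c(lo, b[1]); hi <- c(hi, b[2])
  }
  list(v = v, lower = lo, upper = hi)
}

vector_to_design <- function(v, design, space, layout = design_layout(design, space)) {
  d <- design
  k <- 0L
  for (nm in layout$x0_names) { k <- k + 1L; d$x0[[nm]] <- v[k] }
  if (layout$opt_intervals) {
    dt <- v[(k + 1L):(k + space$n_t)]; k <- k + space$n_t
    dt <- pmax(dt, 0)
    s <- sum(dt)
    dt <- if (s > 0) dt * (design$horizon / s)
          else rep(design$horizon / space$n_t, space$n_t)
    d$intervals <- dt
  }
  for (pp in layout$pert) {
    k <- k + 1L
    key <- as.character(pp$index)
    cur <- d$perturbations[[key]]
    if (is.null(cur)) cur <- stats::setNames(numeric(0), character(0))
    cur[[pp$target]] <- v[k]
    d$perturbations[[key]] <- cur
  }
  for (ii in layout$inputs) {
    k <- k + 1L
    if (identical(ii$slot, "initial"))
      d$input_profile[[ii$label]]$initial <- v[k]
    else d$input_profile[[ii$label]]$changes[[ii$slot]]$value <- v[k]
  }
  d
}

#' Check feasibility of a design against a design space
#'
#' @param design An [experimental_design()].
#' @param space A [design_space()].
#' @param tol Numeric tolerance.
#' @return TRUE or a character vector of violations.
#' @export
design_feasible <- function(design, space, tol = 1e-6) {
  viol <- character(0)
  if (length(design$intervals) != space$n_t)
    viol <- c(viol, "number of intervals differs from space n_t")
  if (abs(sum(design$intervals) - design$horizon) > tol)
    viol <- c(viol, "intervals do not sum to the horizon")
  for (nm in names(space$x0_bounds)) {
    b <- space$x0_bounds[[nm]]
    if (design$x0[[nm]] < b[1] - tol || design$x0[[nm]] > b[2] + tol)
      viol <- c(viol, sprintf("x0[%s] outside bounds", nm))
  }
  if (!is.null(space$interval_bounds)) {
    if (any(design$intervals < space$interval_bounds[1] - tol) ||
        any(design$intervals > space$interval_bounds[2] + tol))
      viol <- c(viol, "an interval violates its box")
  }
  for (key in names(design$perturbations)) {
    p <- design$perturbations[[key]]
    for (tg in names(p)) {
      b <- space$perturbation_bounds[[tg]]
      if (is.null(b)) next
      if (p[[tg]] < b[1] - tol || p[[tg]] > b[2] + tol)
        viol <- c(viol, sprintf("perturbation %s@%s outside bounds", tg, key))
    }
  }
  if (length(viol)) viol else TRUE
}

#' The initial design of the bioreactor benchmark experiment
#'
#' Thirty measurement points spaced two hours apart over a 60 hour horizon;
#' the flow rates are raised at the 10th measurement point (20 h) and the
#' feed substrate concentration is reduced at the 15th (30 h).
#'
#' @param c_in0 Initial feed substrate concentration.
#' @param q0 Initial flow rate (in = out).
#' @param q1 Flow rate after the 10th measurement point.
#' @param c_in1 Feed concentration after the 15th measurement point.
#' @return An [experimental_design()].
#' @export
benchmark_initial_design <- function(c_in0 = 10, q0 = 0.1, q1 = 0.3,
                                     c_in1 = 5) {
  experimental_design(
    intervals = rep(2, 30), horizon = 60,
    x0 = c(B = 0.1, S = 1, M1 = 0, M2 = 0, E = 0.01),
    input_profile = list(
      q_in = list(initial = q0, changes = list(list(index = 10L, value = q1))),
      q_out = list(initial = q0, changes = list(list(index = 10L, value = q1))),
      c_in = list(initial = c_in0, changes = list(list(index = 15L, value = c_in1)))))
}
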