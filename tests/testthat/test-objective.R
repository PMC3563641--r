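test_that("smooth step takes the tanh closed form and its limits", {
  cfg <- step_config(width = 2, center = 1, steepness = 10)
  expect_equal(smooth_step(1, cfg), 0.5)
  expect_gt(smooth_step(1 + 10 * 2, cfg), 1 - 1e-8)
  expect_lt(smooth_step(1 - 10 * 2, cfg), 1e-8)
  # monotone nondecreasing
  x <- seq(-5, 7, length.out = 200)
  expect_true(all(diff(smooth_step(x, cfg)) >= 0))
  # within 0.01 of the exact Heaviside outside center +- width at steepness 5
  cfg5 <- step_config(width = 1, center = 0, steepness = 5)
  xs <- c(seq(-4, -1.001, length.out = 50), seq(1.001, 4, length.out = 50))
  exact <- as.numeric(xs > 0)
  expect_lt(max(abs(smooth_step(xs, cfg5) - exact)), 0.01)
})

test_that("measurement weight suppresses short intervals and perturbed points", {
  cfg_dt <- step_config(width = 0.5, center = 1, steepness = 10)
  cfg_p <- step_config(width = 0.05, center = 0.1, steepness = 10)
  expect_gt(measurement_weight(50, numeric(0), cfg_dt, cfg_p), 0.999)
  expect_lt(measurement_weight(0, numeric(0), cfg_dt, cfg_p), 1e-6)
  expect_lt(measurement_weight(50, c(2, 0), cfg_dt, cfg_p), 1e-6)
})

make_traj <- function(values, times, species = "y") {
  structure(list(times = times,
                 values = matrix(values, nrow = length(species),
                                 dimnames = list(species, NULL)),
                 meta = list(model = "manual")),
            class = "trajectory_set")
}

test_that("homoscedastic objective equals the hand-computed scaled SSQ", {
  times <- c(1, 2, 3)
  t1 <- make_traj(c(3, 3, 3), times)
  t2 <- make_traj(c(1, 1, 1), times)
  d <- experimental_design(intervals = rep(1, 3), x0 = c(y = 0))
  steps <- wide_steps()
  vm <- variance_model("homoscedastic", sigma = 1)
  # three points differing by 2: 3 * 4 / 2 = 6
  expect_equal(discrimination_objective(t1, t2, d, vm, steps), 6,
               tolerance = 1e-9)
  expect_equal(discrimination_objective(t1, t1, d, vm, steps), 0)
  # scaling the difference by c scales J by c^2
  t3 <- make_traj(c(7, 7, 7), times)  # difference 6 = 3 * 2
  expect_equal(discrimination_objective(t3, t2, d, vm, steps),
               9 * discrimination_objective(t1, t2, d, vm, steps),
               tolerance = 1e-9)
  expect_error(discrimination_objective(t1, make_traj(c(1, 1), c(1, 2)),
                                        d, vm, steps),
               "time grid")
})

test_that("per-model KL term vanishes for identical Gaussians and is non-symmetric", {
  times <- c(1, 2, 3)
  d <- experimental_design(intervals = rep(1, 3), x0 = c(y = 0))
  steps <- wide_steps()
  same <- variance_model("per_model", var1 = function(t) 2, var2 = function(t) 2)
  t1 <- make_traj(c(1, 2, 3), times)
  expect_equal(discrimination_objective(t1, t1, d, same, steps), 0)
  diffvar <- variance_model("per_model", var1 = function(t) 1,
                            var2 = function(t) 4)
  swapped <- variance_model("per_model", var1 = function(t) 4,
                            var2 = function(t) 1)
  t2 <- make_traj(c(2, 3, 4), times)
  J12 <- discrimination_objective(t1, t2, d, diffvar, steps)
  J21 <- discrimination_objective(t2, t1, d, swapped, steps)
  expect_false(isTRUE(all.equal(J12, J21)))
  # directed Gaussian KL at one point: 0.5 (log(v2/v1) + v1/v2 + d^2/v2 - 1)
  hand <- 3 * 0.5 * (log(4 / 1) + 1 / 4 + 1 / 4 - 1)
  expect_equal(J12, hand, tolerance = 1e-9)
})

test_that("symmetrized objective is swap-invariant and doubles the homoscedastic value", {
  times <- c(1, 2)
  t1 <- make_traj(c(1, 5), times)
  t2 <- make_traj(c(2, 2), times)
  d <- experimental_design(intervals = rep(1, 2), x0 = c(y = 0))
  steps <- wide_steps()
  vm <- variance_model("homoscedastic", 1)
  expect_equal(symmetric_objective(t1, t2, d, vm, steps),
               symmetric_objective(t2, t1, d, vm, steps))
  expect_equal(symmetric_objective(t1, t2, d, vm, steps),
               2 * discrimination_objective(t1, t2, d, vm, steps))
  dv <- variance_model("per_model", var1 = function(t) 1,
                       var2 = function(t) 3)
  expect_equal(symmetric_objective(t1, t2, d, dv, steps),
               symmetric_objective(t2, t1, d, dv, steps))
})

test_that("objective is finite-difference differentiable in design variables", {
  mA <- get_model("simple_enzyme")
  mB <- get_model("hysteretic_enzyme")
  pA <- c(k1 = 6.4086, km1 = 0.0, k2 = 2.0749)
  pB <- hysteretic_true_params()
  cfg <- objective_config(step_dt = step_config(1, 0.5),
                          step_p = step_config(0.1, 0.05))
  base <- experimental_design(
    intervals = rep(10, 6),
    x0 = c(S = 5, E = 0.2, ES = 0, P = 0, Ei = 0.2, Ea = 0, EiS = 0, EaS = 0))
  # the shared x0 covers both models' species; each rhs picks its own by name
  J <- function(s0) {
    d <- base; d$x0[["S"]] <- s0
    evaluate_design(mA, mB, pA, pB, d, cfg)
  }
  h <- 1e-4
  g <- (J(5 + h) - J(5 - h)) / (2 * h)
  expect_true(is.finite(g))
})

test_that("evaluate_design honors the custom objective hook", {
  sp <- saddle_problem(xi0 = 0.3)
  J <- evaluate_design(sp$modelA, sp$modelB, c(theta = 0.1), c(theta = 0),
                       sp$init_design, sp$cfg)
  expect_equal(J, (0.3 - 0.1)^2 + 0.3)
})
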