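test_that("designs validate their invariants", {
  expect_error(experimental_design(c(1, 2), x0 = c(S = 1), horizon = 4),
               "sum")
  expect_error(experimental_design(c(1, -1, 2), x0 = c(S = 1)),
               "nonnegative")
  expect_error(experimental_design(c(1, 1), x0 = c(S = -1)), "nonnegative")
  expect_error(experimental_design(c(1, 1), x0 = c(S = 1),
                                   perturbations = list("7" = c(S = 1))),
               "indices")
  d <- experimental_design(rep(2, 30), x0 = c(S = 1))
  expect_equal(n_measurements(d), 30)
  expect_equal(measurement_times(d), seq(2, 60, by = 2))
})

test_that("the benchmark initial design has 30 points over 60 hours", {
  d <- benchmark_initial_design()
  expect_equal(n_measurements(d), 30)
  expect_equal(d$horizon, 60)
  expect_equal(unique(diff(measurement_times(d))), 2)
  # first measurement at 2 h: time zero is not a measurement point
  expect_equal(measurement_times(d)[1], 2)
})

test_that("degenerate design space returns the initial design unchanged", {
  sp <- saddle_problem(xi0 = 0.4)
  tight <- design_space(n_t = 2, x0_bounds = list(x = c(0.4, 0.4)))
  opt <- optimal_design(sp$modelA, sp$modelB,
                        list(list(A = sp$paramsA, B = sp$paramsB)),
                        tight, sp$init_design, sp$cfg)
  expect_equal(opt$design$x0[["x"]], 0.4)
  expect_equal(opt$value, opt$initial_value)
})

test_that("monotone separation puts the optimum at the upper initial-value bound", {
  # rival linear responses y = theta S0 t and y = 2 theta S0 t: the separation
  # grows with S0, so the boundary is optimal; verified against a 1-D scan
  cfg <- objective_config(custom = function(design, pA, pB) {
    s0 <- design$x0[["y"]]
    tt <- measurement_times(design)
    sum((pA[["theta"]] * s0 * tt - 2 * pB[["theta"]] * s0 * tt)^2)
  })
  init <- experimental_design(intervals = rep(1, 3), x0 = c(y = 0.5),
                              design_x0 = "y")
  space <- design_space(n_t = 3, x0_bounds = list(y = c(0.1, 2)))
  dummy <- constant_model(1)
  opt <- optimal_design(dummy, dummy, list(list(A = c(theta = 1), B = c(theta = 1))),
                        space, init, cfg)
  expect_equal(opt$design$x0[["y"]], 2, tolerance = 1e-4)
  scan <- vapply(seq(0.1, 2, length.out = 200), function(s) {
    d <- init; d$x0[["y"]] <- s
    cfg$custom(d, c(theta = 1), c(theta = 1))
  }, 0)
  expect_equal(max(scan), opt$value, tolerance = 1e-3)
})

test_that("optimized interval vectors keep summing to the horizon", {
  cfg <- objective_config(custom = function(design, pA, pB) {
    tt <- measurement_times(design)
    sum(exp(-tt))  # rewards early measurements
  })
  init <- experimental_design(intervals = rep(2.5, 4), x0 = c(y = 1))
  space <- design_space(n_t = 4, interval_bounds = c(0, 10))
  dummy <- constant_model(1)
  opt <- optimal_design(dummy, dummy,
                        list(list(A = c(theta = 1), B = c(theta = 1))),
                        space, init, cfg)
  expect_equal(sum(opt$design$intervals), 10, tolerance = 1e-6)
  expect_true(all(opt$design$intervals >= -1e-9))
  expect_gte(opt$value, opt$initial_value)
})

test_that("epigraph reformulation is equivalent to direct maximization", {
  sp <- saddle_problem(xi0 = 0.2)
  pair1 <- list(list(A = c(theta = 0.1), B = sp$paramsB))
  direct <- optimal_design(sp$modelA, sp$modelB, pair1, sp$space,
                           sp$init_design, sp$cfg)
  prob <- epigraph_reformulation(sp$modelA, sp$modelB, pair1, sp$cfg)
  expect_equal(prob$eval_min(direct$design),
               prob$eval_all(direct$design)[1])
  expect_equal(direct$value, prob$eval_min(direct$design))
  # J(xi; 0.1) = (xi - 0.1)^2 + xi is maximized at xi = 1
  expect_equal(direct$design$x0[["x"]], 1, tolerance = 1e-4)
  expect_equal(direct$value, 0.9^2 + 1, tolerance = 1e-4)
})

test_that("a dominated pair controls the epigraph level", {
  sp <- saddle_problem()
  # theta = 0 gives J = xi^2 + xi; a second 'pair' with objective shifted up
  cfg <- objective_config(custom = function(design, pA, pB) {
    xi <- design$x0[["x"]]
    (xi - pA[["theta"]])^2 + xi + pA[["offset"]]
  })
  pairs <- list(list(A = c(theta = 0, offset = 0), B = sp$paramsB),
                list(A = c(theta = 0, offset = 5), B = sp$paramsB))
  prob <- epigraph_reformulation(sp$modelA, sp$modelB, pairs, cfg)
  for (xi in seq(0, 1, by = 0.1)) {
    d <- sp$init_design; d$x0[["x"]] <- xi
    expect_equal(prob$eval_min(d), prob$eval_all(d)[1])
  }
})

test_that("adding a parameter pair never increases the optimal min value", {
  sp <- saddle_problem(xi0 = 0.5)
  p1 <- list(list(A = c(theta = 0.2), B = sp$paramsB))
  p2 <- c(p1, list(list(A = c(theta = 0.9), B = sp$paramsB)))
  o1 <- optimal_design(sp$modelA, sp$modelB, p1, sp$space, sp$init_design,
                       sp$cfg)
  o2 <- optimal_design(sp$modelA, sp$modelB, p2, sp$space, sp$init_design,
                       sp$cfg)
  expect_lte(o2$value, o1$value + 1e-9)
})

test_that("infeasible initial designs are rejected", {
  sp <- saddle_problem(xi0 = 0.4)
  bad_space <- design_space(n_t = 2, x0_bounds = list(x = c(0.6, 1)))
  expect_error(optimal_design(sp$modelA, sp$modelB,
                              list(list(A = sp$paramsA, B = sp$paramsB)),
                              bad_space, sp$init_design, sp$cfg),
               "infeasible")
})

test_that("designs round-trip through export and import", {
  d <- experimental_design(
    intervals = c(1.5, 2.5, 2),
    x0 = c(S = 3.25, E = 0.5, ES = 0, P = 0),
    perturbations = list("2" = c(S = 0.5, E = 0.1)),
    input_profile = list(q = list(initial = 0.1,
                                  changes = list(list(index = 2L, value = 0.4)))),
    design_x0 = "S")
  prefix <- tempfile()
  export_design(d, prefix)
  d2 <- import_design(prefix)
  expect_equal(d2$intervals, d$intervals)
  expect_equal(d2$x0, d$x0)
  expect_equal(d2$perturbations[["2"]], d$perturbations[["2"]])
  expect_equal(d2$input_profile$q$changes[[1]]$value, 0.4)
  expect_equal(d2$design_x0, "S")
  # text dump contains the interval line summing to the horizon
  txt <- readLines(paste0(prefix, ".txt"))
  iv <- txt[startsWith(txt, "intervals")]
  nums <- as.numeric(strsplit(gsub(".*\\[|\\].*", "", iv), ",")[[1]])
  expect_equal(sum(nums), d$horizon)
})

test_that("the exported benchmark initial design lists 30 measurement entries", {
  d <- benchmark_initial_design()
  prefix <- tempfile()
  export_design(d, prefix)
  txt <- readLines(paste0(prefix, ".txt"))
  mt <- txt[startsWith(txt, "measurement_times")]
  nums <- as.numeric(strsplit(gsub(".*\\[|\\].*", "", mt), ",")[[1]])
  expect_length(nums, 30)
})
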