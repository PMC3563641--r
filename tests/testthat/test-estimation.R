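test_that("noiseless data generated by the model are fit exactly from truth", {
  m <- decay_model()
  d <- experimental_design(intervals = rep(1, 5), x0 = c(S = 2))
  ds <- generate_data(m, c(k = 0.7), d, noise_model("additive", 0), 2, seed = 1)
  fit <- least_squares_fit(m, ds, d, init = c(k = 0.7))
  expect_equal(coef(fit)[["k"]], 0.7, tolerance = 1e-8)
  expect_lt(fit$ssr, 1e-10)
})

test_that("a 1-D rate constant is recovered and matches a grid scan", {
  m <- decay_model()
  d <- experimental_design(intervals = rep(1, 3), x0 = c(S = 1))
  ds <- generate_data(m, c(k = 0.7), d, noise_model("additive", 0.01),
                      1, seed = 3)
  fit <- least_squares_fit(m, ds, d, init = c(k = 1.0))
  expect_equal(coef(fit)[["k"]], 0.7, tolerance = 0.05)
  # independent oracle: dense grid scan of the same ssr
  ssr_at <- function(k) {
    pred <- exp(-k * d$intervals |> cumsum())
    sum((ds[[1]]$values["S", ] - pred)^2)
  }
  grid <- seq(0.4, 1.0, length.out = 2001)
  k_grid <- grid[which.min(vapply(grid, ssr_at, 0))]
  expect_equal(coef(fit)[["k"]], k_grid, tolerance = 1e-3)
})

test_that("fixed parameters stay at their initial values", {
  m <- get_model("simple_enzyme")
  p <- c(k1 = 2, km1 = 0.4, k2 = 1)
  d <- experimental_design(intervals = rep(0.5, 6),
                           x0 = c(S = 5, E = 1, ES = 0, P = 0))
  ds <- generate_data(m, p, d, noise_model("additive", 0.01), 2, seed = 5)
  fit <- least_squares_fit(m, ds, d, init = c(k1 = 1.5, km1 = 0.4, k2 = 0.8),
                           fixed = "km1")
  expect_equal(coef(fit)[["km1"]], 0.4)
  expect_equal(coef(fit)[["k1"]], 2, tolerance = 0.1)
})

test_that("residual pooling: k identical noiseless datasets fit like one", {
  m <- decay_model()
  d <- experimental_design(intervals = rep(1, 4), x0 = c(S = 1))
  ds1 <- generate_data(m, c(k = 0.5), d, noise_model("additive", 0), 1, seed = 1)
  ds3 <- rep(ds1, 3)
  f1 <- least_squares_fit(m, ds1, d, init = c(k = 0.9))
  f3 <- least_squares_fit(m, ds3, d, init = c(k = 0.9))
  expect_equal(coef(f1)[["k"]], coef(f3)[["k"]], tolerance = 1e-7)
})

test_that("fitting the simple model to hysteretic data pins dissociation at zero", {
  # the simple mechanism compensates the sigmoid lag with a vanishing
  # dissociation constant, as in the enzyme example's estimated parameters
  mh <- get_model("hysteretic_enzyme")
  ms <- get_model("simple_enzyme")
  dh <- hysteretic_design(S0 = 3, E0 = 0.5, n_points = 13, spacing = 20)
  ds <- generate_data(mh, hysteretic_true_params(), dh,
                      noise_model("additive", 0.03), 2, seed = 2)
  d_simple <- experimental_design(intervals = rep(20, 13),
                                  x0 = c(S = 3, E = 0.5, ES = 0, P = 0))
  box <- parameter_box(c(k1 = 0, km1 = 0, k2 = 0),
                       c(k1 = 100, km1 = 100, k2 = 100))
  fit <- least_squares_fit(ms, ds, d_simple, init = c(k1 = 1, km1 = 1, k2 = 1),
                           box = box)
  expect_lt(coef(fit)[["km1"]], 1e-4)
})

test_that("worst-case estimation returns the degenerate box point unchanged", {
  sp <- saddle_problem(xi0 = 0.4)
  boxes <- list(A = parameter_box(c(theta = 0.3), c(theta = 0.3)))
  wc <- worst_case_params(sp$modelA, sp$modelB, sp$init_design, boxes,
                          sp$paramsA, sp$paramsB, sp$cfg, n_starts = 3,
                          seed = 1)
  expect_equal(wc$params1[["theta"]], 0.3)
  expect_equal(wc$objective, (0.4 - 0.3)^2 + 0.4)
})

test_that("worst-case with one free parameter matches a 1001-point grid search", {
  sp <- saddle_problem(xi0 = 0.35)
  wc <- worst_case_params(sp$modelA, sp$modelB, sp$init_design, sp$boxes,
                          sp$paramsA, sp$paramsB, sp$cfg, n_starts = 5,
                          seed = 0)
  grid <- seq(0, 1, length.out = 1001)
  Jg <- (sp$init_design$x0[["x"]] - grid)^2 + sp$init_design$x0[["x"]]
  theta_grid <- grid[which.min(Jg)]
  expect_equal(wc$params1[["theta"]], theta_grid, tolerance = 1e-3)
  expect_lte(wc$objective, min(Jg) + 1e-9)
})

test_that("worst-case objective undercuts 100 fresh random feasible points", {
  mA <- get_model("simple_enzyme")
  pA <- c(k1 = 6.4086, km1 = 0.0, k2 = 2.0749)
  mB <- get_model("hysteretic_enzyme")
  pB <- hysteretic_true_params()
  x0 <- c(S = 5, E = 0.2, ES = 0, P = 0, Ei = 0.2, Ea = 0, EiS = 0, EaS = 0)
  d <- experimental_design(intervals = rep(20, 5), x0 = x0)
  cfg <- objective_config(step_dt = step_config(1, 0.5),
                          step_p = step_config(0.1, 0.05),
                          settings = solver_settings(1e-6, 1e-8))
  boxes <- list(A = parameter_box(c(k1 = 0.5, k2 = 0.5),
                                  c(k1 = 20, k2 = 10)))
  wc <- worst_case_params(mA, mB, d, boxes, pA, pB, cfg, n_starts = 3,
                          seed = 4)
  set.seed(99)
  for (i in 1:100) {
    p <- pA
    p[["k1"]] <- runif(1, 0.5, 20); p[["k2"]] <- runif(1, 0.5, 10)
    expect_gte(evaluate_design(mA, mB, p, pB, d, cfg) + 1e-9, wc$objective)
  }
})

test_that("increasing the number of starts never increases the best objective", {
  sp <- saddle_problem(xi0 = 0.6)
  vals <- vapply(c(1, 3, 6), function(ns)
    worst_case_params(sp$modelA, sp$modelB, sp$init_design, sp$boxes,
                      sp$paramsA, sp$paramsB, sp$cfg, n_starts = ns,
                      seed = 7)$objective, 0)
  expect_true(all(diff(vals) <= 1e-12))
})
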