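test_that("zero-sigma generation reproduces the noiseless trajectory", {
  m <- decay_model()
  d <- experimental_design(intervals = rep(1, 4), x0 = c(S = 1))
  ds <- generate_data(m, c(k = 0.3), d, noise_model("additive", 0), 3, seed = 1)
  tr <- simulate_design(m, c(k = 0.3), d)
  for (dd in ds) expect_equal(dd$values, tr$values)
  expect_length(ds, 3)
})

test_that("noise laws have the advertised spread", {
  m <- constant_model(1)
  d <- experimental_design(intervals = 1, x0 = c(x1 = 10))
  add <- generate_data(m, c(dummy = 0), d, noise_model("additive", 0.1),
                       10000, seed = 2)
  y <- vapply(add, function(dd) dd$values[1, 1], 0)
  expect_gt(sd(y), 0.097); expect_lt(sd(y), 0.103)
  rel <- generate_data(m, c(dummy = 0), d, noise_model("relative", 0.05),
                       10000, seed = 3)
  yr <- vapply(rel, function(dd) dd$values[1, 1], 0)
  expect_equal(sd(yr), 0.5, tolerance = 0.05)
})

test_that("generation is reproducible for a fixed seed and clips at zero", {
  m <- constant_model(1)
  d <- experimental_design(intervals = rep(1, 3), x0 = c(x1 = 0.01))
  a <- generate_data(m, c(dummy = 0), d, noise_model("additive", 1), 2, seed = 4)
  b <- generate_data(m, c(dummy = 0), d, noise_model("additive", 1), 2, seed = 4)
  expect_identical(a, b)
  expect_true(all(vapply(a, function(dd) all(dd$values >= 0), TRUE)))
  expect_gt(sum(vapply(a, function(dd) dd$n_clipped, 0L)), 0)
})

test_that("datasets round-trip through delimited text with JSON sidecar", {
  m <- decay_model()
  d <- experimental_design(intervals = rep(1, 3), x0 = c(S = 2))
  ds <- generate_data(m, c(k = 0.4), d, noise_model("relative", 0.02),
                      1, seed = 5)[[1]]
  path <- tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$values, ds$values)
  expect_equal(back$times, ds$times)
  expect_equal(back$noise$sigma, 0.02)
  expect_equal(back$seed, 5)
})

test_that("a curve through the replicate means gives F = 0 and no rejection", {
  m <- constant_model(1)
  d <- experimental_design(intervals = rep(1, 5), x0 = c(x1 = 2))
  # symmetric +-delta replicates around the model curve
  tr <- simulate_design(m, c(dummy = 0), d)
  mk <- function(delta) list(times = tr$times, species = "x1",
                             values = tr$values + delta, replicate_id = 1,
                             seed = 0)
  lof <- lack_of_fit_test(m, c(dummy = 0), list(mk(0.1), mk(-0.1)), d,
                          alpha = 0.05, n_params = 1)
  expect_equal(unname(lof$f_statistic["x1"]), 0)
  expect_false(lof$reject[["x1"]])
  expect_error(lack_of_fit_test(m, c(dummy = 0), list(mk(0.1)), d),
               "two replicates")
})

test_that("the lack-of-fit decomposition matches a hand ANOVA table", {
  # 3 times, 2 replicates; model curve eta = (1, 2, 3); data chosen by hand
  m <- kinetic_model("ramp", species = "y", parameters = "a",
                     rhs = function(t, x, p, u) p[["a"]])
  d <- experimental_design(intervals = rep(1, 3), x0 = c(y = 0))
  y1 <- c(1.2, 2.0, 3.4)
  y2 <- c(0.8, 2.4, 2.6)
  mk <- function(v) list(times = 1:3, species = "y",
                         values = matrix(v, 1, dimnames = list("y", NULL)),
                         replicate_id = 1, seed = 0)
  lof <- lack_of_fit_test(m, c(a = 1), list(mk(y1), mk(y2)), d, alpha = 0.05,
                          n_params = 1)
  ybar <- (y1 + y2) / 2                      # 1.0, 2.2, 3.0
  ss_lof <- 2 * sum((ybar - c(1, 2, 3))^2)   # 2 * 0.04 = 0.08
  ss_pure <- sum((y1 - ybar)^2 + (y2 - ybar)^2)  # 0.08 + 0.08 + 0.32 = 0.48
  f_hand <- (ss_lof / (3 - 1)) / (ss_pure / 3)
  expect_equal(unname(lof$f_statistic["y"]), f_hand, tolerance = 1e-12)
  expect_equal(lof$df_lof, 2)
  expect_equal(lof$df_pure, 3)
  expect_equal(lof$critical_value, qf(0.95, 2, 3))
})

test_that("variance-ratio test matches direct computation and F quantiles", {
  r <- rnorm(30)
  same <- variance_ratio_test(r, r, alpha = 0.05)
  expect_equal(same$ratio, 1)
  expect_false(same$reject)
  set.seed(11)
  a <- rnorm(100, sd = 1); a <- (a - mean(a)) / sd(a)        # sd exactly 1
  b <- rnorm(100, sd = 1); b <- 2 * (b - mean(b)) / sd(b)    # sd exactly 2
  vt <- variance_ratio_test(a, b, alpha = 0.05)
  expect_equal(vt$ratio, 4, tolerance = 1e-12)
  expect_equal(vt$critical, qf(0.95, 100, 100))
  expect_true(vt$reject)
  # published F-table entry: F_{0.95}(10, 10) = 2.978 (to 3 decimals)
  small <- variance_ratio_test(rnorm(10), rnorm(10))
  expect_equal(small$critical, 2.978, tolerance = 1e-3)
  # SD-ratio reproduction mode
  vts <- variance_ratio_test(a, b, use_sd = TRUE)
  expect_equal(vts$ratio, 2, tolerance = 1e-12)
  # zero variance in the denominator rejects with infinite ratio
  z <- variance_ratio_test(a, rep(0.5, 20))
  expect_true(is.infinite(z$ratio) && z$reject)
})

test_that("histogram counts conserve the number of successful draws", {
  sp <- saddle_problem(xi0 = 0.4)
  h <- kl_histogram(sp$modelA, sp$modelB, sp$init_design, sp$boxes,
                    sp$paramsA, sp$paramsB, sp$cfg, n_draws = 200,
                    n_bins = 20, seed = 12)
  expect_equal(sum(h$counts), 200)
  expect_equal(h$draws, 200)
  expect_length(h$bin_edges, 21)
  expect_true(all(diff(diff(h$bin_edges)) < 1e-12))  # equally spaced
  expect_equal(h$min_objective, min(h$values))
})

test_that("a single draw in a degenerate box lands in one occupied bin", {
  sp <- saddle_problem(xi0 = 0.4)
  boxes <- list(A = parameter_box(c(theta = 0.2), c(theta = 0.2)))
  h <- kl_histogram(sp$modelA, sp$modelB, sp$init_design, boxes,
                    sp$paramsA, sp$paramsB, sp$cfg, n_draws = 1,
                    n_bins = 5, seed = 13)
  expect_equal(sum(h$counts), 1)
  expect_equal(h$min_objective, (0.4 - 0.2)^2 + 0.4)
})
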