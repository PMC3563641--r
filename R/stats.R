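#' Measurement noise model
#'
#' @param kind "additive" (y = eta + e) or "relative" (y = eta (1 + e)) with
#'   e ~ N(mean, sigma^2).
#' @param sigma Nonnegative standard deviation (0 gives noiseless data).
#' @param mean Noise mean (0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("additive", "relative"), sigma, mean = 0) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0)
  structure(list(kind = kind, sigma = sigma, mean = mean),
            class = "noise_model")
}

#' Generate synthetic replicate datasets
#'
#' Simulates the model under the design once and applies the noise model
#' independently per species, time point and replicate from a single seeded
#' stream. Negative noisy values are clipped at zero; the number of clipped
#' values is recorded per dataset.
#'
#' @param model A [kinetic_model()].
#' @param params Named parameter vector.
#' @param design An [experimental_design()].
#' @param noise A [noise_model()].
#' @param n_datasets Number of independent replicates (>= 1).
#' @param seed RNG seed.
#' @param settings [solver_settings()].
#' @return List of datasets; each a list with `times`, `species`, `values`
#'   (species x times), `noise`, `replicate_id`, `seed`, `n_clipped`.
#' @export
generate_data <- function(model, params, design, noise, n_datasets = 5,
                          seed = 0, settings = solver_settings()) {
  stopifnot(n_datasets >= 1)
  sim <- simulate_design(model, params, design, settings)
  eta <- sim$values
  set.seed(seed)
  lapply(seq_len(n_datasets), function(r) {
    eps <- matrix(stats::rnorm(length(eta), noise$mean, noise$sigma),
                  nrow = nrow(eta), dimnames = dimnames(eta))
    y <- switch(noise$kind,
                additive = eta + eps,
                relative = eta * (1 + eps))
    n_clipped <- sum(y < 0)
    y[y < 0] <- 0
    list(times = sim$times, species = rownames(eta), values = y,
         noise = noise, replicate_id = r, seed = seed,
         n_clipped = n_clipped)
  })
}

#' Write / read a dataset as delimited text with a JSON sidecar
#'
#' The values go to a tab-separated file (time + one column per species); the
#' noise descriptor, seed and replicate id go to `<path>.json`.
#'
#' @param dataset A dataset as returned by [generate_data()].
#' @param path File path for the delimited table.
#' @return `write_dataset` the path invisibly; `read_dataset` a dataset list.
#' @export
write_dataset <- function(dataset, path) {
  df <- data.frame(time = dataset$times, t(dataset$values),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(noise = unclass(dataset$noise), seed = dataset$seed,
               replicate_id = dataset$replicate_id,
               n_clipped = dataset$n_clipped)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else NULL
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  rownames(vals) <- colnames(df)[-1]
  noise <- if (!is.null(meta))
    noise_model(meta$noise$kind, meta$noise$sigma, meta$noise$mean) else NULL
  list(times = df$time, species = rownames(vals), values = vals,
       noise = noise, replicate_id = meta$replicate_id %||% 1L,
       seed = meta$seed %||% NA_integer_,
       n_clipped = meta$n_clipped %||% 0L)
}

#' Replicated-design lack-of-fit test
#'
#' Classical decomposition of the residual variance around a fitted
#' regression curve into lack-of-fit and pure-error components, per observed
#' species: SS_lof = sum_t r (ybar_t - eta_t)^2 with df n_times - n_params,
#' SS_pure = sum_t sum_rep (y - ybar_t)^2 with df n_times (r - 1); their
#' mean-square ratio is compared to the F critical value at level alpha.
#'
#' @param model A [kinetic_model()].
#' @param params Fitted parameter vector defining the regression curve.
#' @param datasets List of >= 2 replicate datasets sharing the time grid.
#' @param design The [experimental_design()] under which they were measured.
#' @param alpha Significance level.
#' @param n_params Number of fitted parameters subtracted from the
#'   lack-of-fit degrees of freedom; defaults to the model's parameter count.
#' @param settings [solver_settings()].
#' @return An object of class `lack_of_fit`: per-species F statistics,
#'   degrees of freedom, critical value and rejection flags.
#' @export
lack_of_fit_test <- function(model, params, datasets, design, alpha = 0.05,
                             n_params = length(model$parameters),
                             settings = solver_settings()) {
  if (length(datasets) < 2)
    stop("pure error requires at least two replicates")
  times <- datasets[[1]]$times
  for (d in datasets)
    if (!isTRUE(all.equal(d$times, times)))
      stop("replicates must share the time grid")
  species <- datasets[[1]]$species
  r <- length(datasets)
  n_t <- length(times)
  df_lof <- n_t - n_params
  df_pure <- n_t * (r - 1)
  if (df_lof <= 0)
    stop("lack-of-fit degrees of freedom are not positive; more time points than parameters are needed")
  sim <- simulate_design(model, params, design, settings)
  eta <- sim$values[species, , drop = FALSE]
  f_stat <- stats::setNames(numeric(length(species)), species)
  for (sp in species) {
    Y <- do.call(rbind, lapply(datasets, function(d) d$values[sp, ]))
    ybar <- colMeans(Y)
    ss_lof <- r * sum((ybar - eta[sp, ])^2)
    ss_pure <- sum(sweep(Y, 2, ybar)^2)
    f_stat[sp] <- (ss_lof / df_lof) / (ss_pure / df_pure)
  }
  crit <- stats::qf(1 - alpha, df_lof, df_pure)
  structure(list(f_statistic = f_stat, df_lof = df_lof, df_pure = df_pure,
                 critical_value = crit, reject = f_stat > crit,
                 alpha = alpha),
            class = "lack_of_fit")
}

#' @export
print.lack_of_fit <- function(x, ...) {
  cat(sprintf("Lack-of-fit test (df %d, %d; alpha %.3g; F crit %.4g)\n",
              x$df_lof, x$df_pure, x$alpha, x$critical_value))
  for (sp in names(x$f_statistic))
    cat(sprintf("  %s: F = %.4g -> %s\n", sp, x$f_statistic[sp],
                if (x$reject[sp]) "reject" else "not rejected"))
  invisible(x)
}

#' Residual-variance F-ratio test between two rival models
#'
#' Compares the residual scatter of two fitted models: the ratio of the
#' larger to the smaller residual variance is referred to an F distribution
#' whose degrees of freedom are the residual counts, and the null of equal
#' scatter is rejected when the ratio exceeds the critical value. A literal
#' standard-deviation ratio (as sometimes quoted) is available for
#' reproduction purposes via `use_sd = TRUE`.
#'
#' @param residualsA,residualsB Nonempty numeric residual vectors.
#' @param alpha Significance level.
#' @param use_sd Compare the SD ratio instead of the variance ratio.
#' @return List: `ratio`, `critical`, `reject`, `df`, plus the per-model
#'   variances.
#' @export
variance_ratio_test <- function(residualsA, residualsB, alpha = 0.05,
                                use_sd = FALSE) {
  stopifnot(length(residualsA) >= 1, length(residualsB) >= 1)
  vA <- stats::var(residualsA); vB <- stats::var(residualsB)
  if (min(vA, vB) == 0) {
    big_first <- vA >= vB
    df <- if (big_first) c(length(residualsA), length(residualsB))
          else c(length(residualsB), length(residualsA))
    return(list(ratio = Inf, critical = stats::qf(1 - alpha, df[1], df[2]),
                reject = TRUE, df = df, var_A = vA, var_B = vB))
  }
  big_first <- vA >= vB
  num <- max(vA, vB); den <- min(vA, vB)
  ratio <- if (use_sd) sqrt(num / den) else num / den
  df <- if (big_first) c(length(residualsA), length(residualsB))
        else c(length(residualsB), length(residualsA))
  critical <- stats::qf(1 - alpha, df[1], df[2])
  list(ratio = ratio, critical = critical, reject = ratio > critical,
       df = df, var_A = vA, var_B = vB)
}

#' KL-divergence robustness histogram
#'
#' Draws parameters uniformly inside the boxes of the free model(s),
#' evaluates the discrimination objective at each draw for a fixed design,
#' and summarizes the values into equally spaced bins over the range of the
#' draws. The minimum observed objective is reported next to the supplied
#' worst-case value: for a converged robust design no draw should fall below
#' the worst-case bar.
#'
#' @param modelA,modelB [kinetic_model()]s.
#' @param design The fixed [experimental_design()].
#' @param boxes List with `A` and/or `B` [parameter_box()]es for the drawn
#'   parameters.
#' @param paramsA,paramsB Full nominal parameter vectors (entries covered by
#'   a box are replaced by the draws).
#' @param objective_cfg An [objective_config()].
#' @param n_draws Number of uniform draws (>= 1).
#' @param n_bins Number of equally spaced bins (default 100).
#' @param seed RNG seed.
#' @param worst_case_value Optional reference objective (the red bar).
#' @return An object of class `kl_histogram`: `draws`, `bin_edges`, `counts`,
#'   `values`, `min_objective`, `worst_case_objective`, `n_failed`.
#' @export
kl_histogram <- function(modelA, modelB, design, boxes, paramsA, paramsB,
                         objective_cfg = objective_config(), n_draws = 1000,
                         n_bins = 100, seed = 0,
                         worst_case_value = NA_real_) {
  stopifnot(n_draws >= 1, n_bins >= 1)
  set.seed(seed)
  vals <- numeric(0); n_failed <- 0L
  for (i in seq_len(n_draws)) {
    pA <- paramsA; pB <- paramsB
    if (!is.null(boxes$A)) pA[names(boxes$A$lower)] <- box_draw(boxes$A)
    if (!is.null(boxes$B)) pB[names(boxes$B$lower)] <- box_draw(boxes$B)
    v <- try(evaluate_design(modelA, modelB, pA, pB, design, objective_cfg),
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) n_failed <- n_failed + 1L
    else vals <- c(vals, v)
  }
  if (n_failed > 0)
    warning(sprintf("%d of %d draws failed to simulate and were excluded",
                    n_failed, n_draws))
  if (!length(vals)) stop("no draw could be evaluated")
  rng <- range(vals)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- as.vector(table(cut(vals, edges, include.lowest = TRUE)))
  structure(list(draws = length(vals), bin_edges = edges, counts = counts,
                 values = vals, min_objective = min(vals),
                 worst_case_objective = worst_case_value,
                 n_failed = n_failed),
            class = "kl_histogram")
}

#' @export
print.kl_histogram <- function(x, ...) {
  cat(sprintf("KL-divergence histogram: %d draws in %d bins on [%.5g, %.5g]\n",
              x$draws, length(x$counts), min(x$bin_edges), max(x$bin_edges)))
  cat(sprintf("  min objective %.6g", x$min_objective))
  if (is.finite(x$worst_case_objective))
    cat(sprintf(" (worst-case bar %.6g)", x$worst_case_objective))
  cat("\n")
  invisible(x)
}

#' @export
plot.kl_histogram <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mids, x$counts, type = "h", xlab = "KL divergence",
                 ylab = "count", ...)
  if (is.finite(x$worst_case_objective))
    graphics::abline(v = x$worst_case_objective, col = "red", lwd = 2)
  invisible(x)
}

#' Export a histogram as delimited text (edges and counts)
#'
#' @param x A `kl_histogram`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_histogram <- function(x, path) {
  df <- data.frame(bin_lower = x$bin_edges[-length(x$bin_edges)],
                   bin_upper = x$bin_edges[-1], count = x$counts)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
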