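#' Robustification gap
#'
#' Absolute difference between the phase-two design objective and the
#' phase-one re-estimated worst-case objective; the stopping monitor of the
#' outer-approximation max-min loop.
#'
#' @param j_design,j_worst Finite objective values.
#' @return Nonnegative scalar.
#' @export
robustification_gap <- function(j_design, j_worst) {
  stopifnot(is.finite(j_design), is.finite(j_worst))
  abs(j_design - j_worst)
}

#' Homotopy configuration for the robust loop
#'
#' When enabled and the robustification gap has dropped below `trigger_gap`,
#' each newly found worst-case pair is introduced into the design problem
#' gradually: phase two is re-solved `n_steps` times with the new pair's
#' blend weight ramped linearly from 1/n_steps to 1, warm-starting the design
#' at each sub-solve. The blend changes the optimization path, not the limit.
#'
#' @param enabled Logical.
#' @param n_steps Integer >= 1 number of ramp sub-solves.
#' @param trigger_gap Positive gap threshold below which the ramp starts.
#' @return An object of class `homotopy_config`.
#' @export
homotopy_config <- function(enabled = FALSE, n_steps = 3, trigger_gap = 0.1) {
  stopifnot(n_steps >= 1, trigger_gap > 0)
  structure(list(enabled = enabled, n_steps = as.integer(n_steps),
                 trigger_gap = trigger_gap),
            class = "homotopy_config")
}

#' Robust optimal design by outer approximation
#'
#' Alternates two phases until the robustification gap closes: phase one
#' re-estimates worst-case parameters (most similar model responses) for the
#' current design by multistart minimization inside the parameter boxes and
#' appends them to the constraint set P_k; phase two computes a new design
#' that maximizes the minimum of the discrimination objective over all pairs
#' in P_k. The loop stops when |J_design - J_worst| <= eps_stop or after
#' `max_iter` iterations. Near convergence an optional homotopy ramp
#' introduces each new worst-case pair gradually to stabilize the design
#' phase.
#'
#' @param modelA,modelB [kinetic_model()]s.
#' @param space A [design_space()].
#' @param boxes List with `A` and/or `B` [parameter_box()]es of the
#'   robustified parameters.
#' @param paramsA,paramsB Full nominal parameter vectors.
#' @param init_design Feasible initial [experimental_design()].
#' @param objective_cfg An [objective_config()].
#' @param eps_stop Positive stopping tolerance on the gap (default 1e-3).
#' @param max_iter Maximum outer iterations (default 50).
#' @param homotopy A [homotopy_config()].
#' @param n_starts Multistarts of the phase-one estimation.
#' @param seed RNG seed; start s of iteration k uses a deterministic
#'   sub-stream.
#' @param warm_start Phase one warm-starts from the previous worst-case point
#'   (plus n_starts - 1 random draws)?
#' @param verbose Print one machine-parsable line per iteration?
#' @return An object of class `robust_state`: iteration count, the pair list
#'   `P`, per-iteration `designs`, `J_design`, `J_worst`, `gaps`, `stopped`
#'   flag and reason, and the final `design`/`objective`.
#' @export
robust_design <- function(modelA, modelB, space, boxes, paramsA, paramsB,
                          init_design, objective_cfg = objective_config(),
                          eps_stop = 1e-3, max_iter = 50,
                          homotopy = homotopy_config(), n_starts = 5,
                          seed = 0, warm_start = TRUE, verbose = FALSE) {
  stopifnot(eps_stop > 0, max_iter >= 1)
  feas <- design_feasible(init_design, space)
  if (!isTRUE(feas))
    stop("initial design infeasible: ", paste(feas, collapse = "; "))
  P <- list()
  designs <- list()
  J_design <- numeric(0); J_worst <- numeric(0); gaps <- numeric(0)
  design <- init_design
  stopped <- FALSE; reason <- "max_iter"
  prev_wc <- NULL
  failures <- character(0)
  # Phase 1 of round k re-estimates the worst case at the design produced by
  # phase 2 of round k-1 (the user's initial design for k = 1); the
  # robustification gap compares that re-estimated value with the design
  # phase's objective, and the loop stops before another design solve once
  # the two agree.
  for (k in seq_len(max_iter + 1L)) {
    wc <- try(worst_case_params(
      modelA, modelB, design, boxes, paramsA, paramsB, objective_cfg,
      n_starts = n_starts, seed = seed + 1000L * k,
      init = if (warm_start && !is.null(prev_wc))
        list(A = prev_wc$params1, B = prev_wc$params2) else NULL),
      silent = TRUE)
    if (inherits(wc, "try-error")) {
      failures <- c(failures, sprintf("round %d: phase one failed", k))
      reason <- "phase1_failure"; break
    }
    prev_wc <- wc
    J_worst[k] <- wc$objective
    if (k > 1) {
      gaps[k - 1] <- robustification_gap(J_design[k - 1], J_worst[k])
      if (verbose)
        cat(sprintf("iter=%d J_design=%.6g J_worst=%.6g gap=%.3g |P|=%d\n",
                    k - 1, J_design[k - 1], J_worst[k], gaps[k - 1],
                    length(P)))
      if (gaps[k - 1] <= eps_stop) {
        stopped <- TRUE; reason <- "converged"; break
      }
    }
    if (k > max_iter) break  # max_iter design solves performed
    new_pair <- list(A = wc$params1, B = wc$params2)
    is_new <- !any(vapply(P, function(pr) pair_close(pr, new_pair), TRUE))
    if (is_new) P[[length(P) + 1L]] <- new_pair
    gap_prev <- if (k > 1) gaps[k - 1] else Inf
    ramp <- homotopy$enabled && is_new && length(P) > 1 &&
      gap_prev < homotopy$trigger_gap
    n_sub <- if (ramp) homotopy$n_steps else 1L
    opt <- NULL
    for (s in seq_len(n_sub)) {
      w <- rep(1, length(P))
      if (ramp) w[length(P)] <- s / n_sub
      opt <- try(optimal_design(modelA, modelB, P, space, design,
                                objective_cfg, weights = w),
                 silent = TRUE)
      if (inherits(opt, "try-error")) break
      design <- opt$design
    }
    if (inherits(opt, "try-error") || is.null(opt)) {
      failures <- c(failures, sprintf("round %d: phase two failed", k))
      reason <- "phase2_failure"; break
    }
    designs[[k]] <- design
    # the unblended min over P_k at the accepted design
    full <- epigraph_reformulation(modelA, modelB, P, objective_cfg)
    J_design[k] <- full$eval_min(design)
  }
  k_final <- length(J_design)
  structure(list(iterations = k_final, P = P, designs = designs,
                 J_design = J_design,
                 J_worst = J_worst, gaps = gaps,
                 stopped = stopped, reason = reason, failures = failures,
                 design = design,
                 objective = if (k_final) J_design[k_final] else NA_real_,
                 worst_objective = J_worst[length(J_worst)],
                 eps_stop = eps_stop, seed = seed),
            class = "robust_state")
}

pair_close <- function(p1, p2, tol = 1e-8) {
  close_vec <- function(a, b) {
    all(abs(a - b) <= tol * pmax(abs(a), abs(b), 1))
  }
  close_vec(p1$A, p2$A) && close_vec(p1$B, p2$B)
}

#' @export
print.robust_state <- function(x, ...) {
  cat("Robust design (outer approximation)\n")
  cat(sprintf("  iterations: %d, stopped: %s (%s)\n",
              x$iterations, x$stopped, x$reason))
  if (x$iterations) {
    cat(sprintf("  final J_design = %.6g, J_worst = %.6g, gap = %.3g (eps_stop %.3g)\n",
                x$J_design[x$iterations], x$worst_objective,
                x$gaps[x$iterations], x$eps_stop))
  }
  cat(sprintf("  constraint set size |P| = %d\n", length(x$P)))
  invisible(x)
}

#' @export
plot.robust_state <- function(x, ...) {
  if (!x$iterations) {
    warning("nothing to plot"); return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  it <- seq_len(x$iterations)
  graphics::plot(it, x$gaps, type = "b", log = "y", xlab = "iteration",
                 ylab = "robustification gap", main = "Gap")
  graphics::plot(it, x$J_design, type = "b", xlab = "iteration",
                 ylab = "objective",
                 ylim = range(c(x$J_design, x$J_worst[it])),
                 main = "Objective values")
  graphics::lines(it, x$J_worst[it], type = "b", lty = 2)
  graphics::legend("topright", legend = c("design phase", "worst case"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Export the gap and objective traces of a robust run
#'
#' @param state A `robust_state`.
#' @param path Optional file path (tab-separated); if `NULL` the data frame is
#'   returned only.
#' @return Data frame with iteration, J_design, J_worst, gap.
#' @export
robust_traces <- function(state, path = NULL) {
  df <- data.frame(iteration = seq_len(state$iterations),
                   J_design = state$J_design,
                   J_worst = state$J_worst[seq_len(state$iterations)],
                   gap = state$gaps)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
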