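#' Empirical-simulation bootstrap for multistate functionals
#'
#' Resamples a multistate study without individual patient data: `B`
#' bootstrap datasets of `n` subjects are generated from the (estimated or
#' supplied) Nelson-Aalen increments by [simulate_empirical()], each
#' replicate is re-estimated (Nelson-Aalen, product integral, state
#' occupation with the replicate's own empirical initial proportions), and
#' percentile confidence intervals are formed from the empirical 2.5% and
#' 97.5% replicate quantiles (linear interpolation, `quantile type 7`).
#' Initial states of each replicate are drawn from `init`, so its sampling
#' variability is propagated into the intervals.
#'
#' @param x either an `msm_events` data.frame (increments and defaults for
#'   `init`/`n` are derived from it) or an [increment_table()].
#' @param init initial distribution (required when `x` is a table; defaults
#'   to the empirical initial proportions when `x` is data).
#' @param censoring censoring law re-applied in every replicate, e.g. the
#'   study's generative law or [censoring_km()] output.
#' @param B number of bootstrap replicates (`>= 2`).
#' @param n replicate sample size (defaults to the source number of
#'   subjects).
#' @param eval_times times at which occupation/transition probabilities are
#'   recorded.
#' @param level confidence level for the percentile interval.
#' @param seed optional integer seed.
#' @return An object of class `msm_boot`: list with the point estimates
#'   (`occupation`, `trans` from the source table), replicate arrays
#'   (`occ_rep`: `B x K x T`; `trans_rep`: `B x K x K x T`), and percentile
#'   bounds (`occ_lower`, `occ_upper`, `trans_lower`, `trans_upper`).
#' @export
empirical_bootstrap <- function(x, init = NULL, censoring = cens_none(),
                                B = 1000, n = NULL, eval_times,
                                level = 0.95, seed = NULL) {
  if (B < 2) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "msm_increments")) {
    tab <- x
    n <- n %||% attr(tab, "n_subjects")
    if (is.null(n)) stop("'n' is required when bootstrapping a bare table")
    if (is.null(init)) stop("'init' is required when bootstrapping a table")
  } else {
    space0 <- attr(x, "space")
    tab <- nelson_aalen(x, space0)
    subjects <- attr(x, "subjects")
    n <- n %||% (if (!is.null(subjects)) nrow(subjects)
                 else length(unique(x$id)))
    if (is.null(init) && !is.null(subjects)) {
      p <- table(factor(subjects$state0)) / nrow(subjects)
      init <- init_dist(stats::setNames(as.numeric(p), names(p)))
    }
    if (is.null(init)) stop("cannot derive 'init' from the data")
  }
  if (n < 1) stop("n must be >= 1")
  if (sum(tab$increment) == 0) stop("degenerate increment table: no events")
  init <- as_init(init)
  space <- inc_space(tab)
  K <- n_states(space)
  eval_times <- sort(as.numeric(eval_times))
  p0 <- numeric(K)
  p0[state_index(space, init$states)] <- init$probs

  ck <- switch(censoring$kind, none = 0L, uniform = 1L,
               administrative = 2L, `empirical-km` = 3L,
               stop("unsupported censoring kind"))
  cpar <- switch(censoring$kind,
                 uniform = c(censoring$a, censoring$b),
                 administrative = censoring$tau, numeric())
  ct <- if (ck == 3L) censoring$times else numeric()
  cp <- if (ck == 3L) censoring$probs else numeric()

  reps <- cpp_empirical_boot(sim_plan(tab), as.integer(n), as.integer(B),
                             p0, ck, cpar, ct, cp, eval_times)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qc <- function(a) apply(a, seq_along(dim(a))[-1L], stats::quantile,
                          probs = probs, type = 7, names = FALSE)
  occ_q <- qc(reps$occ)          # 2 x K x T
  trans_q <- qc(reps$trans)      # 2 x K x K x T

  point <- aalen_johansen(tab, 0, eval_times)
  occ_point <- state_occupation(point, init)
  structure(list(
    times = eval_times, level = level, B = B, n = n,
    space = space, tab = tab, init = init,
    occupation = occ_point, trans = point$P,
    occ_rep = reps$occ, trans_rep = reps$trans,
    occ_lower = array(occ_q[1, , ], dim(reps$occ)[-1L]),
    occ_upper = array(occ_q[2, , ], dim(reps$occ)[-1L]),
    trans_lower = array(trans_q[1, , , ], dim(reps$trans)[-1L]),
    trans_upper = array(trans_q[2, , , ], dim(reps$trans)[-1L])
  ), class = "msm_boot")
}

#' @export
print.msm_boot <- function(x, ...) {
  cat(sprintf(
    "Empirical-simulation bootstrap: B = %d replicates of n = %d subjects\n",
    x$B, x$n))
  K <- n_states(x$space)
  for (ti in seq_along(x$times)) {
    cat(sprintf("  t = %g:\n", x$times[ti]))
    for (j in seq_len(K)) {
      cat(sprintf("    P(X_t = %d) = %.4f  [%.4f, %.4f]\n",
                  x$space$states[j], x$occupation[ti, j],
                  x$occ_lower[j, ti], x$occ_upper[j, ti]))
    }
  }
  invisible(x)
}

#' Efron's nonparametric bootstrap (comparison baseline)
#'
#' Resamples whole subjects with replacement and re-estimates the occupation
#' probabilities.  Unlike [empirical_bootstrap()], this baseline requires the
#' individual multistate trajectories, which is exactly what published-data
#' settings lack; it exists for comparison only.
#'
#' @param data an `msm_events` data.frame.
#' @param B number of replicates.
#' @param eval_times evaluation times.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return List with `occ_rep` (`B x K x T`), `occ_lower`, `occ_upper`.
#' @export
efron_bootstrap <- function(data, B = 1000, eval_times, level = 0.95,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  space <- attr(data, "space") %||% infer_space(data)
  subjects <- attr(data, "subjects")
  ids <- if (!is.null(subjects)) subjects$id else sort(unique(data$id))
  K <- n_states(space)
  eval_times <- sort(as.numeric(eval_times))
  occ <- array(NA_real_, c(B, K, length(eval_times)))
  recs <- split(seq_len(nrow(data)), factor(data$id, levels = ids))
  st0 <- if (!is.null(subjects)) subjects$state0 else
    data$from[!duplicated(data$id)][match(ids, unique(data$id))]
  for (b in seq_len(B)) {
    pick <- sample(length(ids), replace = TRUE)
    rows <- data[unlist(recs[pick]), , drop = FALSE]
    rows$id <- rep(seq_along(pick),
                   lengths(recs[pick]))
    tab <- nelson_aalen(rows, space)
    pin <- tabulate(state_index(space, st0[pick]), K) / length(pick)
    aj <- aalen_johansen(tab, 0, eval_times)
    occ[b, , ] <- t(state_occupation(
      aj, init_dist(stats::setNames(pin, space$states))))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  q <- apply(occ, c(2, 3), stats::quantile, probs = probs, type = 7,
             names = FALSE)
  list(occ_rep = occ,
       occ_lower = array(q[1, , ], dim(occ)[-1L]),
       occ_upper = array(q[2, , ], dim(occ)[-1L]))
}

#' Analytic transition probabilities for constant hazards
#'
#' Under time-constant intensities the process is a time-homogeneous Markov
#' chain, so `P(0, t) = expm(t Q)` and the occupation probabilities are
#' `pi expm(t Q)`.  An eigendecomposition fast path handles many evaluation
#' times at once (with `Matrix::expm` as fallback); for non-constant
#' parametric models the product integral is approximated on a fine grid of
#' step `step`.
#'
#' @param model a parametric [msm_model].
#' @param t evaluation times.
#' @param step grid step for the non-constant fallback.
#' @return List with `P` (`K x K x length(t)`) and `occupation`
#'   (`length(t) x K`, using the model's initial distribution).
#' @export
truth_matrix_exponential <- function(model, t, step = 0.1) {
  stopifnot(inherits(model, "msm_model"), model$kind == "parametric")
  space <- model$space
  K <- n_states(space)
  t <- as.numeric(t)
  constant <- all(vapply(model$hazards, function(h) h$kind == "constant",
                         logical(1)))
  P <- array(NA_real_, c(K, K, length(t)),
             dimnames = list(space$states, space$states, NULL))
  if (constant) {
    Q <- intensity_matrix(model)
    eg <- eigen(Q)
    use_eigen <- all(abs(Im(eg$values)) < 1e-12) &&
      rcond(Re(eg$vectors)) > 1e-10
    if (use_eigen) {
      V <- Re(eg$vectors); lam <- Re(eg$values); Vi <- solve(V)
      for (i in seq_along(t)) {
        P[, , i] <- V %*% (exp(lam * t[i]) * Vi)
      }
    } else {
      for (i in seq_along(t)) {
        P[, , i] <- as.matrix(Matrix::expm(Q * t[i]))
      }
    }
  } else {
    tmax <- max(t)
    grid <- seq(0, tmax, by = step)
    if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
    cums <- lapply(model$hazards, function(h) h$cumulative_fn(grid))
    Pt <- diag(K)
    ti <- 1L
    for (g in seq_along(grid)) {
      if (g > 1L) {
        dA <- matrix(0, K, K)
        for (hi in seq_along(model$hazards)) {
          h <- model$hazards[[hi]]
          dA[state_index(space, h$from), state_index(space, h$to)] <-
            cums[[hi]][g] - cums[[hi]][g - 1L]
        }
        diag(dA) <- -rowSums(dA)
        Pt <- Pt %*% (diag(K) + dA)
      }
      while (ti <= length(t) && t[ti] <= grid[g] + 1e-12) {
        P[, , ti] <- Pt
        ti <- ti + 1L
      }
    }
  }
  # clamp tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  pi_full <- numeric(K)
  pi_full[state_index(space, model$init$states)] <- model$init$probs
  occupation <- t(apply(P, 3L, function(p) as.numeric(pi_full %*% p)))
  dimnames(occupation) <- list(NULL, space$states)
  list(P = P, occupation = occupation)
}

#' Nested coverage experiment for multistate confidence intervals
#'
#' Mirrors the design of the proof-of-concept coverage studies: for each
#' sample size, `R_studies` studies are simulated from the parametric truth
#' model by [simulate_parametric()]; per study a 95% confidence interval for
#' every state-occupation probability `P(X_t = j)` is built either by the
#' empirical-simulation percentile bootstrap (`B_boot` replicates of the
#' study's Nelson-Aalen measure, study-sized, with the study's censoring law
#' re-applied) or by the log-log transformed Wald interval with Aalen-type
#' variances; the reported coverage is the fraction of studies whose
#' interval covers the matrix-exponential truth.  Cells whose truth is
#' exactly 0 or 1 are flagged as degenerate (the estimator is typically
#' exactly equal to the truth there, and coverage is reported by the
#' containment convention but should be read separately).
#'
#' @param truth_model a parametric constant-hazard [msm_model]; its initial
#'   distribution and censoring law are part of the design.
#' @param n_grid study sample sizes.
#' @param t_grid evaluation times.
#' @param R_studies number of simulated studies (`>= 50`; coverage over
#'   fewer studies is meaningless and refused).
#' @param B_boot bootstrap replicates per study (percentile method).
#' @param method `"bootstrap-percentile"` or `"loglog-wald"`.
#' @param level nominal confidence level.
#' @param seed optional integer seed.
#' @return data.frame of class `msm_coverage` with columns `n`, `t`, `state`,
#'   `quantity`, `truth`, `coverage`, `mc_se` (`sqrt(c(1-c)/R)`),
#'   `degenerate`.
#' @export
coverage_experiment <- function(truth_model, n_grid, t_grid, R_studies,
                                B_boot = NULL,
                                method = c("bootstrap-percentile",
                                           "loglog-wald"),
                                level = 0.95, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(truth_model, "msm_model"),
            truth_model$kind == "parametric")
  if (R_studies < 50) {
    stop("R_studies < 50 refused: coverage estimates would be meaningless")
  }
  if (method == "bootstrap-percentile" && is.null(B_boot)) B_boot <- 1000
  if (!is.null(seed)) set.seed(seed)
  space <- truth_model$space
  K <- n_states(space)
  t_grid <- sort(as.numeric(t_grid))
  truth <- truth_matrix_exponential(truth_model, t_grid)$occupation
  out <- list()
  for (n in n_grid) {
    hits <- matrix(0, length(t_grid), K)
    for (r in seq_len(R_studies)) {
      study <- simulate_parametric(truth_model, n)
      subjects <- attr(study, "subjects")
      pin <- tabulate(state_index(space, subjects$state0), K) / n
      init_hat <- init_dist(stats::setNames(pin, space$states))
      if (method == "bootstrap-percentile") {
        # replicate initial states are drawn from the design's published
        # initial proportions -- the information available without IPD --
        # while each replicate's occupation estimate plugs in its own
        # empirical proportions
        bt <- empirical_bootstrap(nelson_aalen(study, space),
                                  init = truth_model$init,
                                  censoring = truth_model$censoring,
                                  B = B_boot, n = n,
                                  eval_times = t_grid, level = level)
        cov_r <- t(bt$occ_lower) <= truth & truth <= t(bt$occ_upper)
      } else {
        tab <- nelson_aalen(study, space)
        av <- aalen_variance(tab, weights = init_hat)
        aj <- aalen_johansen(tab, 0, t_grid)
        occ <- state_occupation(aj, init_hat)
        # variance at the last grid time <= t
        vidx <- findInterval(t_grid, av$times)
        v <- matrix(0, length(t_grid), K)
        v[vidx > 0, ] <- av$occ_var[vidx[vidx > 0], , drop = FALSE]
        ci <- loglog_ci(as.numeric(occ), as.numeric(v), level)
        lo <- matrix(ci$lower, length(t_grid), K)
        up <- matrix(ci$upper, length(t_grid), K)
        cov_r <- lo <= truth & truth <= up
      }
      hits <- hits + cov_r
    }
    cv <- hits / R_studies
    out[[length(out) + 1L]] <- data.frame(
      n = n,
      t = rep(t_grid, K),
      state = rep(space$states, each = length(t_grid)),
      quantity = sprintf("P(X_t = %d)",
                         rep(space$states, each = length(t_grid))),
      truth = as.numeric(truth),
      coverage = as.numeric(cv),
      mc_se = sqrt(as.numeric(cv) * (1 - as.numeric(cv)) / R_studies),
      degenerate = as.numeric(truth) <= 0 | as.numeric(truth) >= 1
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("msm_coverage", "data.frame")
  res
}
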