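#' Construct / validate a hazard-increment table
#'
#' An increment table holds the discrete-time increments of the cumulative
#' transition hazards on a strictly increasing grid of event times: one row
#' per `(time, from, to)` with the increment `#events / #at-risk`, optionally
#' carrying the at-risk count.  It is the exchange format between estimation
#' ([nelson_aalen()]), the empirical simulator ([simulate_empirical()]) and
#' the product-integral machinery ([aalen_johansen()]), and is exactly what
#' can be digitized from published cumulative-hazard plots.
#'
#' @param df data.frame with columns `time`, `from`, `to`, `increment` and
#'   optionally `risk_set`.
#' @param space an [msm_space]; if omitted it is inferred: states are all
#'   labels seen in `from`/`to`, and labels never appearing in `from` are
#'   taken as absorbing.
#' @return The validated table, sorted by `(time, from, to)`, of class
#'   `msm_increments` with the state space in `attr(, "space")`.
#' @export
increment_table <- function(df, space = NULL) {
  need <- c("time", "from", "to", "increment")
  if (!all(need %in% names(df))) {
    stop("increment table needs columns ", paste(need, collapse = ", "))
  }
  df$from <- as.integer(df$from); df$to <- as.integer(df$to)
  if (any(df$increment < 0)) stop("negative increments")
  if (any(df$time <= 0)) stop("grid times must be positive")
  key <- paste(df$time, df$from, df$to)
  if (anyDuplicated(key)) stop("duplicate (time, from, to) rows")
  df <- df[order(df$time, df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(space)) {
    states <- sort(unique(c(df$from, df$to)))
    absorbing <- setdiff(states, unique(df$from))
    space <- msm_space(states, unique(df[, c("from", "to")]), absorbing)
  } else {
    for (i in seq_len(nrow(df))) {
      if (!has_transition(space, df$from[i], df$to[i])) {
        stop("increment on forbidden transition ", df$from[i], "->", df$to[i])
      }
    }
  }
  for (l in unique(df$from)) {
    rows <- df[df$from == l, , drop = FALSE]
    if (any(groupsum_by_time(rows$time, rows$increment)$sum > 1 + 1e-12)) {
      stop("all-cause increment exceeds 1 at some grid time ",
           "(sum_m dA_lm(u) must be <= 1)")
    }
  }
  structure(df, space = space,
            class = c("msm_increments", "data.frame"))
}

inc_space <- function(tab) attr(tab, "space")

# Sum values over exactly equal double times (no string round trip, which
# would silently merge or shift close grid times).
groupsum_by_time <- function(time, value) {
  u <- sort(unique(time))
  s <- as.numeric(rowsum(value, match(time, u), reorder = TRUE))
  list(time = u, sum = s)
}

#' Nelson-Aalen increments from event-history data
#'
#' For every permitted transition `l -> m`, the increment at an observed
#' transition time `u` is the number of observed `l -> m` transitions at `u`
#' divided by the number of individuals observed in state `l` just prior to
#' `u`.  Risk sets use left limits: a subject entering a state exactly at `u`
#' (delayed entry) is not at risk at `u`, while a subject whose record ends at
#' `u` (event or censoring) still is.  Times without events do not enter the
#' grid.
#'
#' @param data event-history data.frame (columns `id`, `from`, `to`, `entry`,
#'   `exit`, `status`; `status` 1 = event, 0 = censored).
#' @param space an [msm_space]; inferred from the data when omitted.
#' @return An [increment_table()] with `risk_set` column; the number of
#'   subjects is attached as `attr(, "n_subjects")`.
#' @export
nelson_aalen <- function(data, space = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(space)) space <- infer_space(data)
  ev <- data[data$status == 1L, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no event records in the data")
  rows <- vector("list", nrow(space$transitions))
  for (i in seq_len(nrow(space$transitions))) {
    l <- space$transitions[i, 1L]; m <- space$transitions[i, 2L]
    tm <- ev$exit[ev$from == l & ev$to == m]
    if (length(tm) == 0L) next
    u <- sort(unique(tm))           # exact double comparison: no string round trip
    cnt <- tabulate(match(tm, u), nbins = length(u))
    recs <- data[data$from == l, , drop = FALSE]
    se <- sort(recs$entry); sx <- sort(recs$exit)
    # at risk just prior to u: entry < u and exit >= u
    y <- findInterval(u, se, left.open = TRUE) - findInterval(u, sx, left.open = TRUE)
    if (any(y <= 0)) {
      stop("zero risk set in state ", l, " at an event time; corrupt data")
    }
    rows[[i]] <- data.frame(time = unname(u), from = l, to = m,
                            increment = unname(as.numeric(cnt) / y),
                            risk_set = unname(y), row.names = NULL)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no events on permitted transitions")
  tab <- increment_table(do.call(rbind, rows), space)
  attr(tab, "n_subjects") <- length(unique(data$id))
  tab
}

infer_space <- function(data) {
  states <- sort(unique(c(data$from, data$to[!is.na(data$to)])))
  ev <- data[data$status == 1L & !is.na(data$to), c("from", "to")]
  trans <- unique(ev)
  absorbing <- setdiff(states, unique(data$from))
  msm_space(states, trans, absorbing)
}

#' Aalen-Johansen transition probability estimator
#'
#' Computes the product-integral plug-in estimator
#' `P(s, t) = prod_{s < u <= t} (I + dA(u))` over the grid times of an
#' increment table, where `dA(u)` has the table's off-diagonal increments and
#' row sums zero.  All transitions tied at the same time enter one joint
#' factor.
#'
#' @param tab an [increment_table()].
#' @param s anchor time (default 0).
#' @param times evaluation times `>= s`; defaults to the table grid.
#' @return An object of class `msm_probs`: list with `s`, `times` and the
#'   `K x K x length(times)` array `P` (dimnames are state labels).
#' @export
aalen_johansen <- function(tab, s = 0, times = NULL) {
  stopifnot(inherits(tab, "msm_increments"))
  space <- inc_space(tab)
  if (is.null(times)) times <- tab$time[tab$time >= s]
  times <- sort(unique(as.numeric(times)))
  if (length(times) == 0L) stop("no evaluation times")
  if (any(times < s)) stop("evaluation times must satisfy s <= t")
  K <- n_states(space)
  P <- cpp_prod_integral(
    as.numeric(tab$time),
    state_index(space, tab$from) - 1L,
    state_index(space, tab$to) - 1L,
    as.numeric(tab$increment),
    as.numeric(s), times, K
  )
  dim(P) <- c(K, K, length(times))
  dimnames(P) <- list(space$states, space$states, NULL)
  structure(list(s = s, times = times, P = P, space = space),
            class = "msm_probs")
}

#' @export
print.msm_probs <- function(x, ...) {
  cat(sprintf("Aalen-Johansen transition probabilities P(%g, t) at %d times\n",
              x$s, length(x$times)))
  tl <- x$times[length(x$times)]
  cat(sprintf("P(%g, %g):\n", x$s, tl))
  print(round(x$P[, , length(x$times)], 4))
  invisible(x)
}

#' State-occupation probabilities
#'
#' Mixes the rows of `P(0, t)` with the initial distribution:
#' `P(X_t = j) = sum_l pi_l * P_lj(0, t)`.  Requires anchor `s = 0`.
#'
#' @param res an `msm_probs` result from [aalen_johansen()] with `s = 0`.
#' @param init an [init_dist] (or named probability vector).
#' @return Matrix `length(times) x K` of occupation probabilities; times as
#'   rownames-compatible attribute `times`.
#' @export
state_occupation <- function(res, init) {
  stopifnot(inherits(res, "msm_probs"))
  if (res$s != 0) stop("state occupation requires anchor s = 0")
  init <- as_init(init)
  K <- n_states(res$space)
  pi_full <- numeric(K)
  pi_full[state_index(res$space, init$states)] <- init$probs
  occ <- t(apply(res$P, 3L, function(p) as.numeric(pi_full %*% p)))
  dimnames(occ) <- list(NULL, res$space$states)
  attr(occ, "times") <- res$times
  occ
}

#' Aalen-type covariance of the Aalen-Johansen estimator
#'
#' Runs the recursion for the covariance of `vec P(0, t)` along the grid:
#' with `F(u) = I + dA(u)`,
#' `Sigma(u) = (F' (x) I) Sigma(u-) (F' (x) I)' + (I (x) P(0,u-)) Psi(u) (I (x) P(0,u-))'`
#' where `Psi(u)` is the estimated (multinomial-type) covariance of the
#' increment matrix built from the risk sets, with
#' `cov(dA_lm, dA_lm') = (delta_mm' dA_lm - dA_lm dA_lm') / Y_l(u)` and the
#' diagonal entries filled in by linearity from `dA_ll = -sum_m dA_lm`.
#' Variances are zero before the first event time.
#'
#' @param tab an [increment_table()] with `risk_set` present.
#' @param weights optional initial distribution; when supplied, variances of
#'   the occupation probabilities `sum_l pi_l P_lj(0, t)` (treating the
#'   weights as fixed) are returned as well.
#' @return List with `times` (the grid), `var` (`K x K x J` array of
#'   variances of `P_lm(0, t_j)`), and `occ_var` (`J x K`, when `weights`
#'   given).
#' @export
aalen_variance <- function(tab, weights = NULL) {
  stopifnot(inherits(tab, "msm_increments"))
  if (is.null(tab$risk_set) || anyNA(tab$risk_set)) {
    stop("risk sets are required for the Aalen-type variance estimator")
  }
  space <- inc_space(tab)
  K <- n_states(space)
  grid <- sort(unique(tab$time))
  J <- length(grid)
  Sig <- matrix(0, K * K, K * K)
  P <- diag(K)
  IK <- diag(K)
  v <- array(0, c(K, K, J), dimnames = list(space$states, space$states, NULL))
  w_full <- NULL
  occ_var <- NULL
  if (!is.null(weights)) {
    weights <- as_init(weights)
    w_full <- numeric(K)
    w_full[state_index(space, weights$states)] <- weights$probs
    occ_var <- matrix(0, J, K, dimnames = list(NULL, space$states))
  }
  row_of <- split(seq_len(nrow(tab)), match(tab$time, grid))
  for (j in seq_len(J)) {
    idx <- row_of[[as.character(j)]] %||% integer()
    if (length(idx) == 0L) next
    dA <- matrix(0, K, K)
    Psi <- matrix(0, K * K, K * K)
    for (l in unique(tab$from[idx])) {
      li <- state_index(space, l)
      sel <- idx[tab$from[idx] == l]
      Y <- tab$risk_set[sel][1L]
      d <- numeric(K)
      d[state_index(space, tab$to[sel])] <- tab$increment[sel]
      dA[li, ] <- dA[li, ] + d
      Cl <- (diag(d) - tcrossprod(d)) / Y        # cov over destinations m != l
      Cl[li, ] <- 0; Cl[, li] <- 0
      B <- Cl
      B[li, ] <- -colSums(Cl)
      B[, li] <- -rowSums(Cl)
      B[li, li] <- sum(Cl)
      pos <- li + (seq_len(K) - 1L) * K          # vec positions of row l
      Psi[pos, pos] <- Psi[pos, pos] + B
    }
    diag(dA) <- -rowSums(dA)
    Ff <- IK + dA
    G <- kronecker(t(Ff), IK)
    H <- kronecker(IK, P)
    Sig <- G %*% Sig %*% t(G) + H %*% Psi %*% t(H)
    P <- P %*% Ff
    v[, , j] <- matrix(pmax(diag(Sig), 0), K, K)
    if (!is.null(w_full)) {
      for (m in seq_len(K)) {
        a <- numeric(K * K)
        a[seq_len(K) + (m - 1L) * K] <- w_full
        occ_var[j, m] <- max(0, as.numeric(a %*% Sig %*% a))
      }
    }
  }
  # carry forward between event-free grid points (none by construction, but
  # keep the contract explicit for tables with all-zero rows removed upstream)
  list(times = grid, var = v, occ_var = occ_var)
}

#' Log-log transformed confidence interval for a probability
#'
#' Computes `p ^ exp(-+ z * sqrt(v) / (p * log p))`, the Wald interval on the
#' `log(-log p)` scale mapped back to `[0, 1]`.  Degenerate inputs
#' (`p` in `{0, 1}` or zero variance) return the point itself.
#'
#' @param p_hat estimated probabilities in `[0, 1]` (vectorized).
#' @param var_hat variance estimates, `>= 0`.
#' @param level confidence level in (0, 1).
#' @return data.frame with columns `lower`, `upper`.
#' @export
loglog_ci <- function(p_hat, var_hat, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("'level' must be inside (0, 1)")
  if (any(var_hat < 0)) stop("negative variance")
  z <- stats::qnorm(1 - (1 - level) / 2)
  n <- max(length(p_hat), length(var_hat))
  p <- rep_len(p_hat, n); v <- rep_len(var_hat, n)
  lower <- upper <- p
  ok <- p > 0 & p < 1 & v > 0
  theta <- z * sqrt(v[ok]) / (p[ok] * log(p[ok]))
  lower[ok] <- p[ok]^exp(-theta)
  upper[ok] <- p[ok]^exp(theta)
  lo <- pmin(lower, upper); up <- pmax(lower, upper)
  data.frame(lower = lo, upper = up)
}

#' Censoring distribution by reverse Kaplan-Meier
#'
#' Estimates the distribution of the right-censoring times from an
#' event-history dataset by swapping the roles of events and censorings:
#' per subject the follow-up ends at the last record's exit, "event" meaning
#' censored.  At tied times events precede censorings, i.e. subjects ending
#' in an event at `c` are still at risk for censoring at `c` (this matches
#' `survival::survfit` on the reversed data).  Residual mass (when the last
#' observation is an event) is assigned to a sentinel atom beyond the last
#' time, meaning "never censored".
#'
#' @param data event-history data.frame.
#' @return An [msm_censoring][censoring] object: `cens_km(...)` when censored
#'   records exist, else `cens_none()`.
#' @export
censoring_km <- function(data) {
  stopifnot(is.data.frame(data))
  o <- order(data$id, data$entry)
  d <- data[o, , drop = FALSE]
  last <- !duplicated(d$id, fromLast = TRUE)
  fu <- d$exit[last]
  cens <- d$status[last] == 0L
  if (!any(cens)) return(cens_none())
  ct <- sort(unique(fu[cens]))
  surv <- 1
  atoms <- numeric(length(ct))
  sfu <- sort(fu)
  for (k in seq_along(ct)) {
    u <- ct[k]
    Y <- length(fu) - findInterval(u, sfu, left.open = TRUE)  # #{fu >= u}
    dc <- sum(fu == u & cens)
    atoms[k] <- surv * dc / Y
    surv <- surv * (1 - dc / Y)
  }
  cens_km(ct, atoms, residual = max(0, 1 - sum(atoms)))
}
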