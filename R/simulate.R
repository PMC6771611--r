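#' Simulate trajectories from a parametric multistate model
#'
#' Generates multistate event histories by the hazard-based nested
#' competing-risks construction: starting from an initial state drawn from
#' the model's initial distribution, the waiting time in the current state
#' `l` is drawn from the all-cause survival
#' `exp(-(A_l.(t) - A_l.(t*)))`, and only then is the destination drawn with
#' probabilities `alpha_lm(T) / alpha_l.(T)` evaluated at the realized event
#' time.  No latent times are ever generated and the transition type is never
#' decided before the event time.  Constant-hazard models use a vectorized
#' exponential sampler; general intensities use inversion with bracketed
#' root-finding on the cumulative all-cause hazard (tolerance 1e-10).
#'
#' @param model a validated parametric [msm_model].
#' @param n number of subjects.
#' @param horizon follow-up horizon; defaults to the model's.  A finite
#'   horizon (or censoring) is required when some transient state has zero
#'   all-cause hazard, otherwise the sojourn there would never end.
#' @param censoring right-censoring law; defaults to the model's.
#' @param seed optional integer seed (`set.seed`) for reproducibility.
#' @return Event-history data.frame (`id`, `from`, `to`, `entry`, `exit`,
#'   `status`) of class `msm_events`; `attr(, "subjects")` holds one row per
#'   subject (`id`, `state0`) including those absorbed at the origin, and
#'   `attr(, "space")` the state space.
#' @export
simulate_parametric <- function(model, n, horizon = NULL, censoring = NULL,
                                seed = NULL) {
  stopifnot(inherits(model, "msm_model"), model$kind == "parametric", n >= 1)
  if (!is.null(seed)) set.seed(seed)
  horizon <- horizon %||% model$horizon
  censoring <- censoring %||% model$censoring
  space <- model$space
  constant <- all(vapply(model$hazards, function(h) h$kind == "constant",
                         logical(1)))
  if (constant) {
    Q <- intensity_matrix(model)
    out_rate <- -diag(Q)
    transient <- !(space$states %in% space$absorbing)
    if (any(out_rate[transient] == 0) && !is.finite(horizon) &&
        censoring$kind == "none") {
      stop("transient state with zero all-cause hazard: ",
           "a finite horizon or censoring is required")
    }
  }
  K <- n_states(space)
  init_p <- numeric(K)
  init_p[state_index(space, model$init$states)] <- model$init$probs
  s0 <- sample.int(K, n, replace = TRUE, prob = init_p)
  cens <- pmin(draw_censoring(censoring, n), horizon)
  dat <- if (constant) {
    sim_constant_markov(Q, space, s0, cens)
  } else {
    sim_general(model, s0, cens)
  }
  subjects <- data.frame(id = seq_len(n), state0 = space$states[s0])
  structure(dat, subjects = subjects, space = space,
            class = c("msm_events", "data.frame"))
}

# vectorized exponential sampler for time-homogeneous Markov models
sim_constant_markov <- function(Q, space, s0, cens) {
  K <- nrow(Q)
  out_rate <- -diag(Q)
  dest_cum <- lapply(seq_len(K), function(l) {
    p <- Q[l, ]; p[l] <- 0
    if (sum(p) > 0) cumsum(p / sum(p)) else rep(1, K)
  })
  absorbing <- space$states %in% space$absorbing
  state <- s0
  tcur <- numeric(length(s0))
  alive <- !absorbing[state]
  recs <- list()
  while (any(alive)) {
    idx <- which(alive)
    rate <- out_rate[state[idx]]
    w <- rep(Inf, length(idx))
    pos <- rate > 0
    w[pos] <- stats::rexp(sum(pos), rate[pos])
    tnew <- tcur[idx] + w
    ev <- tnew <= cens[idx]
    # censored / horizon-reached sojourns
    ci <- idx[!ev]
    if (length(ci)) {
      keep <- is.finite(cens[ci]) & cens[ci] > tcur[ci]
      ci <- ci[keep]
      if (length(ci)) {
        recs[[length(recs) + 1L]] <- data.frame(
          id = ci, from = space$states[state[ci]], to = NA_integer_,
          entry = tcur[ci], exit = cens[ci], status = 0L)
      }
      alive[idx[!ev]] <- FALSE
    }
    ei <- idx[ev]
    if (length(ei)) {
      u <- stats::runif(length(ei))
      dest <- integer(length(ei))
      for (l in unique(state[ei])) {
        sel <- state[ei] == l
        dest[sel] <- findInterval(u[sel], dest_cum[[l]], left.open = TRUE) + 1L
      }
      recs[[length(recs) + 1L]] <- data.frame(
        id = ei, from = space$states[state[ei]], to = space$states[dest],
        entry = tcur[ei], exit = tnew[ev], status = 1L)
      tcur[ei] <- tnew[ev]
      state[ei] <- dest
      alive[ei] <- !absorbing[dest]
    }
  }
  dat <- do.call(rbind, c(recs, list(empty_events())))
  dat <- dat[order(dat$id, dat$entry), , drop = FALSE]
  rownames(dat) <- NULL
  dat
}

empty_events <- function() {
  data.frame(id = integer(), from = integer(), to = integer(),
             entry = numeric(), exit = numeric(), status = integer())
}

# general intensities: per-subject inversion with root bracketing
sim_general <- function(model, s0, cens) {
  space <- model$space
  by_from <- split(model$hazards,
                   vapply(model$hazards, function(h) h$from, integer(1)))
  recs <- list()
  for (i in seq_along(s0)) {
    s <- space$states[s0[i]]
    tcur <- 0
    visits <- stats::setNames(integer(n_states(space)),
                              as.character(space$states))
    path <- list(c(state = s, time = 0))
    repeat {
      if (is_absorbing(space, s)) break
      hs <- by_from[[as.character(s)]]
      hist <- list(state = s, time = tcur, arrival = tcur,
                   visits = visits, path = path)
      Acum <- function(t) sum(vapply(hs, function(h) h$cumulative_fn(t),
                                     numeric(1)))
      E <- stats::rexp(1)
      A0 <- Acum(tcur)
      f <- function(t) Acum(t) - A0 - E
      upper <- max(tcur * 2, tcur + 1)
      lim <- if (is.finite(cens[i])) cens[i] else 1e12
      while (upper < lim && f(upper) < 0) {
        upper <- upper * 2
      }
      tev <- if (f(min(upper, lim)) < 0) Inf else {
        stats::uniroot(f, c(tcur, min(upper, lim)), tol = 1e-10)$root
      }
      if (!is.finite(tev) || tev > cens[i]) {
        if (is.finite(cens[i]) && cens[i] > tcur) {
          recs[[length(recs) + 1L]] <- data.frame(
            id = i, from = s, to = NA_integer_, entry = tcur,
            exit = cens[i], status = 0L)
        } else if (!is.finite(cens[i])) {
          stop("all-cause hazard never accumulates in state ", s,
               " and no censoring/horizon applies")
        }
        break
      }
      rates <- vapply(hs, function(h) h$rate_fn(tev, hist), numeric(1))
      if (sum(rates) <= 0) rates <- rates + 1e-300
      m <- hs[[sample.int(length(hs), 1L, prob = rates)]]$to
      recs[[length(recs) + 1L]] <- data.frame(
        id = i, from = s, to = m, entry = tcur, exit = tev, status = 1L)
      tcur <- tev
      visits[as.character(m)] <- visits[as.character(m)] + 1L
      path[[length(path) + 1L]] <- c(state = m, time = tev)
      s <- m
    }
  }
  dat <- do.call(rbind, c(recs, list(empty_events())))
  rownames(dat) <- NULL
  dat
}

#' Empirical waiting-time distribution out of a state
#'
#' Builds the Kaplan-Meier-type distribution of the next event time out of
#' state `l` for a subject occupying `l` at time `t_star`:
#' `F_l(t) = 1 - prod_{t* < u <= t} (1 - dA_l.(u))` over the table grid,
#' with the atom at `u` equal to the all-cause increment times the
#' probability of having had no event strictly before `u`.  Probability mass
#' not spent by the largest observed time is the residual atom; drawing it
#' censors the subject there.
#'
#' @param tab an [increment_table()].
#' @param from transient state label.
#' @param t_star current time (support of the distribution is strictly
#'   greater).
#' @return List of class `empirical_waiting` with `times`, `probs`,
#'   `residual`.
#' @export
empirical_waiting <- function(tab, from, t_star = 0) {
  stopifnot(inherits(tab, "msm_increments"))
  space <- inc_space(tab)
  if (is_absorbing(space, from)) stop("state ", from, " is absorbing")
  if (t_star < 0) stop("t_star must be >= 0")
  rows <- tab[tab$from == as.integer(from), , drop = FALSE]
  gs <- groupsum_by_time(rows$time, rows$increment)
  keep <- gs$time > t_star
  u <- gs$time[keep]; allc <- gs$sum[keep]
  if (length(u) == 0L) {
    return(structure(list(times = numeric(), probs = numeric(), residual = 1,
                          from = from, t_star = t_star),
                     class = "empirical_waiting"))
  }
  surv_before <- cumprod(c(1, 1 - allc[-length(allc)]))
  probs <- pmax(surv_before * allc, 0)
  structure(list(times = u, probs = probs,
                 residual = max(0, 1 - sum(probs)),
                 from = from, t_star = t_star),
            class = "empirical_waiting")
}

# Sampling plan handed to the C++ kernels.
sim_plan <- function(tab) {
  space <- inc_space(tab)
  K <- n_states(space)
  grid <- sort(unique(tab$time))
  states <- vector("list", K)
  for (li in seq_len(K)) {
    l <- space$states[li]
    rows <- tab[tab$from == l, , drop = FALSE]
    if (nrow(rows) == 0L) next
    gs <- groupsum_by_time(rows$time, rows$increment)
    u <- gs$time; allc <- pmin(gs$sum, 1)
    dest <- lapply(seq_along(u), function(k) {
      r <- rows[rows$time == u[k], , drop = FALSE]
      list(m = state_index(space, r$to) - 1L,
           cum = cumsum(r$increment) / sum(r$increment))
    })
    ndest <- vapply(dest, function(d) length(d$m), integer(1))
    states[[li]] <- list(
      gidx = match(u, grid) - 1L,
      t = u,
      logS = cumsum(log1p(-allc)),
      doff = as.integer(c(0, cumsum(ndest))),
      dstate = as.integer(unlist(lapply(dest, `[[`, "m"))),
      dcum = as.numeric(unlist(lapply(dest, `[[`, "cum")))
    )
  }
  list(K = K, grid = grid,
       absorbing = space$states %in% space$absorbing,
       states = states)
}

#' Simulate trajectories from an empirical hazard measure
#'
#' The empirical analogue of [simulate_parametric()]: the waiting time out of
#' the current state is drawn by a multinomial experiment over the atoms of
#' [empirical_waiting()], i.e. over the Nelson-Aalen increments, and the
#' destination is then drawn proportional to the transition-specific
#' increments at the realized time.  Event times therefore live on the
#' discrete grid of the source table.  A draw of the residual atom censors
#' the subject at the largest observed event time; an independent censoring
#' law can be superimposed (censoring times may fall off-grid and clip the
#' trajectory).  No individual patient data enter: the increment table, an
#' initial distribution and (optionally) a censoring law are all that is
#' needed.
#'
#' @param tab an [increment_table()].
#' @param init an [init_dist] (or named probability vector) over transient
#'   states.
#' @param n number of subjects.
#' @param censoring an [msm_censoring][censoring] law to superimpose.
#' @param seed optional integer seed.
#' @return An `msm_events` data.frame as in [simulate_parametric()].
#' @export
simulate_empirical <- function(tab, init, n, censoring = cens_none(),
                               seed = NULL) {
  stopifnot(inherits(tab, "msm_increments"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  space <- inc_space(tab)
  init <- as_init(init)
  on_abs <- intersect(init$states[init$probs > 0], space$absorbing)
  if (length(on_abs) && !init$allow_absorbing) {
    stop("initial mass on absorbing state(s); override via init_dist()")
  }
  K <- n_states(space)
  p0 <- numeric(K)
  p0[state_index(space, init$states)] <- init$probs
  s0 <- sample.int(K, n, replace = TRUE, prob = p0)
  cens <- draw_censoring(censoring, n)
  raw <- cpp_sim_empirical(sim_plan(tab), s0 - 1L, cens)
  dat <- data.frame(id = raw$id,
                    from = space$states[raw$from + 1L],
                    to = space$states[raw$to + 1L],
                    entry = raw$entry, exit = raw$exit, status = raw$status)
  subjects <- data.frame(id = seq_len(n), state0 = space$states[s0])
  structure(dat, subjects = subjects, space = space,
            class = c("msm_events", "data.frame"))
}

#' Superimpose independent left-truncation
#'
#' Draws a delayed study-entry time per subject from `entry_law`; subjects
#' whose entry falls at or beyond their last observed time are dropped
#' entirely (never enter the study), and the remaining subjects' records are
#' clipped to start at the entry time.
#'
#' @param data an `msm_events` data.frame.
#' @param entry_law either a function `n -> entry times` or a numeric vector
#'   (one entry time per subject, recycled).
#' @return The truncated `msm_events` data.frame (a warning is emitted when
#'   nobody remains).
#' @export
superimpose_truncation <- function(data, entry_law) {
  stopifnot(is.data.frame(data))
  subjects <- attr(data, "subjects")
  ids <- if (!is.null(subjects)) subjects$id else sort(unique(data$id))
  ent <- if (is.function(entry_law)) entry_law(length(ids))
         else rep_len(as.numeric(entry_law), length(ids))
  if (any(ent < 0)) stop("entry times must be >= 0")
  entry_of <- ent[match(data$id, ids)]
  keep <- data$exit > entry_of
  out <- data[keep, , drop = FALSE]
  out$entry <- pmax(out$entry, entry_of[keep])
  kept_ids <- unique(out$id)
  if (nrow(out) == 0L) warning("left-truncation removed every subject")
  rownames(out) <- NULL
  structure(out,
            subjects = if (!is.null(subjects))
              subjects[subjects$id %in% kept_ids, , drop = FALSE],
            space = attr(data, "space"),
            class = c("msm_events", "data.frame"))
}

#' Exposure-free and overall survival times of simulated trajectories
#'
#' `efs_times()` reads off the waiting time in the initial state (the first
#' exit, or the censoring time when the subject is censored before leaving);
#' `os_times()` the arrival time in an absorbing state (censored at the last
#' observed time otherwise).  Subjects without records (absorbed at the
#' origin) get time 0 with status 1.
#'
#' @param data an `msm_events` data.frame.
#' @return data.frame `id`, `time`, `status` (1 = observed, 0 = censored).
#' @export
efs_times <- function(data) {
  o <- order(data$id, data$entry)
  d <- data[o, , drop = FALSE]
  first <- !duplicated(d$id)
  res <- data.frame(id = d$id[first], time = d$exit[first],
                    status = d$status[first])
  add_missing_subjects(res, data, 0, 1L)
}

#' @rdname efs_times
#' @export
os_times <- function(data) {
  space <- attr(data, "space")
  absorbing <- if (!is.null(space)) space$absorbing else
    setdiff(unique(data$to[!is.na(data$to)]), unique(data$from))
  o <- order(data$id, data$entry)
  d <- data[o, , drop = FALSE]
  last <- !duplicated(d$id, fromLast = TRUE)
  hit <- d$status == 1L & d$to %in% absorbing
  res <- data.frame(id = d$id[last], time = d$exit[last],
                    status = as.integer(hit[last]))
  add_missing_subjects(res, data, 0, 1L)
}

add_missing_subjects <- function(res, data, time, status) {
  subjects <- attr(data, "subjects")
  if (!is.null(subjects)) {
    miss <- setdiff(subjects$id, res$id)
    if (length(miss)) {
      res <- rbind(res, data.frame(id = miss, time = time, status = status))
    }
  }
  res[order(res$id), , drop = FALSE]
}

#' Validate an event-history dataset
#'
#' Checks the long-format contract: `entry < exit` on every record, records
#' per subject chronologically contiguous (each next record starts where and
#' when the previous event left off), destinations permitted by the state
#' space, censored records carrying no destination, and nothing following
#' absorption.
#'
#' @param data event-history data.frame.
#' @param space optional [msm_space] (inferred when omitted).
#' @return Invisibly `TRUE`; stops with an informative message otherwise.
#' @export
validate_event_history <- function(data, space = NULL) {
  need <- c("id", "from", "to", "entry", "exit", "status")
  if (!all(need %in% names(data))) {
    stop("event data needs columns ", paste(need, collapse = ", "))
  }
  if (is.null(space)) space <- infer_space(data)
  bad <- which(!(data$entry < data$exit))
  if (length(bad)) stop("entry >= exit in row(s) ", paste(bad, collapse = ","))
  if (any(data$status == 0L & !is.na(data$to))) {
    stop("censored records must not name a destination")
  }
  if (any(data$status == 1L & is.na(data$to))) {
    stop("event records must name a destination")
  }
  ev <- data[data$status == 1L, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    if (!has_transition(space, ev$from[i], ev$to[i])) {
      stop("forbidden transition ", ev$from[i], "->", ev$to[i], " in data")
    }
  }
  o <- order(data$id, data$entry)
  d <- data[o, , drop = FALSE]
  same <- d$id[-1L] == d$id[-nrow(d)]
  if (any(same)) {
    prev <- which(same)
    contig <- d$entry[prev + 1L] == d$exit[prev] &
      d$from[prev + 1L] == d$to[prev] & d$status[prev] == 1L
    if (!all(contig)) {
      stop("records of subject(s) ",
           paste(unique(d$id[prev + 1L][!contig]), collapse = ","),
           " are not chronologically contiguous")
    }
  }
  invisible(TRUE)
}
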