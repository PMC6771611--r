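#' Define a multistate state space
#'
#' A state space is a directed graph on a finite set of state labels together
#' with the set of permitted `l -> m` transitions and the subset of absorbing
#' states.  Absorbing states have no outgoing transitions; every transient
#' (non-absorbing) state must have at least one.
#'
#' @param states integer vector of unique state labels (conventionally
#'   `0:(K-1)`, with absorbing states carrying the largest labels, but any
#'   labelling is accepted).
#' @param transitions two-column matrix (or data.frame) of permitted
#'   transitions, one `(from, to)` pair per row.
#' @param absorbing integer vector, subset of `states`.
#' @return An object of class `msm_space`.
#' @examples
#' # illness-death model with recovery: 0 = normal, 1 = abnormal, 2 = dead
#' msm_space(0:2, rbind(c(0, 1), c(0, 2), c(1, 0), c(1, 2)), absorbing = 2)
#' @export
msm_space <- function(states, transitions, absorbing = integer()) {
  states <- as.integer(states)
  if (length(states) == 0L) stop("at least one state is required")
  if (anyNA(states) || any(states < 0L)) {
    stop("state labels must be small non-negative integers")
  }
  if (anyDuplicated(states)) stop("state labels must be unique")
  absorbing <- as.integer(absorbing)
  if (!all(absorbing %in% states)) stop("absorbing states must be states")
  if (is.null(transitions)) {
    transitions <- matrix(integer(), ncol = 2L)
  }
  transitions <- as.matrix(transitions)
  if (ncol(transitions) != 2L) stop("'transitions' must have two columns")
  storage.mode(transitions) <- "integer"
  colnames(transitions) <- c("from", "to")
  if (nrow(transitions) > 0L) {
    if (any(transitions[, 1L] == transitions[, 2L])) {
      stop("self-transitions l -> l are not permitted")
    }
    if (!all(transitions %in% states)) {
      stop("transitions must connect declared states")
    }
    if (anyDuplicated(transitions)) stop("duplicated transition pairs")
    if (any(transitions[, 1L] %in% absorbing)) {
      stop("no transition may leave an absorbing state")
    }
  }
  transient <- setdiff(states, absorbing)
  if (length(transient) > 0L && !all(transient %in% transitions[, 1L])) {
    stop("every non-absorbing state needs at least one outgoing transition")
  }
  structure(
    list(states = states, absorbing = absorbing, transitions = transitions),
    class = "msm_space"
  )
}

#' @export
print.msm_space <- function(x, ...) {
  cat("Multistate state space:", length(x$states), "states\n")
  cat("  states   :", paste(x$states, collapse = ", "), "\n")
  cat("  absorbing:", if (length(x$absorbing)) paste(x$absorbing, collapse = ", ") else "(none)", "\n")
  cat("  transitions:",
      paste(sprintf("%d->%d", x$transitions[, 1L], x$transitions[, 2L]),
            collapse = ", "), "\n")
  invisible(x)
}

n_states <- function(space) length(space$states)

state_index <- function(space, s) {
  i <- match(as.integer(s), space$states)
  if (anyNA(i)) stop("unknown state label(s): ", paste(s[is.na(i)], collapse = ", "))
  i
}

is_absorbing <- function(space, s) as.integer(s) %in% space$absorbing

has_transition <- function(space, from, to) {
  any(space$transitions[, 1L] == from & space$transitions[, 2L] == to)
}

#' Constant transition hazard
#'
#' Builds the hazard specification for one permitted transition with a
#' time-constant intensity, so that the cumulative hazard is `rate * t`.
#'
#' @param from,to state labels of the transition.
#' @param rate non-negative constant intensity (events per time unit).
#' @return An object of class `msm_hazard` with elements `rate_fn(t, history)`
#'   and `cumulative_fn(t)`.
#' @examples
#' h <- constant_hazard(0, 1, 0.0005)
#' h$cumulative_fn(1000)  # 0.5
#' @export
constant_hazard <- function(from, to, rate) {
  if (length(rate) != 1L || is.na(rate) || rate < 0) {
    stop("'rate' must be a single non-negative number")
  }
  force(rate)
  structure(
    list(
      from = as.integer(from), to = as.integer(to),
      kind = "constant", rate = rate,
      rate_fn = function(t, history = NULL) rep_len(rate, length(t)),
      cumulative_fn = function(t) rate * t
    ),
    class = "msm_hazard"
  )
}

#' General transition hazard
#'
#' Hazard specification given by an arbitrary non-negative intensity function.
#' The `history` argument received by `rate_fn` carries the trajectory so far
#' (`state`, `time`, `arrival`, `visits`, `path`), which allows non-Markov
#' intensities depending on, e.g., the duration in the current state.
#'
#' @param from,to state labels of the transition.
#' @param rate_fn function `(t, history)` returning the intensity at `t`.
#' @param cumulative_fn optional function `t -> A(t)`; must be nondecreasing
#'   with `A(0) = 0`.  When omitted, cumulatives are obtained by adaptive
#'   quadrature of `rate_fn` (history-independent intensities only).
#' @return An object of class `msm_hazard`.
#' @export
hazard_fn <- function(from, to, rate_fn, cumulative_fn = NULL) {
  stopifnot(is.function(rate_fn))
  if (is.null(cumulative_fn)) {
    rf <- rate_fn
    cumulative_fn <- function(t) {
      vapply(t, function(ti) {
        if (ti <= 0) return(0)
        stats::integrate(function(u) rf(u, NULL), 0, ti,
                         rel.tol = 1e-10, abs.tol = 1e-12)$value
      }, numeric(1))
    }
  }
  if (cumulative_fn(0) != 0) stop("cumulative_fn(0) must be 0")
  structure(
    list(from = as.integer(from), to = as.integer(to), kind = "function",
         rate = NULL, rate_fn = rate_fn, cumulative_fn = cumulative_fn),
    class = "msm_hazard"
  )
}

#' Initial state distribution
#'
#' @param probs named numeric vector mapping state labels to probabilities at
#'   the time origin; must sum to one.
#' @param allow_absorbing permit mass on absorbing states (off by default:
#'   a trajectory started in an absorbing state is constant).
#' @return An object of class `msm_init`.
#' @examples
#' init_dist(c(`0` = 0.43, `1` = 0.57))
#' @export
init_dist <- function(probs, allow_absorbing = FALSE) {
  if (is.null(names(probs))) {
    names(probs) <- as.character(seq_along(probs) - 1L)
  }
  if (anyDuplicated(names(probs))) stop("duplicated state labels in 'probs'")
  if (any(probs < 0)) stop("initial probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("initial probabilities must sum to 1 (tolerance 1e-12)")
  }
  structure(list(probs = probs, states = as.integer(names(probs)),
                 allow_absorbing = isTRUE(allow_absorbing)),
            class = "msm_init")
}

as_init <- function(init) {
  if (inherits(init, "msm_init")) return(init)
  if (is.numeric(init)) return(init_dist(init))
  stop("'init' must be an msm_init or a named probability vector")
}

#' Censoring mechanisms
#'
#' Constructors for the right-censoring laws understood by the simulators:
#' no censoring, Uniform(a, b) random censoring, administrative censoring at a
#' fixed time `tau`, and a discrete empirical distribution as produced by the
#' reverse Kaplan-Meier estimator ([censoring_km()]).  For the empirical kind,
#' `residual` is the probability of never being censored (mass beyond the last
#' observed censoring time).
#'
#' @param a,b Uniform support bounds, `0 <= a < b`.
#' @param tau administrative censoring time, `tau > 0`.
#' @param times,probs support and atom probabilities of the empirical law.
#' @param residual probability mass beyond the largest censoring time.
#' @return An object of class `msm_censoring`.
#' @name censoring
NULL

#' @rdname censoring
#' @export
cens_none <- function() {
  structure(list(kind = "none"), class = "msm_censoring")
}

#' @rdname censoring
#' @export
cens_uniform <- function(a, b) {
  if (!(a >= 0 && a < b)) stop("uniform censoring requires 0 <= a < b")
  structure(list(kind = "uniform", a = a, b = b), class = "msm_censoring")
}

#' @rdname censoring
#' @export
cens_admin <- function(tau) {
  if (!(tau > 0)) stop("administrative censoring requires tau > 0")
  structure(list(kind = "administrative", tau = tau), class = "msm_censoring")
}

#' @rdname censoring
#' @export
cens_km <- function(times, probs, residual = 0) {
  o <- order(times)
  times <- times[o]; probs <- probs[o]
  if (any(probs < 0) || residual < 0) stop("censoring atoms must be non-negative")
  if (abs(sum(probs) + residual - 1) > 1e-12) {
    stop("censoring atoms (incl. residual) must sum to 1 (tolerance 1e-12)")
  }
  structure(list(kind = "empirical-km", times = times, probs = probs,
                 residual = residual),
            class = "msm_censoring")
}

#' Draw censoring times
#'
#' @param cm an [msm_censoring][censoring] object.
#' @param n number of draws.
#' @return numeric vector of length `n`; `Inf` means "never censored".
#' @export
draw_censoring <- function(cm, n) {
  switch(cm$kind,
    none = rep(Inf, n),
    uniform = stats::runif(n, cm$a, cm$b),
    administrative = rep(cm$tau, n),
    `empirical-km` = {
      k <- length(cm$times)
      i <- findInterval(stats::runif(n), cumsum(c(cm$probs, cm$residual))) + 1L
      out <- c(cm$times, Inf)[pmin(i, k + 1L)]
      out
    },
    stop("unknown censoring kind: ", cm$kind)
  )
}

#' Validate and assemble a multistate model
#'
#' Checks that every permitted transition of the state space carries exactly
#' one hazard specification (and none is attached to a forbidden pair), that
#' the initial distribution is supported on the state space (by default on its
#' transient part), and returns an immutable model handle used by the
#' simulators and the analytic truth computations.  Passing an already
#' validated model returns an equivalent handle (the operation is idempotent).
#'
#' @param space an [msm_space], or an `msm_model` to revalidate.
#' @param hazards list of [msm_hazard][constant_hazard] objects, or a single
#'   increment table ([increment_table()]) for an empirical model.
#' @param init an [init_dist] (or named probability vector).
#' @param censoring an [msm_censoring][censoring] law attached to the model as
#'   its default; simulators can override it.
#' @param horizon default simulation horizon (may be `Inf` when every
#'   transient state can reach absorption).
#' @return An object of class `msm_model` with `kind` `"parametric"` or
#'   `"empirical"`.
#' @export
msm_model <- function(space, hazards = NULL, init = NULL,
                      censoring = cens_none(), horizon = Inf) {
  if (inherits(space, "msm_model")) {
    m <- space
    return(msm_model(m$space, m$hazards %||% m$increments, m$init,
                     m$censoring, m$horizon))
  }
  stopifnot(inherits(space, "msm_space"))
  init <- as_init(init)
  bad <- setdiff(init$states, space$states)
  if (length(bad)) stop("initial distribution puts mass on unknown states")
  on_abs <- intersect(init$states[init$probs > 0], space$absorbing)
  if (length(on_abs) && !init$allow_absorbing) {
    stop("initial mass on absorbing state(s) ", paste(on_abs, collapse = ","),
         "; use init_dist(..., allow_absorbing = TRUE) to override")
  }
  if (inherits(hazards, "msm_increments")) {
    tab <- hazards
    pairs <- unique(tab[, c("from", "to")])
    for (i in seq_len(nrow(pairs))) {
      if (!has_transition(space, pairs$from[i], pairs$to[i])) {
        stop("forbidden transition in increment table: ",
             pairs$from[i], "->", pairs$to[i])
      }
    }
    out <- list(kind = "empirical", space = space, increments = tab,
                init = init, censoring = censoring, horizon = horizon)
  } else {
    if (inherits(hazards, "msm_hazard")) hazards <- list(hazards)
    pairs <- vapply(hazards, function(h) c(h$from, h$to), integer(2))
    if (anyDuplicated(t(pairs))) stop("duplicate hazard specification")
    for (h in hazards) {
      if (!has_transition(space, h$from, h$to)) {
        stop("forbidden transition: hazard attached to ",
             h$from, "->", h$to, " which is not a permitted transition")
      }
    }
    for (i in seq_len(nrow(space$transitions))) {
      fr <- space$transitions[i, 1L]; to <- space$transitions[i, 2L]
      if (!any(pairs[1L, ] == fr & pairs[2L, ] == to)) {
        stop("missing hazard for permitted transition ", fr, "->", to)
      }
    }
    names(hazards) <- sprintf("%d->%d", pairs[1L, ], pairs[2L, ])
    out <- list(kind = "parametric", space = space, hazards = hazards,
                init = init, censoring = censoring, horizon = horizon)
  }
  class(out) <- "msm_model"
  out
}

#' @rdname msm_model
#' @export
validate_model <- msm_model

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("Multistate model (%s), %d states\n", x$kind, n_states(x$space)))
  print(x$space)
  cat("  init:", paste(sprintf("P(X0=%s)=%g", names(x$init$probs), x$init$probs),
                       collapse = ", "), "\n")
  cat("  censoring:", x$censoring$kind, "\n")
  invisible(x)
}

#' Transition intensity matrix of a parametric model
#'
#' Evaluates `Q(t)` with off-diagonal entries `alpha_lm(t)` and the diagonal
#' convention that every row sums to zero.
#'
#' @param model a parametric [msm_model].
#' @param t single evaluation time.
#' @param history optional history passed to non-Markov intensities.
#' @return `K x K` matrix with dimnames given by the state labels.
#' @export
intensity_matrix <- function(model, t = 0, history = NULL) {
  stopifnot(inherits(model, "msm_model"), model$kind == "parametric")
  K <- n_states(model$space)
  Q <- matrix(0, K, K, dimnames = list(model$space$states, model$space$states))
  for (h in model$hazards) {
    Q[state_index(model$space, h$from), state_index(model$space, h$to)] <-
      h$rate_fn(t, history)
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a model from a JSON-style configuration list
#'
#' The configuration format mirrors what [read_model_config()] parses:
#' `states`, `absorbing`, a list of `hazards` (each `from`, `to`, `kind`
#' (`"constant"`), `rate`), an `init` mapping, and a `censoring` spec
#' (`kind` one of `"none"`, `"uniform"` with `a`, `b`, `"administrative"`
#' with `tau`).
#'
#' @param config a configuration list (e.g. from [preset()] or
#'   [read_model_config()]).
#' @return An [msm_model].
#' @export
as_msm_model <- function(config) {
  if (inherits(config, "msm_model")) return(config)
  stopifnot(is.list(config), !is.null(config$hazards))
  haz <- lapply(config$hazards, function(h) {
    kind <- h$kind %||% "constant"
    if (kind != "constant") {
      stop("config hazards support kind 'constant' only; got ", kind)
    }
    constant_hazard(h$from, h$to, h$rate)
  })
  trans <- t(vapply(haz, function(h) c(h$from, h$to), integer(2)))
  space <- msm_space(config$states, trans, config$absorbing %||% integer())
  init <- init_dist(unlist(config$init))
  cens <- config$censoring
  cm <- if (is.null(cens) || identical(cens$kind, "none")) {
    cens_none()
  } else if (cens$kind == "uniform") {
    cens_uniform(cens$a, cens$b)
  } else if (cens$kind == "administrative") {
    cens_admin(cens$tau)
  } else stop("unsupported censoring kind in config: ", cens$kind)
  msm_model(space, haz, init, cm, config$horizon %||% Inf)
}
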