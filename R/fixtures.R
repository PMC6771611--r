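#' Named scenario presets
#'
#' Deterministic registry of model configurations used throughout the tests
#' and examples.  `"csl-constant"` is the liver-cirrhosis-trial-like
#' illness-death model *with* recovery (states 0 normal, 1 abnormal
#' prothrombin, 2 dead) with constant transition-specific incidence rates
#' 0.0005 (0->1), 0.0002 (0->2), 0.002 (1->0), 0.0012 (1->2), initial
#' proportions 0.43 / 0.57 and Uniform(0, 4400) censoring; the time unit is
#' days since randomization.  `"csl-exposure"` is the matching illness-death
#' model *without* recovery written as an exposure model: exposure hazard
#' 0.0005, baseline death hazard 0.0002 and log hazard ratio `log(6)` (so
#' the death hazard under exposure is 0.0012), everyone unexposed at origin,
#' no censoring.
#'
#' @param name preset name, see [preset_names()].
#' @return A configuration list that round-trips through JSON identically
#'   ([write_model_config()] / [read_model_config()]) and feeds
#'   [as_msm_model()].
#' @examples
#' model <- as_msm_model(preset("csl-constant"))
#' @export
preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' @rdname preset
#' @export
preset_names <- function() names(preset_registry())

preset_registry <- function() {
  list(
    `csl-constant` = list(
      name = "csl-constant",
      time_unit = "days",
      states = c(0L, 1L, 2L),
      absorbing = 2L,
      hazards = list(
        list(from = 0L, to = 1L, kind = "constant", rate = 0.0005),
        list(from = 0L, to = 2L, kind = "constant", rate = 0.0002),
        list(from = 1L, to = 0L, kind = "constant", rate = 0.002),
        list(from = 1L, to = 2L, kind = "constant", rate = 0.0012)
      ),
      init = list(`0` = 0.43, `1` = 0.57),
      censoring = list(kind = "uniform", a = 0, b = 4400)
    ),
    `csl-exposure` = list(
      name = "csl-exposure",
      time_unit = "days",
      states = c(0L, 1L, 2L),
      absorbing = 2L,
      hazards = list(
        list(from = 0L, to = 1L, kind = "constant", rate = 0.0005),
        list(from = 0L, to = 2L, kind = "constant", rate = 0.0002),
        list(from = 1L, to = 2L, kind = "constant", rate = 0.0012)
      ),
      init = list(`0` = 1),
      censoring = list(kind = "none")
    )
  )
}

#' Hand-checkable toy event datasets
#'
#' Small fixed datasets whose Nelson-Aalen increments and risk sets can be
#' tallied by hand; used as unit-test fixtures and CLI demo inputs.
#'
#' * `"survival-5"`: 5 subjects in a two-state survival model, events at
#'   times 1, 2, 3 and censorings at 2.5 and 4; the 0->1 increments are
#'   1/5, 1/4, 1/2.
#' * `"illness-death-10"`: 10 subjects in the illness-death model with
#'   recovery, mixing switches, deaths and censorings.
#' * `"ties"`: two different transitions at the same time (they share one
#'   joint product-integral factor).
#' * `"truncated"`: delayed study entries, so risk sets do not start at the
#'   full sample size.
#'
#' @param kind one of `"survival-5"`, `"illness-death-10"`, `"ties"`,
#'   `"truncated"`.
#' @return An `msm_events` data.frame with its state space attached.
#' @export
toy_event_dataset <- function(kind = c("survival-5", "illness-death-10",
                                       "ties", "truncated")) {
  kind <- match.arg(kind)
  surv_space <- msm_space(0:1, rbind(c(0L, 1L)), absorbing = 1L)
  idm_space <- msm_space(0:2, rbind(c(0, 1), c(0, 2), c(1, 0), c(1, 2)),
                         absorbing = 2L)
  df <- switch(kind,
    `survival-5` = data.frame(
      id = 1:5, from = 0L,
      to = c(1L, 1L, 1L, NA, NA),
      entry = 0,
      exit = c(1, 2, 3, 2.5, 4),
      status = c(1L, 1L, 1L, 0L, 0L)
    ),
    `illness-death-10` = data.frame(
      id = c(1L, 1L, 2L, 2L, 2L, 3L, 4L, 4L, 5L, 6L, 6L, 7L, 8L, 9L, 10L),
      from = c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L),
      to = c(1L, 2L, 1L, 0L, 2L, 2L, 0L, NA, 2L, 0L, NA, NA, 2L, 1L, NA),
      entry = c(0, 2, 0, 1, 4, 0, 0, 3, 0, 0, 2.5, 0, 0, 0, 0),
      exit = c(2, 5, 1, 4, 7, 6, 3, 8, 4.5, 2.5, 6.5, 5.5, 7.5, 8.5, 9),
      status = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L)
    ),
    ties = data.frame(
      id = c(1L, 1L, 2L, 3L, 4L),
      from = c(0L, 1L, 0L, 0L, 0L),
      to = c(1L, 2L, 2L, NA, 2L),
      entry = c(0, 1, 0, 0, 0),
      exit = c(1, 2, 1, 2, 3),
      status = c(1L, 1L, 1L, 0L, 1L)
    ),
    truncated = data.frame(
      id = 1:5, from = 0L,
      to = c(1L, 1L, NA, 1L, NA),
      entry = c(0, 0.5, 1, 2, 2.5),
      exit = c(2, 3, 4, 5, 6),
      status = c(1L, 1L, 0L, 1L, 0L)
    )
  )
  space <- switch(kind,
    `survival-5` = surv_space,
    `illness-death-10` = idm_space,
    ties = idm_space,
    truncated = surv_space
  )
  st0 <- df$from[!duplicated(df$id)]
  structure(df,
            subjects = data.frame(id = unique(df$id), state0 = st0),
            space = space,
            class = c("msm_events", "data.frame"))
}
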