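test_that("Nelson-Aalen matches hand tallies on the toy fixtures", {
  d <- toy_event_dataset("survival-5")
  tab <- nelson_aalen(d, attr(d, "space"))
  expect_equal(tab$time, c(1, 2, 3))
  expect_equal(tab$increment, c(1 / 5, 1 / 4, 1 / 2))
  expect_equal(tab$risk_set, c(5, 4, 2))

  # delayed entry: risk sets by hand (entries 0, 0.5, 1, 2, 2.5)
  # at u=2 the id-4 subject enters exactly at 2 and is NOT yet at risk;
  # at u=3 subjects 2,3,4,5 are at risk; at u=5 only 4 and 5 remain
  dt <- toy_event_dataset("truncated")
  tt <- nelson_aalen(dt, attr(dt, "space"))
  expect_equal(tt$time, c(2, 3, 5))
  expect_equal(tt$risk_set, c(3, 4, 2))
  expect_equal(tt$increment, c(1 / 3, 1 / 4, 1 / 2))
})

test_that("tied transitions enter one joint product factor", {
  d <- toy_event_dataset("ties")
  sp <- attr(d, "space")
  tab <- nelson_aalen(d, sp)
  # at u = 1 both a 0->1 and a 0->2 occur among 4 subjects in state 0
  r1 <- tab[tab$time == 1, ]
  expect_equal(nrow(r1), 2L)
  expect_equal(r1$increment, c(1 / 4, 1 / 4))
  aj <- aalen_johansen(tab, 0, 1)
  expect_equal(unname(aj$P[1, , 1]), c(0.5, 0.25, 0.25))
})

test_that("Nelson-Aalen equals a brute-force counting-process tally", {
  set.seed(77)
  d <- simulate_parametric(csl_model(), 40)
  sp <- attr(d, "space")
  tab <- nelson_aalen(d, sp)
  oracle <- brute_nelson_aalen(d, sp)
  expect_equal(tab$time, oracle$time)
  expect_equal(tab$increment, oracle$increment)
  expect_equal(tab$risk_set, oracle$risk_set)
  # transitions with no events are absent from the grid
  expect_true(all(tab$increment > 0))
})

test_that("Nelson-Aalen refuses empty or corrupt data", {
  d <- toy_event_dataset("survival-5")
  expect_error(nelson_aalen(d[d$status == 0L, ], attr(d, "space")),
               "no event")
  # a zero-length record puts its own mover outside the left-limit risk set
  bad <- data.frame(id = 1L, from = 0L, to = 1L, entry = 5, exit = 5,
                    status = 1L)
  expect_error(nelson_aalen(bad, attr(d, "space")), "zero risk set")
})

test_that("Aalen-Johansen product is row-stochastic and matches one-factor algebra", {
  sp <- msm_space(0:2, rbind(c(0, 1), c(0, 2)), absorbing = c(1, 2))
  tab <- increment_table(data.frame(
    time = 10, from = c(0, 0), to = c(1, 2), increment = c(0.5, 0.25)), sp)
  aj <- aalen_johansen(tab, 0, 20)
  expect_equal(unname(aj$P[1, , 1]), c(0.25, 0.5, 0.25))
  # empty product: no grid times in (s, t]
  aj0 <- aalen_johansen(tab, 15, 20)
  expect_equal(unname(aj0$P[, , 1]), diag(3))
  # absorbing rows are unit rows
  expect_equal(unname(aj$P[2, , 1]), c(0, 1, 0))
  expect_equal(unname(aj$P[3, , 1]), c(0, 0, 1))
})

test_that("increment tables reject an all-cause increment above one", {
  sp <- msm_space(0:2, rbind(c(0, 1), c(0, 2)), absorbing = c(1, 2))
  expect_error(increment_table(data.frame(
    time = 10, from = c(0, 0), to = c(1, 2), increment = c(0.7, 0.4)), sp),
    "exceeds 1")
})

test_that("Aalen-Johansen equals the brute-force product and Chapman-Kolmogorov holds", {
  set.seed(101)
  d <- simulate_parametric(csl_model(), 120)
  sp <- attr(d, "space")
  tab <- nelson_aalen(d, sp)
  grid <- sort(unique(tab$time))
  s <- grid[5]; u <- grid[floor(length(grid) / 2)]; t <- grid[length(grid) - 3]
  P_st <- aalen_johansen(tab, s, t)$P[, , 1]
  expect_equal(unname(P_st), brute_product(tab, s, t, 3, sp))
  P_su <- aalen_johansen(tab, s, u)$P[, , 1]
  P_ut <- aalen_johansen(tab, u, t)$P[, , 1]
  expect_equal(P_su %*% P_ut, P_st)
  expect_equal(unname(rowSums(P_st)), c(1, 1, 1), tolerance = 1e-10)
  expect_true(all(P_st >= 0 & P_st <= 1 + 1e-12))
})

test_that("state occupation mixes rows with the initial law and sums to one", {
  sp <- msm_space(0:2, rbind(c(0, 1), c(0, 2), c(1, 0), c(1, 2)), absorbing = 2)
  tab <- increment_table(data.frame(
    time = 5, from = 0, to = 1, increment = 0.2), sp)
  init <- init_dist(c(`0` = 0.43, `1` = 0.57))
  # t = 0: empty product, occupation equals pi
  aj0 <- aalen_johansen(tab, 0, c(1, 10))
  occ <- state_occupation(aj0, init)
  expect_equal(unname(occ[1, ]), c(0.43, 0.57, 0))
  expect_equal(unname(occ[2, ]), c(0.43 * 0.8, 0.57 + 0.43 * 0.2, 0))
  expect_equal(unname(rowSums(occ)), c(1, 1))
  # two-state direct product
  sp2 <- msm_space(0:1, rbind(c(0, 1)), absorbing = 1)
  tab2 <- increment_table(data.frame(time = 3, from = 0, to = 1,
                                     increment = 0.2), sp2)
  occ2 <- state_occupation(aalen_johansen(tab2, 0, 4), init_dist(c(`0` = 1)))
  expect_equal(unname(occ2[1, ]), c(0.8, 0.2))
  # anchor must be 0
  expect_error(state_occupation(aalen_johansen(tab, 1, 10), init), "s = 0")
})

test_that("Aalen-type variance reproduces the one-event Greenwood value", {
  sp <- msm_space(0:1, rbind(c(0, 1)), absorbing = 1)
  n <- 10
  tab <- increment_table(data.frame(time = 1, from = 0, to = 1,
                                    increment = 1 / n, risk_set = n), sp)
  av <- aalen_variance(tab)
  # hand recursion: one factor, var(P00) = d(1-d)/Y with d = 1/n
  greenwood <- (1 - 1 / n)^2 * 1 / (n * (n - 1))
  expect_equal(av$var[1, 1, 1], (1 / n) * (1 - 1 / n) / n)
  expect_equal(av$var[1, 1, 1], greenwood)
  expect_equal(av$var[1, 2, 1], av$var[1, 1, 1])  # P01 = 1 - P00
  # no events before the first grid time -> variance zero there
  expect_error(aalen_variance(increment_table(data.frame(
    time = 1, from = 0, to = 1, increment = 0.1), sp)), "risk set")
})

test_that("log-log CI matches the closed-form delta-method computation", {
  p <- 0.5; v <- 0.01
  ci <- loglog_ci(p, v, 0.95)
  z <- qnorm(0.975)
  theta <- z * sqrt(v) / (p * log(p))
  hand <- sort(c(p^exp(-theta), p^exp(theta)))
  expect_equal(c(ci$lower, ci$upper), hand)
  # degenerate inputs return the point
  expect_equal(unlist(loglog_ci(0.5, 0)), c(lower = 0.5, upper = 0.5))
  expect_equal(unlist(loglog_ci(0, 0.01)), c(lower = 0, upper = 0))
  expect_equal(unlist(loglog_ci(1, 0.01)), c(lower = 1, upper = 1))
  expect_error(loglog_ci(0.5, 0.01, level = 1.2), "level")
  # ordering property over random draws
  set.seed(3)
  p <- runif(1000); v <- runif(1000, 0, 0.2)
  ci <- loglog_ci(p, v)
  expect_true(all(ci$lower <= p & p <= ci$upper))
  expect_true(all(ci$lower >= 0 & ci$upper <= 1))
})

test_that("reverse Kaplan-Meier censoring distribution matches hand table and survfit", {
  # all censored at the same time -> point mass
  d <- data.frame(id = 1:3, from = 0L, to = NA_integer_, entry = 0,
                  exit = 4, status = 0L)
  cm <- censoring_km(d)
  expect_equal(cm$times, 4)
  expect_equal(cm$probs, 1)
  # no censored records -> no censoring model
  d2 <- toy_event_dataset("survival-5")
  expect_equal(censoring_km(d2[d2$status == 1L, ])$kind, "none")

  # mixed 6-record set, hand reverse-KM:
  # follow-up times 1(ev) 2(cens) 3(ev) 3(cens) 5(cens) 6(ev)
  d3 <- data.frame(id = 1:6, from = 0L,
                   to = c(1L, NA, 1L, NA, NA, 1L),
                   entry = 0,
                   exit = c(1, 2, 3, 3, 5, 6),
                   status = c(1L, 0L, 1L, 0L, 0L, 1L))
  cm3 <- censoring_km(d3)
  # at 2: Y=5, atom 1/5; at 3: Y=4 (both time-3 subjects at risk),
  # surv 4/5 -> atom 4/5 * 1/4 = 1/5; at 5: Y=2, surv 3/5 -> atom 3/10;
  # residual 1 - 7/10 = 3/10
  expect_equal(cm3$times, c(2, 3, 5))
  expect_equal(cm3$probs, c(1 / 5, 1 / 5, 3 / 10))
  expect_equal(cm3$residual, 3 / 10)

  skip_if_not_installed("survival")
  fu <- c(1, 2, 3, 3, 5, 6); cens <- c(0, 1, 0, 1, 1, 0)
  fit <- survival::survfit(survival::Surv(fu, cens) ~ 1)
  surv_at <- stats::stepfun(fit$time, c(1, fit$surv))
  expect_equal(1 - sum(cm3$probs), surv_at(5))
})
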