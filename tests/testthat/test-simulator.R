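test_that("parametric simulator outputs valid event histories deterministically", {
  m <- csl_model()
  d1 <- simulate_parametric(m, 300, seed = 11)
  d2 <- simulate_parametric(m, 300, seed = 11)
  expect_identical(d1, d2)
  expect_true(validate_event_history(d1, attr(d1, "space")))
  # everyone terminates by the Uniform(0,4400) censoring bound
  expect_true(all(d1$exit <= 4400))
  # EFS <= OS, equality only for death straight out of the initial state
  efs <- efs_times(d1); os <- os_times(d1)
  expect_true(all(efs$time <= os$time))
  first <- d1[!duplicated(d1$id), ]
  straight <- first$status == 1L & first$to == 2L
  equal_obs <- efs$time[efs$status == 1 & os$status == 1] ==
    os$time[efs$status == 1 & os$status == 1]
  expect_equal(sum(equal_obs), sum(straight & first$to == 2L))
})

test_that("waiting time and event type follow the competing-risks laws", {
  # illness-death without recovery, constant hazards, no censoring
  spec <- exposure_spec(alpha01 = 0.0005, alpha0 = 0.0002, beta = log(6))
  m <- exposure_model(spec)
  n <- 40000
  d <- simulate_parametric(m, n, seed = 21)
  efs <- efs_times(d)
  expect_true(all(efs$status == 1))
  # EFS ~ Exp(a01 + a02): Kolmogorov-Smirnov at alpha = 0.01
  ks <- suppressWarnings(ks.test(efs$time, "pexp", 0.0007))
  expect_gt(ks$p.value, 0.01)
  # P(EFS <= t, X_EFS = 1): empirical frequency vs the closed form,
  # binomial 4-sigma tolerance
  first <- d[!duplicated(d$id), ]
  for (t in c(500, 1000, 3000)) {
    p_hat <- mean(first$exit <= t & first$to == 1L)
    p <- 0.0005 / 0.0007 * (1 - exp(-0.0007 * t))
    expect_lt(abs(p_hat - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("empirical waiting distribution follows the product form", {
  sp <- msm_space(0:1, rbind(c(0, 1)), absorbing = 1)
  # single grid time with all-cause increment 1: point mass, no residual
  tab1 <- increment_table(data.frame(time = 2, from = 0, to = 1,
                                     increment = 1), sp)
  w1 <- empirical_waiting(tab1, 0, 0)
  expect_equal(w1$times, 2)
  expect_equal(w1$probs, 1)
  expect_equal(w1$residual, 0)
  # two times at 0.5 each: atoms (0.5, 0.25), residual 0.25
  tab2 <- increment_table(data.frame(time = c(1, 2), from = 0, to = 1,
                                     increment = c(0.5, 0.5)), sp)
  w2 <- empirical_waiting(tab2, 0, 0)
  expect_equal(w2$probs, c(0.5, 0.25))
  expect_equal(w2$residual, 0.25)
  # conditioning: t_star past the first atom rescales the remaining mass
  w3 <- empirical_waiting(tab2, 0, 1)
  expect_equal(w3$times, 2)
  expect_equal(w3$probs, 0.5)
  expect_equal(w3$residual, 0.5)
})

test_that("empirical waiting atoms match a brute-force sequential product", {
  set.seed(31)
  d <- simulate_parametric(csl_model(), 251)
  tab <- nelson_aalen(d, attr(d, "space"))
  for (l in 0:1) {
    w <- empirical_waiting(tab, l, 0)
    rows <- tab[tab$from == l, ]
    u <- sort(unique(rows$time))
    allc <- vapply(u, function(ui) sum(rows$increment[rows$time == ui]),
                   numeric(1))
    surv <- 1
    atoms <- numeric(length(u))
    for (k in seq_along(u)) {       # sequential oracle
      atoms[k] <- surv * allc[k]
      surv <- surv * (1 - allc[k])
    }
    expect_equal(w$times, u)
    expect_equal(w$probs, atoms)
    expect_equal(w$residual, surv)
    expect_equal(sum(w$probs) + w$residual, 1, tolerance = 1e-12)
  }
})

test_that("a forced single transition is reproduced exactly", {
  sp <- msm_space(0:2, rbind(c(0, 1), c(0, 2)), absorbing = c(1, 2))
  tab <- increment_table(data.frame(time = 7, from = 0, to = 2,
                                    increment = 1), sp)
  d <- simulate_empirical(tab, init_dist(c(`0` = 1)), 50, seed = 5)
  expect_equal(nrow(d), 50L)
  expect_true(all(d$from == 0 & d$to == 2 & d$exit == 7 & d$status == 1))
})

test_that("empirical simulation censors residual draws at the last grid time", {
  sp <- msm_space(0:1, rbind(c(0, 1)), absorbing = 1)
  tab <- increment_table(data.frame(time = c(1, 2), from = 0, to = 1,
                                    increment = c(0.5, 0.5)), sp)
  n <- 4000
  d <- simulate_empirical(tab, init_dist(c(`0` = 1)), n, seed = 6)
  cens <- d[d$status == 0L, ]
  expect_true(all(cens$exit == 2))
  # atom frequencies (0.5, 0.25) and residual 0.25, binomial 4-sigma
  for (case in list(c(1, 0.5), c(2, 0.25))) {
    f <- mean(d$status == 1L & d$exit == case[1])
    expect_lt(abs(f - case[2]), 4 * sqrt(case[2] * (1 - case[2]) / n))
  }
  expect_lt(abs(nrow(cens) / n - 0.25), 4 * sqrt(0.25 * 0.75 / n))
})

test_that("empirical simulation is a fixed point of Nelson-Aalen re-estimation", {
  # moderate-scale version of the regeneration check (the acceptance test
  # runs the large one): administrative censoring keeps risk sets healthy
  set.seed(41)
  src <- simulate_parametric(csl_model(), 400, censoring = cens_admin(1500))
  sp <- attr(src, "space")
  tab <- nelson_aalen(src, sp)
  m <- 40000
  d <- simulate_empirical(tab, init_dist(c(`0` = 0.43, `1` = 0.57)), m,
                          seed = 42)
  tab2 <- nelson_aalen(d, sp)
  key <- function(x) paste(x$time, x$from, x$to)
  expect_true(all(key(tab2) %in% key(tab)))
  i <- match(key(tab2), key(tab))
  # per-atom binomial tolerance from the replicate risk sets
  tol <- 5 * sqrt(tab$increment[i] * (1 - tab$increment[i]) /
                    pmax(tab2$risk_set, 1)) + 1e-12
  expect_true(all(abs(tab2$increment - tab$increment[i]) < tol))
  # and the bulk of the source grid is visited
  expect_gt(length(i) / nrow(tab), 0.95)
})

test_that("superimposed censoring matches the reverse-KM law it came from", {
  set.seed(51)
  src <- simulate_parametric(csl_model(), 500)
  cm <- censoring_km(src)
  expect_equal(cm$kind, "empirical-km")
  n <- 20000
  x <- draw_censoring(cm, n)
  # compare atom frequencies at the five largest atoms
  top <- order(cm$probs, decreasing = TRUE)[1:5]
  for (k in top) {
    f <- mean(x == cm$times[k])
    expect_lt(abs(f - cm$probs[k]),
              4 * sqrt(cm$probs[k] * (1 - cm$probs[k]) / n) + 1e-12)
  }
  expect_lt(abs(mean(is.infinite(x)) - cm$residual),
            4 * sqrt(cm$residual * (1 - cm$residual) / n) + 1e-12)
})

test_that("left-truncation clips records and drops never-entering subjects", {
  d <- toy_event_dataset("survival-5")
  # entry at 0 changes nothing
  expect_equal(as.data.frame(superimpose_truncation(d, 0)), as.data.frame(d))
  # entry beyond everyone's follow-up empties the dataset with a warning
  expect_warning(out <- superimpose_truncation(d, 100), "removed every")
  expect_equal(nrow(out), 0L)
  # per-subject entries clip the covering record
  out2 <- superimpose_truncation(d, c(0.5, 10, 0, 0, 0))
  expect_false(2 %in% out2$id)             # id 2 never enters
  expect_equal(out2$entry[out2$id == 1], 0.5)
})

test_that("Nelson-Aalen stays consistent under independent left-truncation", {
  set.seed(61)
  m <- csl_model()
  d <- simulate_parametric(m, 30000, censoring = cens_admin(2500))
  dt <- superimpose_truncation(d, function(k) rexp(k, 1 / 500))
  tab <- nelson_aalen(dt, attr(d, "space"))
  r01 <- tab[tab$from == 0 & tab$to == 1, ]
  A01 <- cumsum(r01$increment)
  # analytic MC scale: sd(A(t)) ~ sqrt(int alpha du / (n ybar)); with
  # n = 30000 and occupancy above ~0.2 this is < 0.01 at t = 2000
  keep <- r01$time <= 2000
  expect_lt(max(abs(A01[keep] - 0.0005 * r01$time[keep])), 0.04 * 1)
  # risk sets rise after the origin (delayed entry) before falling again
  expect_gt(which.max(r01$risk_set), 5)
})

test_that("the OS law is invariant under relabelling the transient states", {
  # destination is drawn after the event time, so permuting state labels
  # (and the matching hazards/init) cannot change the marginal OS law
  cfg <- preset("csl-constant")
  m1 <- as_msm_model(cfg)
  relab <- cfg
  relab$hazards <- list(
    list(from = 0L, to = 1L, kind = "constant", rate = 0.002),
    list(from = 0L, to = 2L, kind = "constant", rate = 0.0012),
    list(from = 1L, to = 0L, kind = "constant", rate = 0.0005),
    list(from = 1L, to = 2L, kind = "constant", rate = 0.0002)
  )
  relab$init <- list(`0` = 0.57, `1` = 0.43)
  m2 <- as_msm_model(relab)
  os1 <- os_times(simulate_parametric(m1, 20000, censoring = cens_none(),
                                      seed = 71))
  os2 <- os_times(simulate_parametric(m2, 20000, censoring = cens_none(),
                                      seed = 72))
  ks <- suppressWarnings(ks.test(os1$time, os2$time))
  expect_gt(ks$p.value, 0.01)
})
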