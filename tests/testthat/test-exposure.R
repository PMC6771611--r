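test_that("population hazard is the prevalence-weighted mixture", {
  spec <- exposure_spec(alpha01 = 0.0005, alpha0 = 0.0002, beta = log(6))
  # beta = 0 collapses the mixture
  spec0 <- exposure_spec(0.0005, 0.0002, 0)
  expect_equal(population_hazard(spec0, c(10, 500, 5000)),
               rep(0.0002, 3))
  # single-component mixture when nobody is unexposed
  sp_fn <- function(t) cbind(rep(0, length(t)), rep(0.4, length(t)))
  expect_equal(population_hazard(spec, 100, sp_fn), 0.0002 * 6)
  # extinct population: hazard set to 0
  sp_dead <- function(t) cbind(0, 0)
  expect_equal(population_hazard(spec, 100, sp_dead), 0)
  # convexity: always between alpha0 and alpha0 exp(beta)
  a <- population_hazard(spec, seq(0, 8000, by = 250))
  expect_true(all(a >= 0.0002 - 1e-15 & a <= 0.0012 + 1e-15))
  expect_true(all(diff(a) > 0))  # prevalence of exposure grows over time
})

test_that("integrated population hazard reproduces the simulated OS survival", {
  spec <- exposure_spec(alpha01 = 0.0005, alpha0 = 0.0002, beta = log(6))
  n <- 100000
  os <- os_times(simulate_parametric(exposure_model(spec), n, seed = 81))
  for (t in c(100, 1000)) {
    Lambda <- stats::integrate(function(u) population_hazard(spec, u),
                               0, t, rel.tol = 1e-8)$value
    S_hat <- mean(os$time > t)
    # delta method on -log(S_hat): sd ~ sqrt((1-S)/(S n))
    tol <- 4 * sqrt((1 - exp(-Lambda)) / (exp(-Lambda) * n))
    expect_lt(abs(-log(S_hat) - Lambda), tol)
  }
})

test_that("exposure cumulative incidence has the stated closed form and limits", {
  spec <- exposure_spec(alpha01 = 0.0005, alpha0 = 0.0002, beta = log(6))
  expect_equal(cumulative_incidence_exposure(spec, 0), 0)
  a01 <- 0.0005; a02 <- 0.0002
  expect_equal(cumulative_incidence_exposure(spec, 1e9),
               a01 / (a01 + a02), tolerance = 1e-12)
  # closed form at t = 1000 equals a01/(a01+a02) * (1 - exp(-0.7)) and the
  # brute-force quadrature of the integrand
  v <- cumulative_incidence_exposure(spec, 1000)
  expect_equal(v, a01 / (a01 + a02) * (1 - exp(-0.7)))
  quad <- stats::integrate(function(u) exp(-(a01 + a02) * u) * a01, 0, 1000,
                           rel.tol = 1e-12)$value
  expect_equal(v, quad, tolerance = 1e-10)
  # monotone and bounded by the limiting fraction
  tt <- seq(0, 20000, by = 500)
  ci <- cumulative_incidence_exposure(spec, tt)
  expect_true(all(diff(ci) >= 0))
  expect_true(all(ci <= a01 / (a01 + a02) + 1e-12))
  # function-valued hazards agree with the constant closed form
  specf <- exposure_spec(function(t) rep(a01, length(t)),
                         function(t) rep(a02, length(t)), log(6))
  expect_equal(cumulative_incidence_exposure(specf, 1000), v,
               tolerance = 1e-8)
})

test_that("latent-time comparator reduces correctly in the degenerate corners", {
  # a01 = 0: nobody exposed, EFS = OS = OS1
  spec <- exposure_spec(0, 0.0002, log(6))
  d <- simulate_latent(spec, 500, seed = 91)
  expect_true(all(!d$exposed))
  expect_equal(d$efs, d$os)
  # exp(beta) = 0: exposure confers immortality, survival plateaus at the
  # never-exposed fraction a01/(a01+a02)
  spec2 <- exposure_spec(0.0005, 0.0002, -Inf)
  d2 <- simulate_latent(spec2, 20000, seed = 92)
  expect_true(all(is.infinite(d2$os[d2$exposed])))
  plateau <- mean(is.infinite(d2$os))
  expect_lt(abs(plateau - 0.0005 / 0.0007),
            4 * sqrt(5 / 7 * 2 / 7 / 20000))
  # EFS <= OS always, equality iff death without prior exposure
  spec3 <- exposure_spec(0.0005, 0.0002, log(6))
  d3 <- simulate_latent(spec3, 5000, seed = 93)
  expect_true(all(d3$efs <= d3$os))
  expect_equal(d3$efs == d3$os, !d3$exposed)
})

test_that("multistate and latent-time OS laws coincide (desk-scale check)", {
  spec <- exposure_spec(0.0005, 0.0002, log(6))
  n <- 30000
  os_ms <- os_times(simulate_parametric(exposure_model(spec), n, seed = 94))
  os_lat <- simulate_latent(spec, n, seed = 95)$os
  ks <- suppressWarnings(ks.test(os_ms$time, os_lat))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditional survival is continuous at t0, monotone, and matches quadrature", {
  spec <- exposure_spec(0.0005, 0.0002, log(6))
  t0 <- 700
  eps <- 1e-9
  expect_equal(conditional_survival(spec, t0 - eps, t0),
               conditional_survival(spec, t0 + eps, t0), tolerance = 1e-6)
  tt <- seq(0, 5000, by = 50)
  s <- conditional_survival(spec, tt, t0)
  expect_true(all(diff(s) <= 0))
  # closed form for t > t0
  expect_equal(conditional_survival(spec, 2000, t0),
               exp(-0.0002 * t0) * exp(-0.0012 * (2000 - t0)))
  # beta = 0: independent of t0
  spec0 <- exposure_spec(0.0005, 0.0002, 0)
  expect_equal(conditional_survival(spec0, 1500, 700),
               exp(-0.0002 * 1500))
  expect_equal(conditional_survival(spec0, 1500, 10),
               conditional_survival(spec0, 1500, 4000))
  # non-constant baseline hazard against quadrature
  a0f <- function(t) 2e-4 * (1 + t / 2000)
  specf <- exposure_spec(0.0005, a0f, log(2))
  A0 <- function(t) stats::integrate(a0f, 0, t, rel.tol = 1e-10)$value
  expect_equal(conditional_survival(specf, 300, 700), exp(-A0(300)),
               tolerance = 1e-8)
  expect_equal(conditional_survival(specf, 1500, 700),
               exp(-(A0(700) + 2 * (A0(1500) - A0(700)))), tolerance = 1e-8)
  expect_error(conditional_survival(spec, -1, 5), "negative")
})
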