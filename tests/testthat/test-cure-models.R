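test_that("population survival has the mixture closed forms and limits", {
  w <- cure_model("weibull", pi = 0.2, theta = c(1 / 10, 1.5))
  expect_identical(cure_survival(w, 0), 1)

  e <- cure_model("exponential", pi = 0.2, theta = 0.1)
  expect_equal(cure_survival(e, 10), 0.2 + 0.8 * exp(-1), tolerance = 1e-12)
  expect_equal(cure_survival(e, 1e6), 0.2, tolerance = 1e-9)

  # non-increasing on a grid, limit = pi, for every family
  specs <- list(
    cure_model("exponential", 0.3, 0.05),
    cure_model("weibull", 0.3, c(1 / 20, 1.7)),
    cure_model("loglogistic", 0.3, c(1 / 20, 2.2)),
    cure_model("lognormal", 0.3, c(3, 0.8)))
  grid <- c(0, 10^seq(-2, 2, length.out = 40))
  for (s in specs) {
    sv <- cure_survival(s, grid)
    expect_identical(sv[1L], 1)
    expect_true(all(diff(sv) <= 1e-14))
    expect_equal(cure_survival(s, 1e6 * 20), 0.3, tolerance = 1e-6)
  }
  expect_error(cure_survival(e, -1), "non-negative")
})

test_that("density carries the susceptible mass and matches -dS/dt", {
  expect_equal(cure_density(cure_model("weibull", 1, c(0.1, 2)), 5), 0)
  e0 <- cure_model("exponential", 0, 0.1)
  expect_equal(cure_density(e0, 10), 0.1 * exp(-1), tolerance = 1e-12)

  q <- cure_model("lognormal", 0.25, c(2, 0.7))
  mass <- stats::integrate(function(t) cure_density(q, t), 0, Inf)$value
  expect_equal(mass, 0.75, tolerance = 1e-6)

  specs <- list(
    cure_model("exponential", 0.2, 0.08),
    cure_model("weibull", 0.2, c(1 / 15, 1.6)),
    cure_model("loglogistic", 0.2, c(1 / 15, 2.5)),
    cure_model("lognormal", 0.2, c(2.5, 0.6)))
  grid <- seq(0.5, 60, length.out = 25)
  h <- 1e-4
  for (s in specs) {
    num <- -(cure_survival(s, grid + h) - cure_survival(s, grid - h)) / (2 * h)
    expect_equal(cure_density(s, grid), num, tolerance = 1e-6)
  }
})

test_that("hazard is density over survival and decays under a cure tail", {
  e0 <- cure_model("exponential", 0, 0.07)
  expect_equal(cure_hazard(e0, c(1, 5, 80)), rep(0.07, 3), tolerance = 1e-12)

  e <- cure_model("exponential", 0.2, 0.1)
  expect_equal(cure_hazard(e, 10), 0.8 * 0.1 * exp(-1) / (0.2 + 0.8 * exp(-1)),
               tolerance = 1e-12)

  w <- cure_model("weibull", 0.2, c(1 / 10, 2))
  hz <- cure_hazard(w, seq(20, 200, by = 5))
  expect_true(all(diff(hz) <= 0))
  expect_lt(hz[length(hz)], 1e-6)
})

test_that("latency quantile inverts the susceptible survival exactly", {
  expect_equal(latency_quantile("exponential", 0.1, 0.5), log(2) / 0.1,
               tolerance = 1e-12)
  expect_equal(latency_quantile("weibull", c(1 / 10, 2), exp(-1)), 10,
               tolerance = 1e-12)
  cases <- list(
    list("exponential", 0.03), list("weibull", c(1 / 30, 0.8)),
    list("loglogistic", c(1 / 30, 3)), list("lognormal", c(3.2, 1.1)))
  for (cs in cases) for (p in c(0.01, 0.5, 0.99)) {
    q <- latency_quantile(cs[[1L]], cs[[2L]], p)
    expect_equal(latency_survival(cs[[1L]], cs[[2L]], q), p,
                 tolerance = 1e-10)
  }
  expect_error(latency_quantile("exponential", 0.1, 0), "strictly in")
  expect_error(latency_quantile("exponential", 0.1, 1), "strictly in")
})

test_that("with pi = 0 each family reduces to its reference distribution", {
  grid <- seq(0.2, 80, length.out = 20)
  th <- list(exponential = 0.05, weibull = c(1 / 25, 1.8),
             loglogistic = c(1 / 25, 2.4), lognormal = c(2.8, 0.9))
  refs <- list(
    exponential = function(t) stats::pexp(t, 0.05, lower.tail = FALSE),
    weibull = function(t)
      stats::pweibull(t, shape = 1.8, scale = 25, lower.tail = FALSE),
    loglogistic = function(t)
      stats::plogis(2.4 * (log(t) - log(25)), lower.tail = FALSE),
    lognormal = function(t)
      stats::plnorm(t, 2.8, 0.9, lower.tail = FALSE))
  for (fam in cure_families()) {
    s <- cure_model(fam, 0, th[[fam]])
    expect_equal(cure_survival(s, grid), refs[[fam]](grid),
                 tolerance = 1e-10, info = fam)
  }
})

test_that("conditional sampler is exact: memorylessness and no-truncation", {
  set.seed(101)
  n <- 1e5
  x <- sample_conditional("exponential", 0.1, c = 5, n = n)
  expect_true(all(x > 5))
  se <- 10 / sqrt(n)
  expect_lt(abs(mean(x) - 15), 3 * se)

  # c = 0 equals the unconditional law
  set.seed(102)
  a <- sample_conditional("lognormal", c(2, 0.8), c = 0, n = 1e4)
  b <- latency_quantile("lognormal", c(2, 0.8), stats::runif(1e4))
  expect_gt(suppressWarnings(stats::ks.test(a, b))$p.value, 0.01)

  expect_error(sample_conditional("exponential", 0.1, c = -1, n = 5),
               "non-negative")
  # no mass beyond c: Weibull survival underflows to exactly 0
  expect_error(sample_conditional("weibull", c(1, 3), c = 1e4, n = 5),
               "no latency mass")
})

test_that("population sampler splits cured and susceptible correctly", {
  set.seed(103)
  all_cured <- sample_population(cure_model("weibull", 1, c(0.1, 2)), 100)
  expect_true(all(all_cured$cured))
  expect_true(all(is.na(all_cured$time)))

  pop <- sample_population(cure_model("exponential", 0.25, 0.1), 1e5)
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_lt(abs(mean(pop$cured) - 0.25), 3 * se)
  expect_true(all(pop$time[!pop$cured] > 0))

  pop0 <- sample_population(cure_model("exponential", 0, 0.1), 1e5)
  expect_lt(abs(mean(pop0$time) - 10), 3 * 10 / sqrt(1e5))
})

test_that("model specification rejects malformed parameters", {
  expect_error(cure_model("gamma", 0.2, c(1, 1)), "unknown latency family")
  expect_error(cure_model("weibull", 1.2, c(1, 1)), "probability")
  expect_error(cure_model("weibull", 0.2, 1), "needs 2")
  expect_error(cure_model("exponential", 0.2, -0.1), "strictly positive")
  expect_error(cure_model("lognormal", 0.2, c(1, -2)), "strictly positive")
  # lognormal location may be negative
  expect_s3_class(cure_model("lognormal", 0.2, c(-1, 2)), "cure_model")
})
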