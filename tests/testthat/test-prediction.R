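# A small blinded snapshot: 6 events, 4 administrative censors, fully
# enrolled (target 10).
small_snapshot <- function() {
  make_snapshot(
    entry = c(0, 2, 4, 6, 8, 10, 1, 3, 5, 7),
    x     = c(5, 4, 6, 3, 2, 4, 19, 17, 15, 13),
    event = c(rep(TRUE, 6), rep(FALSE, 4)),
    admin = c(rep(FALSE, 6), rep(TRUE, 4)),
    tau = 20, target_n = 10)
}

test_that("parameter resampling is centered, constrained and degenerate-safe", {
  snap <- recovery_snapshot(seed = 9, n = 1000)
  fit <- fit_cure(snap, "weibull")
  set.seed(106)
  draws <- t(replicate(1e4, {
    d <- resample_parameters(fit)
    c(stats::qlogis(d$pi), log(d$theta))
  }))
  se <- sqrt(diag(fit$covariance) / 1e4)
  expect_true(all(abs(colMeans(draws) - fit$raw_params) < 3.5 * se))

  nat <- t(apply(draws, 1, function(r) c(stats::plogis(r[1]), exp(r[2:3]))))
  expect_true(all(nat[, 1] > 0 & nat[, 1] < 1))
  expect_true(all(nat[, 2:3] > 0))

  # zero covariance: the draw is the point estimate, exactly
  degen <- as_cure_fit(fit$spec)
  d0 <- resample_parameters(degen)
  expect_identical(d0$pi, fit$spec$pi)
})

test_that("one completion obeys the accounting identities", {
  snap <- small_snapshot()
  ds <- design_spec(10, 8, design_hr = 1 / 1.38)

  # forced cure of the whole risk set: no event source left
  set.seed(107)
  res <- simulate_one_completion(snap, cure_model("exponential", 1, 0.1),
                                 accrual = NULL, design = ds)
  expect_false(res$complete)
  expect_identical(res$n_cured, 4L)

  # no risk set, no future enrollment, D(tau) < D*: incomplete
  ev_only <- make_snapshot(c(0, 1), c(3, 4), c(TRUE, TRUE), c(FALSE, FALSE),
                           tau = 20, target_n = 2)
  res2 <- simulate_one_completion(ev_only, cure_model("exponential", 0.2, 0.1),
                                  NULL, design_spec(2, 2))
  expect_true(res2$complete)  # 2 observed events already reach D* = 2
  res3 <- simulate_one_completion(
    make_snapshot(0, 3, TRUE, FALSE, tau = 20, target_n = 1),
    cure_model("exponential", 0.2, 0.1), NULL, design_spec(1, 1))
  expect_true(res3$complete)

  # conservation: cured + new events + future outcomes + D + LTFU = N
  spec <- cure_model("weibull", 0.3, c(0.05, 1.5))
  big <- make_snapshot(
    entry = c(seq(0, 45, length.out = 20)),
    x = c(rep(3, 8), 50 - seq(0, 45, length.out = 20)[9:18], 2, 1),
    event = c(rep(TRUE, 8), rep(FALSE, 12)),
    admin = c(rep(FALSE, 8), rep(TRUE, 10), FALSE, FALSE),
    tau = 50, target_n = 30)
  k <- snapshot_counts(big)
  set.seed(108)
  for (i in 1:20) {
    r <- simulate_one_completion(big, spec, accrual_model(0.5),
                                 design_spec(30, 25))
    n_future <- 30L - k$n
    expect_identical(r$n_future_events + r$n_future_never, n_future)
    expect_identical(r$n_cured + r$n_new_events, k$g)
    expect_identical(r$n_cured + r$n_new_events + r$n_future_events +
                       r$n_future_never + k$d + k$n_ltfu, 30L)
  }
})

test_that("simulated extension times respect the observation boundary", {
  snap <- small_snapshot()
  spec <- cure_model("exponential", 0, 0.1)
  ds <- design_spec(10, 10)
  set.seed(109)
  for (i in 1:50) {
    r <- simulate_one_completion(snap, spec, NULL, ds)
    # the 7th..10th ranked events are the at-risk extensions: all beyond tau
    expect_true(r$complete)
    expect_gt(r$time, snap$tau)
  }
})

test_that("increasing the target event count never shortens an iteration", {
  snap <- small_snapshot()
  fit <- as_cure_fit(cure_model("exponential", 0.2, 0.1),
                     covariance = diag(c(0.04, 0.01)))
  p8 <- predict_analysis_time(snap, fit, design_spec(10, 8), NULL,
                              n_iter = 300, seed = 21)
  p9 <- predict_analysis_time(snap, fit, design_spec(10, 9), NULL,
                              n_iter = 300, seed = 21)
  both <- !is.na(p8$times) & !is.na(p9$times)
  expect_true(all(p9$times[both] >= p8$times[both]))
  expect_true(all(is.na(p9$times)[is.na(p8$times)]))  # p_sic monotone too
  expect_gte(p9$p_sic, p8$p_sic)
})

test_that("prediction summaries follow their definitions", {
  snap <- small_snapshot()
  fit <- as_cure_fit(cure_model("exponential", 0.1, 0.1))
  p <- predict_analysis_time(snap, fit, design_spec(10, 9), NULL,
                             n_iter = 500, alpha = 0.10, seed = 3)
  expect_equal(p$p_sic, sum(is.na(p$times)) / 500)
  fin <- p$times[!is.na(p$times)]
  expect_equal(p$point_estimate, stats::median(fin))
  expect_true(p$ci_lower <= p$point_estimate & p$point_estimate <= p$ci_upper)
  expect_true(all(fin > snap$tau))

  # single iteration: both limits collapse onto the lone finite time
  p1 <- predict_analysis_time(snap, fit, design_spec(10, 7), NULL,
                              n_iter = 1, seed = 4)
  expect_equal(p1$ci_lower, p1$ci_upper)
  expect_equal(p1$ci_lower, p1$point_estimate)

  # reruns with the same seed are bitwise identical
  p_again <- predict_analysis_time(snap, fit, design_spec(10, 9), NULL,
                                   n_iter = 500, alpha = 0.10, seed = 3)
  expect_identical(p, p_again)
})

test_that("an already-reached target returns the observed event date", {
  snap <- small_snapshot()   # 6 events observed
  fit <- as_cure_fit(cure_model("exponential", 0.2, 0.1))
  p <- predict_analysis_time(snap, fit, design_spec(10, 5), NULL,
                             n_iter = 10, seed = 1)
  obs <- sort(snap$records$entry_time[snap$records$event] +
                snap$records$observed_time[snap$records$event])
  expect_equal(p$point_estimate, obs[5])
  expect_equal(p$ci_lower, p$ci_upper)
  expect_equal(p$p_sic, 0)
})

test_that("completion times match a direct order-statistic oracle", {
  # pi = 0, exponential latency: by memorylessness each at-risk patient
  # completes at E_i + X_i + Exp(rate); T* (D* = 8 with 6 observed) is the
  # 2nd smallest of the four extensions.
  snap <- small_snapshot()
  spec <- cure_model("exponential", 0, 0.12)
  ds <- design_spec(10, 8)
  n_run <- 4000
  set.seed(110)
  sim <- replicate(n_run,
    simulate_one_completion(snap, spec, NULL, ds)$time)
  adm <- snap$records$administrative_censor
  base <- snap$records$entry_time[adm] + snap$records$observed_time[adm]
  set.seed(111)
  orc <- replicate(n_run, sort(base + stats::rexp(4, 0.12))[2])
  expect_gt(suppressWarnings(stats::ks.test(sim, orc))$p.value, 0.01)
})
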