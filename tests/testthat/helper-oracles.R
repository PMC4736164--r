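# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Hand-rolled product-limit estimator (loop over distinct event times).
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    d <- sum(time == ut[k] & event)
    r <- sum(time >= ut[k])
    s <- s * (1 - d / r)
    surv[k] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Rejection sampler for the left-truncated latency law: draw unconditional
# times, keep those beyond c.
rejection_conditional <- function(family, theta, c, n) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- latency_quantile(family, theta, stats::runif(4L * n))
    out <- c(out, cand[cand > c])
  }
  out[seq_len(n)]
}

# A small snapshot built directly from vectors.
make_snapshot <- function(entry, x, event, admin, tau, target_n) {
  trial_snapshot(
    data.frame(id = sprintf("S%03d", seq_along(entry)),
               entry_time = entry, observed_time = x,
               event = event, administrative_censor = admin),
    tau = tau, target_n = target_n)
}

# A moderately mature Weibull-cure snapshot used by several files.
recovery_snapshot <- function(seed = 42, n = 2000) {
  cfg <- trial_config(n, accrual_rate = n / 30,
                      truth = cure_model("weibull", 0.25, c(1 / 12, 1.4)),
                      ltfu_rate = 0, seed = seed)
  snapshot_at(generate_trial(cfg), 60)
}

# Central-difference gradient on the unconstrained scale.
num_gradient <- function(fn, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    e <- replace(numeric(length(par)), i, h * (1 + abs(par[i])))
    (fn(par + e) - fn(par - e)) / (2 * e[i])
  }, numeric(1L))
}
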