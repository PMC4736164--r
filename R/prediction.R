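#' Design specification of an event-driven trial
#'
#' @param target_n planned total sample size `N`.
#' @param target_events prespecified total event count `D*` triggering the
#'   final analysis (`<= target_n`).
#' @param design_hr hazard ratio under the design alternative.
#' @param alpha two-sided significance level.
#' @param allocation fraction randomized to the experimental arm.
#' @export
design_spec <- function(target_n, target_events, design_hr = 1 / 1.38,
                        alpha = 0.05, allocation = 0.5) {
  stopifnot(target_events >= 1, target_events <= target_n, design_hr > 0,
            alpha > 0, alpha < 1, allocation > 0, allocation < 1)
  structure(list(target_n = as.integer(target_n),
                 target_events = as.integer(target_events),
                 design_hr = design_hr, alpha = alpha,
                 allocation = allocation),
            class = "design_spec")
}

# Square root factor L of a covariance matrix via eigendecomposition, so a
# draw is mean + L %*% z. Handles the zero matrix (degenerate normal)
# exactly. Slightly negative eigenvalues within tolerance are clipped; a
# genuinely indefinite matrix gets one nearest-PSD repair with a message.
mvn_sqrt <- function(covariance) {
  S <- (covariance + t(covariance)) / 2
  ev <- eigen(S, symmetric = TRUE)
  tol <- 1e-8 * max(1, abs(ev$values[1L]))
  if (any(ev$values < -tol)) {
    message("covariance not positive semi-definite; ",
            "applying nearest-PSD repair (negative eigenvalues clipped)")
  }
  vals <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(vals), length(vals))
}

#' Draw one parameter vector from the estimation uncertainty
#'
#' One multivariate-normal draw on the unconstrained scale, centered at the
#' fitted `raw_params` with the fitted covariance, mapped back to the
#' natural scale — so the drawn model always has `pi` in (0, 1) and
#' positive latency parameters. With a zero covariance the draw equals the
#' point estimate exactly.
#'
#' @param fit a converged `cure_fit`.
#' @return A [cure_model()].
#' @export
resample_parameters <- function(fit) {
  stopifnot(inherits(fit, "cure_fit"))
  if (!fit$converged || is.null(fit$covariance))
    stop("resampling needs a converged fit with a covariance matrix")
  L <- mvn_sqrt(fit$covariance)
  raw <- fit$raw_params + as.numeric(L %*% stats::rnorm(length(fit$raw_params)))
  from_unconstrained(fit$family, raw)
}

#' Simulate one completion of the trial
#'
#' One iteration of the Monte-Carlo prediction procedure, with the
#' parameter draw `spec` held fixed:
#' \enumerate{
#'   \item each of the `G(tau)` administratively censored (at-risk)
#'     patients is independently marked cured with probability
#'     `min(1, max(0, pi * N / G(tau)))`;
#'   \item each non-cured at-risk patient draws an event time from the
#'     latency law conditional on exceeding their observed follow-up
#'     ([sample_conditional()]), giving calendar time `E_i + T_i`;
#'   \item the `N - N(tau)` future patients get entry dates from
#'     [simulate_entries()] and outcomes from the full population law
#'     ([sample_population()]);
#'   \item all finite event calendar times — observed events included —
#'     are ranked; `T*` is the `D*`-th smallest, or the iteration is
#'     incomplete if fewer than `D*` events can ever occur.
#' }
#' Losses to follow-up are never extended: they can no longer yield events.
#' Consumes the session RNG.
#'
#' The default `"aggregate"` cure rule is the monitoring procedure's
#' literal prescription. Note that when enrollment is materially incomplete
#' it counts the cure mass of not-yet-enrolled patients twice (once in the
#' risk set, again among simulated future patients) and predictions drift
#' late; the `"conditional"` alternative instead cures each at-risk patient
#' with the individually correct posterior probability
#' \eqn{\pi / \{\pi + (1-\pi) S_u(c_i)\}} given event-free follow-up
#' `c_i`.
#'
#' @param snapshot a [trial_snapshot()].
#' @param spec a [cure_model()] (typically a [resample_parameters()] draw).
#' @param accrual an [accrual_model()], or `NULL` when enrollment is
#'   complete.
#' @param design a [design_spec()].
#' @param cure_rule `"aggregate"` (default) or `"conditional"`, see
#'   Details.
#' @return List: `time` (calendar `T*`, `NA` when incomplete), `complete`,
#'   and the iteration bookkeeping `n_cured`, `n_new_events`,
#'   `n_future_events`, `n_future_never`.
#' @export
simulate_one_completion <- function(snapshot, spec, accrual, design,
                                    cure_rule = c("aggregate",
                                                  "conditional")) {
  cure_rule <- match.arg(cure_rule)
  stopifnot(inherits(snapshot, "trial_snapshot"),
            inherits(spec, "cure_model"), inherits(design, "design_spec"))
  r <- snapshot$records
  obs_events <- r$entry_time[r$event] + r$observed_time[r$event]

  # (a) cure assignment within the risk set, then (b) conditional extension
  adm <- r$administrative_censor
  g <- sum(adm)
  n_cured <- 0L
  new_events <- numeric(0)
  if (g > 0L) {
    if (cure_rule == "aggregate") {
      p_cure <- min(1, max(0, spec$pi * design$target_n / g))
    } else {
      su_c <- latency_survival(spec$family, spec$theta,
                               r$observed_time[adm])
      p_cure <- spec$pi / (spec$pi + (1 - spec$pi) * su_c)
    }
    cured <- stats::runif(g) < p_cure
    n_cured <- sum(cured)
    if (any(!cured)) {
      ci <- r$observed_time[adm][!cured]
      new_events <- r$entry_time[adm][!cured] +
        sample_conditional(spec$family, spec$theta, c = ci, n = length(ci))
    }
  }

  # (c) complete enrollment with full-population outcomes
  n_future <- max(0L, design$target_n - nrow(r))
  future_events <- numeric(0)
  n_future_never <- 0L
  if (n_future > 0L) {
    if (is.null(accrual))
      stop("enrollment incomplete but no accrual model supplied")
    entries <- simulate_entries(accrual, n_future, snapshot$tau)
    pop <- sample_population(spec, n_future)
    n_future_never <- sum(pop$cured)
    future_events <- entries[!pop$cured] + pop$time[!pop$cured]
  }

  # (d) rank all achievable event calendar times
  all_events <- c(obs_events, new_events, future_events)
  if (length(all_events) >= design$target_events) {
    list(time = sort(all_events)[design$target_events], complete = TRUE,
         n_cured = n_cured, n_new_events = length(new_events),
         n_future_events = length(future_events),
         n_future_never = n_future_never)
  } else {
    list(time = NA_real_, complete = FALSE,
         n_cured = n_cured, n_new_events = length(new_events),
         n_future_events = length(future_events),
         n_future_never = n_future_never)
  }
}

# Deterministic per-iteration substream seed below 2^31, independent of
# execution order.
derive_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483647) * 69069 + i * 104729) %%
               2147483629)
}

#' Predict the calendar time of the target event count
#'
#' Runs `n_iter` independent iterations, each pairing a fresh
#' [resample_parameters()] draw with one [simulate_one_completion()]. The
#' fraction of incomplete iterations is the probability of study
#' incompletion `P(SIC)`; the point estimate is the median of the finite
#' completion times (the mean is reported alongside) and the `alpha/2`,
#' `1 - alpha/2` quantiles give the confidence limits, both computed over
#' completed iterations only. Fully reproducible from `seed` and `n_iter`.
#'
#' If the snapshot already holds `D*` events the observed `D*`-th event
#' date is returned with a zero-width interval and `p_sic = 0`.
#'
#' @param snapshot a [trial_snapshot()].
#' @param fit a converged `cure_fit`.
#' @param design a [design_spec()].
#' @param accrual an [accrual_model()]; `NULL` is allowed once enrollment
#'   is complete.
#' @param n_iter number of Monte-Carlo iterations (the monitoring default
#'   used throughout is 10,000).
#' @param alpha two-sided level for the prediction interval.
#' @param seed master seed; per-iteration substreams are derived from it.
#' @param cure_rule passed to [simulate_one_completion()].
#' @return Object of class `cure_prediction`: `times` (length `n_iter`,
#'   `NA` marks incomplete iterations), `p_sic`, `point_estimate`,
#'   `mean_estimate`, `ci_lower`, `ci_upper`, `n_iter`, `alpha`, `seed`,
#'   `resampled` (per-iteration natural-scale parameter draws).
#' @export
predict_analysis_time <- function(snapshot, fit, design, accrual = NULL,
                                  n_iter = 10000L, alpha = 0.05,
                                  seed = 1L,
                                  cure_rule = c("aggregate",
                                                "conditional")) {
  cure_rule <- match.arg(cure_rule)
  stopifnot(inherits(snapshot, "trial_snapshot"), inherits(fit, "cure_fit"),
            inherits(design, "design_spec"), n_iter >= 1L)
  if (!fit$converged) stop("prediction needs a converged fit")
  counts <- snapshot_counts(snapshot)

  if (counts$d >= design$target_events) {
    r <- snapshot$records
    obs <- sort(r$entry_time[r$event] + r$observed_time[r$event])
    t_star <- obs[design$target_events]
    return(structure(list(times = rep(t_star, n_iter), p_sic = 0,
                          point_estimate = t_star, mean_estimate = t_star,
                          ci_lower = t_star, ci_upper = t_star,
                          n_iter = as.integer(n_iter), alpha = alpha,
                          seed = as.integer(seed),
                          resampled = NULL, already_reached = TRUE),
                     class = "cure_prediction"))
  }

  L <- mvn_sqrt(fit$covariance)
  k <- length(fit$raw_params)
  times <- rep(NA_real_, n_iter)
  draws <- matrix(NA_real_, n_iter, k)
  for (i in seq_len(n_iter)) {
    set.seed(derive_seed(seed, i))
    raw <- fit$raw_params + as.numeric(L %*% stats::rnorm(k))
    spec_i <- from_unconstrained(fit$family, raw)
    draws[i, ] <- c(spec_i$pi, spec_i$theta)
    res <- simulate_one_completion(snapshot, spec_i, accrual, design,
                                   cure_rule = cure_rule)
    if (res$complete) times[i] <- res$time
  }

  finite <- times[!is.na(times)]
  p_sic <- sum(is.na(times)) / n_iter
  if (length(finite)) {
    qs <- unname(stats::quantile(finite, c(alpha / 2, 1 - alpha / 2)))
    point <- stats::median(finite); avg <- mean(finite)
    lo <- qs[1L]; hi <- qs[2L]
  } else {
    point <- avg <- lo <- hi <- NA_real_
  }
  resampled <- data.frame(pi = draws[, 1L])
  resampled$theta1 <- draws[, 2L]
  resampled$theta2 <- if (k >= 3L) draws[, 3L] else NA_real_
  structure(list(times = times, p_sic = p_sic, point_estimate = point,
                 mean_estimate = avg, ci_lower = lo, ci_upper = hi,
                 n_iter = as.integer(n_iter), alpha = alpha,
                 seed = as.integer(seed), resampled = resampled,
                 already_reached = FALSE),
            class = "cure_prediction")
}

#' @export
print.cure_prediction <- function(x, ...) {
  cat("Analysis-time prediction (", x$n_iter, " iterations, seed ",
      x$seed, ")\n", sep = "")
  cat("  P(study incompletion) =", format(x$p_sic), "\n")
  if (is.na(x$point_estimate)) {
    cat("  no completed iteration; point estimate undefined\n")
  } else {
    cat("  T* estimate =", format(x$point_estimate), "days  [",
        format(x$ci_lower), ",", format(x$ci_upper), "] (",
        format(100 * (1 - x$alpha)), "% CI )\n")
  }
  invisible(x)
}
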