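## Maximum-likelihood estimation of (pi, theta) from a blinded snapshot.
##
## Optimization runs on an unconstrained scale: logit(pi), log(theta),
## except the lognormal location which is already unconstrained. The
## covariance reported in a fit is on this scale and is consumed directly
## by the multivariate-normal parameter resampler in prediction, so drawn
## parameters map back to valid (pi in (0,1), theta > 0) models.

to_unconstrained <- function(spec) {
  raw <- log(spec$theta)
  if (spec$family == "lognormal") raw[1L] <- spec$theta[1L]
  c(stats::qlogis(spec$pi), raw)
}

from_unconstrained <- function(family, raw) {
  theta <- exp(raw[-1L])
  if (family == "lognormal") theta[1L] <- raw[2L]
  cure_model(family, pi = stats::plogis(raw[1L]), theta = theta)
}

#' Censored-data log-likelihood of a mixture cure model
#'
#' For each record the contribution is
#' \eqn{\delta_i \log\{(1-\pi) f_u(X_i)\} +
#'      (1-\delta_i) \log\{\pi + (1-\pi) S_u(X_i)\}};
#' administrative censors and losses to follow-up enter identically (both
#' are right-censored at `X_i`). Returns `-Inf` (a value, never an error)
#' when any event term has zero density — e.g. an observed event under
#' `pi = 1`.
#'
#' @param snapshot a [trial_snapshot()] with at least one record.
#' @param spec a [cure_model()].
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
cure_loglik <- function(snapshot, spec) {
  stopifnot(inherits(snapshot, "trial_snapshot"),
            inherits(spec, "cure_model"))
  r <- snapshot$records
  if (nrow(r) == 0L) stop("log-likelihood needs at least one record")
  x <- r$observed_time
  d <- r$event
  ll <- 0
  if (any(d)) {
    if (spec$pi >= 1) return(-Inf)
    le <- log1p(-spec$pi) + latency_logdensity(spec$family, spec$theta, x[d])
    if (any(!is.finite(le) & le > 0)) return(NaN)
    ll <- ll + sum(le)
  }
  if (any(!d)) {
    su <- latency_survival(spec$family, spec$theta, x[!d])
    lc <- log(spec$pi + (1 - spec$pi) * su)
    ll <- ll + sum(lc)
  }
  if (is.nan(ll)) -Inf else ll
}

# Moment / quantile-based latency inits from the event times alone
# (the plain pi = 0 family fitted to events; censoring ignored on purpose,
# the optimizer refines from here).
latency_init <- function(family, x_events) {
  x <- x_events[x_events > 0]
  if (!length(x)) x <- pmax(x_events, 1e-3)
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- m / 2
  switch(family,
    exponential = 1 / m,
    weibull = {
      shape <- max(0.3, min(10, (s / m)^(-1.086)))
      scale <- m / gamma(1 + 1 / shape)
      c(1 / scale, shape)
    },
    loglogistic = {
      slog <- stats::sd(log(x))
      if (!is.finite(slog) || slog <= 0) slog <- 1
      c(1 / stats::median(x), max(0.3, min(10, base::pi / (sqrt(3) * slog))))
    },
    lognormal = {
      slog <- stats::sd(log(x))
      if (!is.finite(slog) || slog <= 0) slog <- 1
      c(mean(log(x)), slog)
    })
}

# KM plateau: survival at the largest event time, a crude cure-fraction read.
km_plateau <- function(snapshot) {
  km <- km_estimate(snapshot)
  p <- min(km$survival)
  min(max(p, 0.01), 0.95)
}

# Deterministic multi-start grid: pi inits crossed with fixed multiplicative
# perturbations of the latency init. No RNG — a fit is a pure function of
# the data.
start_grid <- function(snapshot, family, n_starts) {
  r <- snapshot$records
  th0 <- latency_init(family, r$observed_time[r$event])
  pis <- c(km_plateau(snapshot), 0.1, 0.3)
  mults <- c(1, 0.5, 2)
  starts <- list()
  for (m in mults) for (p0 in pis) {
    th <- th0
    if (family == "lognormal") th[2L] <- th[2L] * m else th <- th * m
    starts[[length(starts) + 1L]] <-
      to_unconstrained(cure_model(family, p0, th))
  }
  starts[seq_len(min(n_starts, length(starts)))]
}

central_hessian <- function(fn, par) {
  k <- length(par)
  h <- 1e-5 * (1 + abs(par))
  H <- matrix(0, k, k)
  f0 <- fn(par)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / h[i]^2
    if (i < k) for (j in seq((i + 1L), k)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fn(par + ei - ej) -
           fn(par - ei + ej) + fn(par - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit a mixture cure rate model by maximum likelihood
#'
#' Maximizes [cure_loglik()] on the unconstrained scale from a
#' deterministic multi-start grid (cure-fraction inits at the Kaplan-Meier
#' plateau, 0.1 and 0.3, crossed with perturbed moment-based latency
#' inits), Nelder-Mead followed by a BFGS polish. The covariance is the
#' inverse of the observed information at the optimum, differenced
#' centrally with step `1e-5 * (1 + |param|)`. A failed optimization sets
#' `converged = FALSE` rather than raising.
#'
#' @param snapshot a [trial_snapshot()] containing at least one event.
#' @param family one of [cure_families()].
#' @param n_starts number of grid starts to try (default 3).
#' @return Object of class `cure_fit`: `spec` (natural-scale estimates),
#'   `raw_params`, `covariance` (unconstrained scale), `loglik`, `aic`,
#'   `bic` (with `n` = number of patients), `n_obs`, `converged`,
#'   `n_starts_used`.
#' @export
fit_cure <- function(snapshot, family, n_starts = 3L) {
  stopifnot(inherits(snapshot, "trial_snapshot"), n_starts >= 1L)
  family <- match_family(family)
  counts <- snapshot_counts(snapshot)
  if (counts$d == 0L)
    stop("cannot fit: snapshot has no events (likelihood unbounded in pi)")

  negll <- function(raw) {
    ll <- cure_loglik(snapshot, from_unconstrained(family, raw))
    if (!is.finite(ll)) 1e12 else -ll
  }
  negll_grad <- function(raw) {
    vapply(seq_along(raw), function(i) {
      h <- 1e-6 * (1 + abs(raw[i]))
      e <- replace(numeric(length(raw)), i, h)
      (negll(raw + e) - negll(raw - e)) / (2 * h)
    }, numeric(1L))
  }

  starts <- start_grid(snapshot, family, n_starts)
  best <- NULL
  for (s in starts) {
    fit1 <- tryCatch({
      o <- stats::optim(s, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
      o <- stats::optim(o$par, negll, gr = negll_grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
      # gradient-based polish: drives the stationarity residual down on
      # likelihood surfaces whose value dwarfs the curvature scale
      nl <- stats::nlm(function(raw) {
        v <- negll(raw)
        attr(v, "gradient") <- negll_grad(raw)
        v
      }, o$par, gradtol = 1e-8, steptol = 1e-12, iterlim = 300)
      if (is.finite(nl$minimum) && nl$minimum <= o$value)
        list(par = nl$estimate, value = nl$minimum)
      else list(par = o$par, value = o$value)
    }, error = function(e) NULL)
    if (is.null(fit1) || !is.finite(fit1$value) || fit1$value >= 1e12)
      next
    if (is.null(best) || fit1$value < best$value - 1e-8) best <- fit1
  }

  if (is.null(best)) {
    return(structure(list(family = family, spec = NULL, raw_params = NULL,
                          covariance = NULL, loglik = -Inf, aic = Inf,
                          bic = Inf, n_obs = counts$n, converged = FALSE,
                          n_starts_used = length(starts)),
                     class = "cure_fit"))
  }

  raw <- best$par
  spec <- from_unconstrained(family, raw)
  ll <- cure_loglik(snapshot, spec)
  k <- 1L + n_latency_params(family)
  H <- central_hessian(negll, raw)
  covariance <- tryCatch({
    V <- solve(H)
    (V + t(V)) / 2
  }, error = function(e) {
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    vals <- ifelse(ev$values > 1e-10, 1 / ev$values, 0)
    V <- ev$vectors %*% diag(vals, k) %*% t(ev$vectors)
    (V + t(V)) / 2
  })

  structure(list(family = family, spec = spec, raw_params = raw,
                 covariance = covariance, loglik = ll,
                 aic = -2 * ll + 2 * k,
                 bic = -2 * ll + k * log(counts$n),
                 n_obs = counts$n, converged = TRUE,
                 n_starts_used = length(starts)),
            class = "cure_fit")
}

#' Build a degenerate fit object from a known model
#'
#' Wraps a [cure_model()] as a `cure_fit` with a supplied (default zero)
#' unconstrained-scale covariance. Useful for scenario analyses and
#' simulation studies where the parameters are posited rather than
#' estimated; the prediction machinery treats it like any other fit.
#'
#' @param spec a [cure_model()].
#' @param covariance optional covariance on the unconstrained scale
#'   (dimension `1 + length(theta)`); defaults to the zero matrix.
#' @export
as_cure_fit <- function(spec, covariance = NULL) {
  stopifnot(inherits(spec, "cure_model"), spec$pi < 1)
  if (spec$pi == 0) spec$pi <- 1e-12   # keep logit finite
  k <- 1L + n_latency_params(spec$family)
  if (is.null(covariance)) covariance <- matrix(0, k, k)
  stopifnot(is.matrix(covariance), all(dim(covariance) == k))
  structure(list(family = spec$family, spec = spec,
                 raw_params = to_unconstrained(spec),
                 covariance = covariance, loglik = NA_real_,
                 aic = NA_real_, bic = NA_real_, n_obs = NA_integer_,
                 converged = TRUE, n_starts_used = 0L),
            class = "cure_fit")
}

#' @export
print.cure_fit <- function(x, ...) {
  cat("Mixture cure rate fit (", x$family, " latency)\n", sep = "")
  if (!x$converged) {
    cat("  NOT converged\n")
    return(invisible(x))
  }
  cat("  pi_hat =", format(x$spec$pi),
      "| theta_hat =", paste(format(x$spec$theta), collapse = ", "), "\n")
  cat("  loglik =", format(x$loglik), "| AIC =", format(x$aic),
      "| BIC =", format(x$bic), "\n")
  invisible(x)
}

#' Fit and rank all candidate latency families
#'
#' Fits each family and ranks by AIC or BIC (ascending). Criterion ties
#' break by the fixed family order exponential, weibull, loglogistic,
#' lognormal, so selection is deterministic.
#'
#' @param snapshot a [trial_snapshot()].
#' @param families candidate families (default all four).
#' @param criterion `"aic"` or `"bic"`.
#' @param n_starts starts per family, see [fit_cure()].
#' @return Object of class `cure_selection`: `fits` (named list),
#'   `table` (family, loglik, aic, bic, converged), `ranking_aic`,
#'   `ranking_bic`, `best`, `criterion`.
#' @export
select_model <- function(snapshot, families = cure_families(),
                         criterion = c("aic", "bic"), n_starts = 3L) {
  criterion <- match.arg(criterion)
  if (!length(families)) stop("need at least one candidate family")
  families <- unname(vapply(families, match_family, character(1L)))
  fits <- lapply(families, function(f) fit_cure(snapshot, f, n_starts))
  names(fits) <- families
  if (!any(vapply(fits, `[[`, logical(1L), "converged")))
    stop("no candidate family converged")
  tab <- data.frame(
    family = families,
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    aic = vapply(fits, `[[`, numeric(1L), "aic"),
    bic = vapply(fits, `[[`, numeric(1L), "bic"),
    converged = vapply(fits, `[[`, logical(1L), "converged"),
    row.names = NULL)
  fam_order <- match(families, cure_families())
  rank_by <- function(crit) families[order(tab[[crit]], fam_order)]
  ranking_aic <- rank_by("aic")
  ranking_bic <- rank_by("bic")
  best <- if (criterion == "aic") ranking_aic[1L] else ranking_bic[1L]
  structure(list(fits = fits, table = tab, ranking_aic = ranking_aic,
                 ranking_bic = ranking_bic, best = best,
                 criterion = criterion),
            class = "cure_selection")
}

#' @export
print.cure_selection <- function(x, ...) {
  cat("Model selection over", nrow(x$table), "families (criterion:",
      x$criterion, ")\n")
  print(x$table, row.names = FALSE)
  cat("Best:", x$best, "\n")
  invisible(x)
}

#' Fitted survival curve against the Kaplan-Meier estimate
#'
#' The graphical goodness-of-fit check: model survival evaluated on a grid
#' alongside the KM step function, plus the maximum absolute vertical gap
#' between the two at the KM event times.
#'
#' @param snapshot a [trial_snapshot()].
#' @param fit a converged `cure_fit`.
#' @param grid times at which to evaluate the model curve.
#' @return List with `km` (data.frame), `model` (data.frame `time,
#'   survival`), `max_gap`.
#' @export
fitted_vs_km <- function(snapshot, fit, grid) {
  stopifnot(inherits(fit, "cure_fit"))
  if (!fit$converged) stop("fit did not converge")
  km <- km_estimate(snapshot)
  model <- data.frame(time = grid, survival = cure_survival(fit$spec, grid))
  ev_t <- sort(unique(snapshot$records$observed_time[snapshot$records$event]))
  max_gap <- if (length(ev_t)) {
    max(abs(cure_survival(fit$spec, ev_t) - km_survival_at(km, ev_t)))
  } else NA_real_
  list(km = km, model = model, max_gap = max_gap)
}
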