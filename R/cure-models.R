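#' Supported latency families
#'
#' The time-to-event law among susceptible patients can be exponential,
#' Weibull, log-logistic or lognormal. The population survival is the
#' two-component mixture \eqn{S(t) = \pi + (1-\pi) S_u(t)}, where \eqn{\pi}
#' is the cured (non-susceptible) fraction and \eqn{S_u} the latency
#' survival.
#'
#' @return Character vector of the four family tags.
#' @export
cure_families <- function() {
  c("exponential", "weibull", "loglogistic", "lognormal")
}

match_family <- function(tag) {
  if (!is.character(tag) || length(tag) != 1L || !tag %in% cure_families())
    stop("unknown latency family: ", paste(tag, collapse = ", "),
         " (expected one of ", paste(cure_families(), collapse = ", "), ")")
  tag
}

n_latency_params <- function(family) {
  if (family == "exponential") 1L else 2L
}

#' Mixture cure rate model specification
#'
#' Bundles a latency family with its parameters. Parametrizations (all
#' rate-based so that `theta[1]` is on a common 1/time scale):
#' \itemize{
#'   \item exponential: \eqn{S_u(t) = \exp(-\theta_1 t)}
#'   \item weibull: \eqn{S_u(t) = \exp(-(\theta_1 t)^{\theta_2})}
#'   \item loglogistic: \eqn{S_u(t) = 1 / (1 + (\theta_1 t)^{\theta_2})}
#'   \item lognormal: \eqn{S_u(t) = 1 - \Phi((\log t - \theta_1)/\theta_2)};
#'     here \eqn{\theta_1} is a log-scale location and may be any real.
#' }
#' Users mapping estimates to other conventions (e.g. Weibull scale =
#' `1/theta[1]`, shape = `theta[2]`) should note that predictions are
#' invariant to reparametrization but the printed parameter values are not.
#'
#' @param family one of [cure_families()].
#' @param pi cured fraction in \[0, 1\].
#' @param theta latency parameters (length 1 for exponential, 2 otherwise);
#'   strictly positive except the lognormal location.
#' @return An object of class `cure_model`.
#' @examples
#' m <- cure_model("weibull", pi = 0.2, theta = c(1/10, 1.5))
#' cure_survival(m, c(0, 5, 50))
#' @export
cure_model <- function(family, pi, theta) {
  family <- match_family(family)
  if (!is.numeric(pi) || length(pi) != 1L || is.na(pi) || pi < 0 || pi > 1)
    stop("pi must be a single probability in [0, 1]")
  theta <- as.numeric(theta)
  if (length(theta) != n_latency_params(family))
    stop("family '", family, "' needs ", n_latency_params(family),
         " latency parameter(s), got ", length(theta))
  if (any(is.na(theta))) stop("latency parameters must be finite")
  positive <- if (family == "lognormal") theta[2L] else theta
  if (any(positive <= 0))
    stop("latency parameters must be strictly positive",
         if (family == "lognormal") " (except the lognormal location)" else "")
  structure(list(family = family, pi = pi, theta = theta),
            class = "cure_model")
}

#' @export
print.cure_model <- function(x, ...) {
  cat("Mixture cure rate model (", x$family, " latency)\n", sep = "")
  cat("  cured fraction pi =", format(x$pi), "\n")
  cat("  theta =", paste(format(x$theta), collapse = ", "), "\n")
  invisible(x)
}

## Latency building blocks. All closed forms; vectorized in t / p.

latency_survival <- function(family, theta, t) {
  switch(family,
    exponential = exp(-theta[1L] * t),
    weibull     = exp(-(theta[1L] * t)^theta[2L]),
    loglogistic = 1 / (1 + (theta[1L] * t)^theta[2L]),
    lognormal   = stats::plnorm(t, meanlog = theta[1L], sdlog = theta[2L],
                                lower.tail = FALSE))
}

latency_density <- function(family, theta, t) {
  switch(family,
    exponential = stats::dexp(t, rate = theta[1L]),
    weibull     = stats::dweibull(t, shape = theta[2L], scale = 1 / theta[1L]),
    loglogistic = {
      u <- (theta[1L] * t)^theta[2L]
      at0 <- if (theta[2L] > 1) 0 else if (theta[2L] == 1) theta[1L] else Inf
      ifelse(t > 0, theta[2L] * u / (t * (1 + u)^2), at0)
    },
    lognormal   = stats::dlnorm(t, meanlog = theta[1L], sdlog = theta[2L]))
}

latency_logdensity <- function(family, theta, t) {
  switch(family,
    exponential = stats::dexp(t, rate = theta[1L], log = TRUE),
    weibull     = stats::dweibull(t, shape = theta[2L], scale = 1 / theta[1L],
                                  log = TRUE),
    loglogistic = {
      lu <- theta[2L] * (log(theta[1L]) + log(t))
      log(theta[2L]) + lu - log(t) - 2 * log1p(exp(pmin(lu, 700)))
    },
    lognormal   = stats::dlnorm(t, meanlog = theta[1L], sdlog = theta[2L],
                                log = TRUE))
}

#' Population survival, density and hazard of a mixture cure model
#'
#' `cure_survival` returns \eqn{\pi + (1-\pi) S_u(t)}; `cure_density`
#' returns \eqn{(1-\pi) f_u(t)}, which integrates to \eqn{1-\pi} (the
#' susceptible mass); `cure_hazard` is their ratio and, whenever
#' \eqn{\pi > 0}, tends to zero as `t` grows — the defining kinetic of a
#' survival plateau.
#'
#' @param spec a [cure_model()].
#' @param t non-negative time(s).
#' @return Numeric vector the length of `t`.
#' @export
cure_survival <- function(spec, t) {
  stopifnot(inherits(spec, "cure_model"))
  if (any(t < 0)) stop("t must be non-negative")
  spec$pi + (1 - spec$pi) * latency_survival(spec$family, spec$theta, t)
}

#' @rdname cure_survival
#' @export
cure_density <- function(spec, t) {
  stopifnot(inherits(spec, "cure_model"))
  if (any(t < 0)) stop("t must be non-negative")
  (1 - spec$pi) * latency_density(spec$family, spec$theta, t)
}

#' @rdname cure_survival
#' @export
cure_hazard <- function(spec, t) {
  s <- cure_survival(spec, t)
  if (any(s <= 0)) stop("hazard undefined where survival is zero")
  cure_density(spec, t) / s
}

#' Latency quantile: invert the susceptible survival function
#'
#' Returns the time `t` with \eqn{S_u(t) = p}. This is the workhorse of the
#' exact samplers: a uniform draw pushed through it is an inverse-CDF draw
#' from the latency distribution.
#'
#' @param family one of [cure_families()].
#' @param theta latency parameters.
#' @param p survival probability strictly inside (0, 1) (vectorized).
#' @export
latency_quantile <- function(family, theta, p) {
  family <- match_family(family)
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  switch(family,
    exponential = -log(p) / theta[1L],
    weibull     = (-log(p))^(1 / theta[2L]) / theta[1L],
    loglogistic = ((1 - p) / p)^(1 / theta[2L]) / theta[1L],
    lognormal   = stats::qlnorm(p, meanlog = theta[1L], sdlog = theta[2L],
                                lower.tail = FALSE))
}

#' Sample latency times conditional on survival beyond an observed time
#'
#' Draws event times from the latency distribution left-truncated at `c`:
#' with \eqn{U \sim} uniform(0,1), \eqn{T = S_u^{-1}(U \cdot S_u(c)) > c}.
#' This is how at-risk patients are extended in the prediction procedure —
#' patients with longer follow-up draw from further out in the tail.
#' Consumes the session RNG; `set.seed()` beforehand for reproducibility.
#'
#' @param family,theta latency family and parameters.
#' @param c truncation time(s), `>= 0`; either scalar or length `n`.
#' @param n number of draws.
#' @return `n` times, each strictly greater than (its) `c`.
#' @export
sample_conditional <- function(family, theta, c, n) {
  family <- match_family(family)
  if (any(c < 0)) stop("truncation time c must be non-negative")
  if (n < 1L) stop("n must be at least 1")
  if (!length(c) %in% c(1L, n)) stop("c must be scalar or length n")
  sc <- latency_survival(family, theta, c)
  if (any(sc <= 0))
    stop("no latency mass beyond the truncation time (S_u(c) = 0)")
  latency_quantile(family, theta, stats::runif(n) * sc)
}

#' Sample complete population outcomes from a mixture cure model
#'
#' Each subject is cured with probability `pi` (then never experiences the
#' event) or draws an unconditional latency time. Cured subjects carry
#' `time = NA`; the `cured` column is the authoritative marker — never do
#' arithmetic on the time of a cured subject.
#'
#' @param spec a [cure_model()].
#' @param n number of subjects.
#' @return `data.frame` with columns `cured` (logical) and `time` (numeric,
#'   `NA` when cured).
#' @export
sample_population <- function(spec, n) {
  stopifnot(inherits(spec, "cure_model"))
  if (n < 1L) stop("n must be at least 1")
  cured <- stats::runif(n) < spec$pi
  time <- rep(NA_real_, n)
  k <- sum(!cured)
  if (k > 0L)
    time[!cured] <- latency_quantile(spec$family, spec$theta, stats::runif(k))
  data.frame(cured = cured, time = time)
}
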