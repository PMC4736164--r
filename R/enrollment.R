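#' Accrual model
#'
#' A single average enrollment rate, realized either as a homogeneous
#' Poisson process (exponential inter-arrival gaps) or as a deterministic
#' uniform spacing for reproducibility-sensitive runs.
#'
#' @param rate patients per day, `> 0`.
#' @param model `"poisson_process"` (default) or `"uniform_rate"`.
#' @export
accrual_model <- function(rate, model = c("poisson_process", "uniform_rate")) {
  model <- match.arg(model)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("accrual rate must be a single positive number")
  structure(list(rate = rate, model = model), class = "accrual_model")
}

#' Estimate the accrual rate from observed entries
#'
#' Rate = N(tau) / (span of observed entry times). An optional
#' `window_days` restricts the estimate to the most recent entries, for
#' trials with pronounced ramp-up.
#'
#' @param snapshot a [trial_snapshot()] with at least two entries.
#' @param model passed to [accrual_model()].
#' @param window_days optional recent window (days before the last entry).
#' @export
estimate_accrual <- function(snapshot,
                             model = c("poisson_process", "uniform_rate"),
                             window_days = NULL) {
  stopifnot(inherits(snapshot, "trial_snapshot"))
  e <- snapshot$records$entry_time
  if (!is.null(window_days)) e <- e[e >= max(e) - window_days]
  if (length(e) < 2L)
    stop("accrual estimation needs at least two enrolled patients")
  span <- max(e) - min(e)
  if (span <= 0)
    stop("all entries at a single instant; accrual rate undefined")
  accrual_model(length(e) / span, model = model)
}

#' Simulate enrollment dates for patients not yet randomized
#'
#' Returns `n_remaining` sorted calendar entry times strictly after `tau`.
#' Under `poisson_process` gaps are exponential with mean `1/rate`
#' (consumes the session RNG); under `uniform_rate` arrivals sit
#' deterministically at `tau + k/rate`.
#'
#' @param model an [accrual_model()].
#' @param n_remaining how many patients remain to be enrolled (`>= 0`).
#' @param tau calendar time after which enrollment resumes.
#' @export
simulate_entries <- function(model, n_remaining, tau) {
  stopifnot(inherits(model, "accrual_model"), n_remaining >= 0L)
  if (n_remaining == 0L) return(numeric(0))
  if (model$model == "uniform_rate") {
    tau + seq_len(n_remaining) / model$rate
  } else {
    tau + cumsum(stats::rexp(n_remaining, rate = model$rate))
  }
}
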