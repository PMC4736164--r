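#' Configuration of a synthetic trial
#'
#' Defines the generating truth for a complete simulated trial: staggered
#' Poisson accrual, mixture-cure event times, optional exponential loss to
#' follow-up, and a seed making the whole trial deterministic.
#'
#' @param n_patients number of patients to randomize.
#' @param accrual_rate patients per day (`> 0`).
#' @param truth the generating [cure_model()].
#' @param ltfu_rate hazard of loss to follow-up per day (`0` disables).
#' @param seed integer seed.
#' @export
trial_config <- function(n_patients, accrual_rate, truth, ltfu_rate = 0,
                         seed = 1L) {
  stopifnot(n_patients >= 1L, accrual_rate > 0, ltfu_rate >= 0,
            inherits(truth, "cure_model"))
  structure(list(n_patients = as.integer(n_patients),
                 accrual_rate = accrual_rate, truth = truth,
                 ltfu_rate = ltfu_rate, seed = as.integer(seed)),
            class = "trial_config")
}

#' Default configuration shaped like a phase III immunotherapy trial
#'
#' A documentation-friendly default: 502 patients accrued over roughly 18
#' months, Weibull-cure truth with a 16\% long-term event-free fraction
#' and a median latency around one year. Purely illustrative.
#'
#' @param seed integer seed.
#' @export
example_trial_config <- function(seed = 1L) {
  trial_config(
    n_patients = 502L,
    accrual_rate = 502 / 540,
    truth = cure_model("weibull", pi = 0.16, theta = c(1 / 400, 1.3)),
    ltfu_rate = 0,
    seed = seed)
}

#' Generate a complete synthetic trial
#'
#' Entry times come from a Poisson process at `accrual_rate`, shifted so
#' the first randomization defines calendar day 0. Event outcomes come
#' from the full mixture law ([sample_population()]); cured patients carry
#' `event_time = NA`. Losses to follow-up are exponential at `ltfu_rate`
#' (`NA` = never when the rate is 0). Deterministic given the config seed.
#'
#' @param config a [trial_config()].
#' @return Object of class `synthetic_trial`: `patients` data.frame
#'   (`entry_time`, `cured`, `event_time`, `ltfu_time`) plus the config.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  n <- config$n_patients
  entry <- cumsum(stats::rexp(n, rate = config$accrual_rate))
  entry <- entry - entry[1L]
  pop <- sample_population(config$truth, n)
  ltfu <- if (config$ltfu_rate > 0)
    stats::rexp(n, rate = config$ltfu_rate) else rep(NA_real_, n)
  structure(list(patients = data.frame(entry_time = entry,
                                       cured = pop$cured,
                                       event_time = pop$time,
                                       ltfu_time = ltfu),
                 config = config),
            class = "synthetic_trial")
}

#' Freeze a blinded snapshot of a synthetic trial at calendar time tau
#'
#' Applies the observation rule `X_i = min(T_i, C_i, (tau - E_i)^+)` to
#' every patient randomized by `tau`, with `delta_i = 1` iff the event
#' comes first. Exact ties (measure zero) resolve in the order
#' event > loss-to-follow-up > administrative, matching the `<=` in the
#' censoring indicator convention.
#'
#' @param trial a [generate_trial()] result.
#' @param tau calendar time of the snapshot (`> 0`).
#' @return A [trial_snapshot()] (possibly empty of records).
#' @export
snapshot_at <- function(trial, tau) {
  stopifnot(inherits(trial, "synthetic_trial"), tau > 0)
  p <- trial$patients[trial$patients$entry_time <= tau, , drop = FALSE]
  n <- nrow(p)
  if (n == 0L) {
    empty <- data.frame(id = character(0), entry_time = numeric(0),
                        observed_time = numeric(0), event = logical(0),
                        administrative_censor = logical(0))
    return(trial_snapshot(empty, tau, trial$config$n_patients))
  }
  fu <- pmax(tau - p$entry_time, 0)
  ev <- ifelse(is.na(p$event_time), Inf, p$event_time)
  lt <- ifelse(is.na(p$ltfu_time), Inf, p$ltfu_time)
  is_event <- ev <= pmin(lt, fu)
  is_ltfu <- !is_event & lt <= fu
  x <- ifelse(is_event, ev, ifelse(is_ltfu, lt, fu))
  rec <- data.frame(
    id = sprintf("P%05d", seq_len(nrow(trial$patients)))[
      trial$patients$entry_time <= tau],
    entry_time = p$entry_time,
    observed_time = x,
    event = is_event,
    administrative_censor = !is_event & !is_ltfu)
  trial_snapshot(rec, tau, trial$config$n_patients)
}

#' True calendar date of the d-th event of a synthetic trial
#'
#' Ground truth for calibration: the `d_star`-th smallest `E_i + T_i` over
#' patients who are not cured and whose event is not preempted by loss to
#' follow-up. `NA` (incomplete) if fewer such events exist.
#'
#' @param trial a [generate_trial()] result.
#' @param d_star target event count (`>= 1`).
#' @export
true_analysis_time <- function(trial, d_star) {
  stopifnot(inherits(trial, "synthetic_trial"), d_star >= 1L)
  p <- trial$patients
  lt <- ifelse(is.na(p$ltfu_time), Inf, p$ltfu_time)
  keep <- !p$cured & !is.na(p$event_time) & p$event_time <= lt
  cal <- sort(p$entry_time[keep] + p$event_time[keep])
  if (length(cal) < d_star) NA_real_ else cal[d_star]
}

#' Write a synthetic trial's full (unblinded) truth to CSV
#'
#' @param trial a `synthetic_trial`.
#' @param path output path.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "synthetic_trial"))
  utils::write.csv(trial$patients, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
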