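#' Blinded trial snapshot
#'
#' A snapshot freezes the pooled (arms-combined) patient-level data at the
#' prediction time `tau`, measured in days from first randomization. Each
#' record carries the entry calendar time `E_i`, the observed time on study
#' `X_i = min(T_i, C_i, (tau - E_i)^+)`, the event indicator `delta_i`, and
#' a flag separating administrative censoring (event-free purely because of
#' the data cutoff — the risk set `G(tau)` that prediction re-simulates)
#' from loss to follow-up (censored for good).
#'
#' @param records data.frame with columns `id`, `entry_time`,
#'   `observed_time`, `event`, `administrative_censor`.
#' @param tau prediction calendar time (days from first randomization).
#' @param target_n planned total sample size `N`.
#' @return Object of class `trial_snapshot`.
#' @export
trial_snapshot <- function(records, tau, target_n) {
  stopifnot(is.data.frame(records), is.numeric(tau), length(tau) == 1L)
  needed <- c("id", "entry_time", "observed_time", "event",
              "administrative_censor")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  records$id <- as.character(records$id)
  records$event <- as.logical(records$event)
  records$administrative_censor <- as.logical(records$administrative_censor)
  validate_records(records, tau)
  if (nrow(records) > target_n)
    stop("snapshot has more patients (", nrow(records),
         ") than the target sample size (", target_n, ")")
  structure(list(tau = tau, records = records[, needed],
                 target_n = as.integer(target_n)),
            class = "trial_snapshot")
}

# admin censors must sit at the cutoff: |X - (tau - E)| <= 1 day
ADMIN_TOL <- 1 + 1e-9

validate_records <- function(records, tau) {
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop("invalid record in row ", idx[1L], ": ", what)
  }
  bad_row(is.na(records$entry_time) | is.na(records$observed_time),
          "missing time")
  bad_row(records$observed_time < 0, "negative observed_time")
  bad_row(records$entry_time < 0, "negative entry_time")
  bad_row(records$entry_time > tau, "entry_time after tau")
  bad_row(records$event & records$administrative_censor,
          "event and administrative_censor both set")
  adm <- records$administrative_censor
  bad_row(adm & abs(records$observed_time -
                      pmax(tau - records$entry_time, 0)) > ADMIN_TOL,
          "administrative censor not at the data cutoff")
  invisible(records)
}

#' Read a trial snapshot from CSV
#'
#' Expects header `id,entry_time,observed_time,event,administrative_censor`
#' (the last column optional; flags as 0/1). When `administrative_censor`
#' is absent it is inferred: a censored record whose follow-up reaches
#' `tau - entry_time` to within one day is administrative, anything shorter
#' is a loss to follow-up.
#'
#' @param path CSV file path.
#' @param tau,target_n see [trial_snapshot()].
#' @export
read_snapshot <- function(path, tau, target_n) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "entry_time", "observed_time", "event")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("snapshot file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"administrative_censor" %in% names(df)) {
    df$administrative_censor <-
      df$event == 0 &
      df$observed_time >= pmax(tau - df$entry_time, 0) - 1
  }
  trial_snapshot(df, tau = tau, target_n = target_n)
}

#' Write a trial snapshot to CSV
#'
#' Same dialect as [read_snapshot()]; flags written as 0/1. Round-trips to
#' identical records.
#'
#' @param snapshot a `trial_snapshot`.
#' @param path output file path.
#' @export
write_snapshot <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "trial_snapshot"))
  df <- snapshot$records
  df$event <- as.integer(df$event)
  df$administrative_censor <- as.integer(df$administrative_censor)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Snapshot bookkeeping counts
#'
#' @param snapshot a `trial_snapshot`.
#' @return List with `n` = N(tau) randomized, `d` = D(tau) events, `g` =
#'   G(tau) administrative censors (the risk set), and `n_ltfu` losses to
#'   follow-up; `d + g + n_ltfu == n`.
#' @export
snapshot_counts <- function(snapshot) {
  stopifnot(inherits(snapshot, "trial_snapshot"))
  r <- snapshot$records
  d <- sum(r$event)
  g <- sum(r$administrative_censor)
  list(n = nrow(r), d = d, g = g, n_ltfu = nrow(r) - d - g)
}

#' @export
print.trial_snapshot <- function(x, ...) {
  k <- snapshot_counts(x)
  cat("Trial snapshot at tau =", format(x$tau), "days\n")
  cat("  N(tau) =", k$n, "of target", x$target_n,
      "| D(tau) =", k$d, "| G(tau) =", k$g, "| LTFU =", k$n_ltfu, "\n")
  invisible(x)
}

#' Pooled Kaplan-Meier estimate of a snapshot
#'
#' Product-limit estimator with arms combined, used for the graphical
#' goodness-of-fit check against a fitted cure model. Delegates to
#' [survival::survfit()].
#'
#' @param snapshot a `trial_snapshot` with at least one record.
#' @return data.frame `(time, survival, n_risk)`: a right-continuous step
#'   function starting at `(0, 1, n)`.
#' @export
km_estimate <- function(snapshot) {
  stopifnot(inherits(snapshot, "trial_snapshot"))
  r <- snapshot$records
  if (nrow(r) == 0L) stop("km_estimate needs at least one record")
  sf <- survival::survfit(
    survival::Surv(r$observed_time, r$event) ~ 1, conf.type = "none")
  data.frame(time = c(0, sf$time),
             survival = c(1, sf$surv),
             n_risk = c(nrow(r), sf$n.risk))
}

# Step-function lookup of a KM curve at arbitrary times.
km_survival_at <- function(km, t) {
  f <- stats::stepfun(km$time[-1L], km$survival, right = FALSE)
  f(t)
}
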