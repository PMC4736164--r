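#' Longitudinal monitoring report
#'
#' Strings together fit, model selection, analysis-time prediction and
#' design-power tracking over a sequence of review snapshots — the
#' quantities a data monitoring committee sees over the life of an
#' event-driven trial: per review, the selection table, the best family,
#' the estimated cure fraction, `P(SIC)`, the predicted analysis date with
#' confidence limits, the observed event count and the Schoenfeld power at
#' that count.
#'
#' A snapshot that cannot be fitted (e.g. no events yet) yields a row
#' flagged `insufficient_data` instead of aborting the whole report.
#'
#' @param snapshots list of [trial_snapshot()] objects, ordered by `tau`.
#' @param design a [design_spec()].
#' @param families candidate families for [select_model()].
#' @param criterion `"aic"` or `"bic"`.
#' @param n_iter Monte-Carlo iterations per review (default 10,000).
#' @param alpha two-sided level.
#' @param seed master seed; each review derives its own substream.
#' @return Object of class `monitoring_report` (list of per-review rows +
#'   metadata), serializable with [write_report()].
#' @export
run_monitoring <- function(snapshots, design, families = cure_families(),
                           criterion = c("aic", "bic"), n_iter = 10000L,
                           alpha = 0.05, seed = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(design, "design_spec"))
  if (length(snapshots) > 1L) {
    taus <- vapply(snapshots, `[[`, numeric(1L), "tau")
    if (is.unsorted(taus)) stop("snapshots must be ordered by tau")
  }
  rows <- vector("list", length(snapshots))
  for (j in seq_along(snapshots)) {
    snap <- snapshots[[j]]
    counts <- snapshot_counts(snap)
    row <- list(tau = snap$tau, n = counts$n, d = counts$d, g = counts$g,
                n_ltfu = counts$n_ltfu,
                power = schoenfeld_power(max(1, counts$d), design$design_hr,
                                         design$alpha, design$allocation),
                insufficient_data = FALSE)
    sel <- tryCatch(select_model(snap, families, criterion),
                    error = function(e) e)
    if (inherits(sel, "error")) {
      row$insufficient_data <- TRUE
      row$message <- conditionMessage(sel)
      rows[[j]] <- row
      next
    }
    best_fit <- sel$fits[[sel$best]]
    accrual <- if (counts$n < design$target_n)
      estimate_accrual(snap) else NULL
    pred <- predict_analysis_time(snap, best_fit, design, accrual,
                                  n_iter = n_iter, alpha = alpha,
                                  seed = derive_seed(seed, j))
    row$selection <- sel$table
    row$best_family <- sel$best
    row$pi_hat <- best_fit$spec$pi
    row$theta_hat <- best_fit$spec$theta
    row$p_sic <- pred$p_sic
    row$predicted_date <- pred$point_estimate
    row$ci_lower <- pred$ci_lower
    row$ci_upper <- pred$ci_upper
    rows[[j]] <- row
  }
  structure(list(reviews = rows,
                 design = unclass(design),
                 n_iter = as.integer(n_iter), alpha = alpha,
                 seed = as.integer(seed), criterion = criterion),
            class = "monitoring_report")
}

#' Serialize a monitoring report to JSON
#'
#' Byte-identical output for identical inputs and seeds, so reruns can be
#' diffed.
#'
#' @param report a `monitoring_report` (or any serializable list).
#' @param path output path; `NULL` returns the JSON string.
#' @export
write_report <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE, dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @export
print.monitoring_report <- function(x, ...) {
  cat("Monitoring report:", length(x$reviews), "review(s), target D* =",
      x$design$target_events, "\n")
  for (row in x$reviews) {
    if (row$insufficient_data) {
      cat(sprintf("  tau=%8.1f  D=%4d  [insufficient data]\n",
                  row$tau, row$d))
    } else {
      cat(sprintf(
        "  tau=%8.1f  D=%4d  best=%-11s pi_hat=%6.3f  P(SIC)=%6.3f  T*=%s  power=%5.3f\n",
        row$tau, row$d, row$best_family, row$pi_hat, row$p_sic,
        if (is.na(row$predicted_date)) "   --" else
          sprintf("%8.1f", row$predicted_date),
        row$power))
    }
  }
  invisible(x)
}
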