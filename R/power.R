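#' Schoenfeld power for the log-rank test
#'
#' Normal-approximation power of the two-sided log-rank test under
#' proportional hazards, as a function of the number of events alone:
#' \deqn{\Phi\left(|\log hr| \sqrt{d\, a(1-a)} - z_{1-\alpha/2}\right),}
#' with `a` the allocation fraction. This is the design-assumption power a
#' monitoring team tracks against the observed event count; it does not
#' account for cure-induced non-proportionality.
#'
#' @param d_events observed or planned number of events (`>= 1`).
#' @param hr hazard ratio under the alternative (e.g. a 38\% increase in
#'   median survival under exponential margins corresponds to
#'   `hr = 1/1.38`).
#' @param alpha two-sided significance level.
#' @param allocation fraction randomized to the experimental arm.
#' @return Power in (0, 1). Symmetric in `hr` vs `1/hr`.
#' @examples
#' schoenfeld_power(416, hr = 1 / 1.38)  # ~0.907
#' @export
schoenfeld_power <- function(d_events, hr, alpha = 0.05, allocation = 0.5) {
  if (any(d_events < 1)) stop("d_events must be at least 1")
  if (hr <= 0) stop("hazard ratio must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (allocation <= 0 || allocation >= 1)
    stop("allocation must be in (0, 1)")
  stats::pnorm(abs(log(hr)) * sqrt(d_events * allocation * (1 - allocation)) -
                 stats::qnorm(1 - alpha / 2))
}

#' Required number of events for a target log-rank power
#'
#' Inverts the Schoenfeld formula:
#' \eqn{d = \lceil (z_{1-\alpha/2} + z_{power})^2 /
#'   \{(\log hr)^2 a (1-a)\} \rceil}. The returned count always achieves at
#' least the requested power.
#'
#' @param power target power in (0, 1).
#' @param hr hazard ratio under the alternative, `!= 1`.
#' @param alpha,allocation as in [schoenfeld_power()].
#' @export
required_events <- function(power, hr, alpha = 0.05, allocation = 0.5) {
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (hr <= 0 || hr == 1) stop("hr must be positive and different from 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  ceiling(z^2 / (log(hr)^2 * allocation * (1 - allocation)))
}
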