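# curemonitor

Blinded event monitoring and analysis-time prediction for event-driven
clinical trials whose population contains a non-susceptible ("cured")
fraction.

Immuno-oncology trials routinely show Kaplan-Meier curves that plateau: a
fraction of patients never experiences the event of interest. In an
event-driven trial — one whose final analysis fires when a prespecified
event count `D*` is reached — that plateau can stretch the study far past
its planned duration, because standard projection methods assume every
patient will eventually have an event. `curemonitor` gives the study team
(or an independent monitoring committee) tools to track such a trial using
only blinded, arms-pooled data:

* **Mixture cure rate models.** The population survival is
  `S(t) = π + (1 − π)·S_u(t)`, where `π` is the cured fraction and `S_u`
  the latency (susceptible-population) survival, with exponential,
  Weibull, log-logistic or lognormal latency. Fitting is censored-data
  maximum likelihood with multi-start optimization; model choice is by
  AIC/BIC plus a Kaplan-Meier overlay.
* **Monte-Carlo analysis-time prediction.** Each iteration draws
  `(π̃, θ̃)` from the estimation uncertainty (multivariate normal on an
  unconstrained scale), marks a fraction `π̃N/G(τ)` of the at-risk set as
  cured, extends the rest conditionally on their observed follow-up,
  completes enrollment, and reads off the calendar date of the `D*`-th
  event. The outputs are a median predicted date, quantile confidence
  limits, and the **probability of study incompletion** `P(SIC)` — the
  fraction of iterations in which `D*` events can never occur.
* **Power tracking.** Schoenfeld's log-rank power formula
  `Φ(|log hr|·√(d·a(1−a)) − z_{1−α/2})` evaluated at the observed event
  count, plus its inversion to a required event count.
* **A synthetic-trial generator** (staggered Poisson accrual, mixture-cure
  event times, loss to follow-up, administrative cutoff) so the whole
  pipeline can be validated without any external data.

## Worked example

A simulated 502-patient trial (Weibull-cure truth, 16 % cured fraction,
accrual over ~18 months) monitored at day 1000 against a design that needs
`D* = 416` events:

```r
library(curemonitor)

trial <- generate_trial(example_trial_config(seed = 2026))
snap  <- snapshot_at(trial, tau = 1000)
snap
#> Trial snapshot at tau = 1000 days
#>   N(tau) = 502 of target 502 | D(tau) = 370 | G(tau) = 132 | LTFU = 0

sel <- select_model(snap, criterion = "aic")
fit <- sel$fits[[sel$best]]          # weibull wins; pi_hat = 0.129

design <- design_spec(target_n = 502, target_events = 416,
                      design_hr = 1 / 1.38)
pred <- predict_analysis_time(snap, fit, design, n_iter = 10000, seed = 11)
pred
#> Analysis-time prediction (10000 iterations, seed 11)
#>   P(study incompletion) = 0.1812
#>   T* estimate = 1296.471 days  [ 1179.347 , 1750.061 ] ( 95 % CI )

schoenfeld_power(snapshot_counts(snap)$d, hr = 1 / 1.38)
#> [1] 0.8723846
```

Reading: with 370 of 416 events observed, an 18 % chance remains that the
target count is never reached (the estimated 13 % cure fraction leaves
little susceptible mass); if the study does complete, the final analysis
is predicted around day 1296 with a wide right tail — and the trial's true
416th-event date (day 1407, known here because the data are simulated)
falls inside the interval. The log-rank power at the current event count
is 87 %.

The same pipeline is scriptable from a shell via
`Rscript inst/cli/curepredict.R predict --snapshot snap.csv --tau 1000
--target-n 502 --target-events 416 --family auto --iters 10000 --seed 11`
(subcommands: `fit`, `select`, `predict`, `power`, `events`, `simulate`,
`monitor`).

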