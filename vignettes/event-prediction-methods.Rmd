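---
title: "Predicting analysis times under a cure fraction: models, procedure, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting analysis times under a cure fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curemonitor)
```

## The problem

In an event-driven trial the final analysis is triggered by a prespecified
total event count $D^\*$, not a calendar date. When a therapy induces
long-term event-free survival in a subset of patients — the hallmark of
cancer immunotherapy — the Kaplan-Meier curve plateaus, the event rate
decays toward zero, and projections that assume everyone eventually has an
event become badly optimistic. The monitoring questions are: *when* will
the $D^\*$-th event occur, *will it ever*, and what log-rank power does the
observed event count already buy? All of this must be answered from
blinded data, pooled across arms.

## The model

The population survival is a two-component mixture
$$ S(t) = \pi + (1 - \pi)\, S_u(t), $$
with $\pi \in [0,1]$ the non-susceptible (cured) fraction and $S_u$ the
latency survival of the susceptible subpopulation. Four latency families
are supported, parametrized so that $\theta_1$ is a rate ($1/$time) in
every family with a scale parameter:

| family      | $S_u(t)$                                   | parameters |
|-------------|--------------------------------------------|------------|
| exponential | $\exp(-\theta_1 t)$                        | $\theta_1 > 0$ |
| weibull     | $\exp\{-(\theta_1 t)^{\theta_2}\}$         | $\theta_1, \theta_2 > 0$ |
| loglogistic | $1/\{1 + (\theta_1 t)^{\theta_2}\}$        | $\theta_1, \theta_2 > 0$ |
| lognormal   | $1 - \Phi\{(\log t - \theta_1)/\theta_2\}$ | $\theta_1 \in \mathbb R$, $\theta_2 > 0$ |

These shapes span the kinetics of interest: a gradually declining curve
with a plateau (Weibull cure, typical of immunotherapy overall survival),
a sharp early decline then plateau (lognormal cure, progression-type
endpoints), early-benefit/uncertain-tail behaviour (log-logistic), and the
constant-hazard reference (exponential). With $\pi > 0$ the population
hazard always decays to zero — which is exactly why proportional-hazards
projections fail. Predictions are invariant to reparametrization;
published estimates in scale/shape conventions map via scale
$= 1/\theta_1$.

Covariate-dependent cure probabilities and latency (and non-mixture,
promotion-time cure models) are out of scope: the monitoring setting
assumes only $(X_i, \delta_i)$ are available at prediction time.

## Data model

A snapshot at calendar time $\tau$ (days since first randomization)
records, per patient, the entry time $E_i$, the observed time on study
$X_i = \min(T_i, C_i, (\tau - E_i)^+)$, and the event indicator
$\delta_i$. Censored patients are split into **administrative censors**
(event-free purely because of the data cutoff — the risk set $G(\tau)$)
and **losses to follow-up**, which can never yield events and are
therefore never extended in prediction. When an input file lacks the
distinguishing flag, a censored record whose follow-up reaches
$\tau - E_i$ to within one day is inferred administrative. Times are kept
as numeric day offsets; treatment arm is deliberately not representable,
preserving blinding.

## Estimation

The censored-data log-likelihood is
$$ \ell(\pi, \theta) = \sum_i \delta_i \log\{(1-\pi) f_u(X_i)\}
   + (1 - \delta_i) \log\{\pi + (1-\pi) S_u(X_i)\}. $$
Maximization runs on an unconstrained scale — $\operatorname{logit}\pi$,
$\log\theta$ (the lognormal location is already unconstrained) — from a
deterministic multi-start grid: cure-fraction starts at the Kaplan-Meier
plateau, 0.1 and 0.3, crossed with moment-based latency initials and fixed
perturbations of them. Each start runs Nelder-Mead, a BFGS pass with
central-difference gradients, then a gradient-tolerance (`nlm`) polish;
mixture likelihoods on immature data are multi-modal, hence the grid. The
covariance is the inverse observed information at the optimum, differenced
centrally with step $10^{-5}(1 + |\text{param}|)$, on the unconstrained
scale — deliberately, because the prediction step resamples parameters
from a normal centered there, and draws map back to valid models
($\tilde\pi \in (0,1)$, $\tilde\theta > 0$) by construction. A fit is a
pure function of the data: rerunning it is bitwise identical.

AIC is $-2\ell + 2k$ and BIC $-2\ell + k\log n$ with $k = 1 + |\theta|$
and $n$ the number of *patients* (the standard, if debatable, convention
for censored data). Candidate families are ranked by either criterion;
ties break by the fixed order exponential, weibull, loglogistic,
lognormal, so selection is deterministic. Graphical assessment is served
by `fitted_vs_km()`, which reports the maximum vertical gap between the
fitted and product-limit curves at the event times.

When the cure fraction is weakly identified — short follow-up relative to
the latency scale — the MLE can land on the $\pi = 0$ boundary, where the
likelihood is flat in the $\operatorname{logit}\pi$ direction and the
observed information is numerically singular or indefinite. The
covariance is then repaired to the nearest positive semi-definite matrix
(negative eigenvalues clipped, with a message). The repaired covariance
understates the cure-fraction uncertainty; predictions made in this
regime should be read the way any early-review output should — as
provisional. The monitoring quantities themselves (an unstable $\hat\pi$
trajectory, a high $P(SIC)$) are the intended diagnostic.

## Prediction procedure

Given a fitted model at time $\tau$, each of `n_iter` iterations:

1. draws $(\tilde\pi, \tilde\theta)$ from the multivariate normal on the
   unconstrained scale and maps back;
2. marks each of the $G(\tau)$ at-risk patients cured independently with
   probability $\min\{1, \tilde\pi N / G(\tau)\}$, where $N$ is the
   *target* sample size;
3. gives every non-cured at-risk patient an event at
   $E_i + S_u^{-1}\{U \cdot S_u(X_i)\}$ — an exact inverse-CDF draw from
   the latency law left-truncated at the observed follow-up, so patients
   censored late draw from further out in the tail;
4. if enrollment is incomplete, simulates the remaining $N - N(\tau)$
   entry dates from the accrual model (homogeneous Poisson at the
   observed average rate by default; a deterministic uniform spacing is
   available) and gives each future patient a full-population outcome:
   cured with probability $\tilde\pi$, otherwise an untruncated latency
   draw;
5. ranks all finite event calendar times — observed events included — and
   records the $D^\*$-th smallest as $T^\*$, or marks the iteration
   *incomplete* if fewer than $D^\*$ events can ever occur.

$P(SIC)$ is the exact fraction of incomplete iterations. The point
estimate is the median of the finite $T^\*$ (the mean is reported
alongside; the median is robust to the heavy right tails these
distributions develop), and the $\alpha/2$, $1-\alpha/2$ quantiles give
the confidence limits, all computed over completed iterations only. Each
iteration runs on a seed derived from the master seed and the iteration
index, so results are reproducible independent of execution order, and
increasing $D^\*$ under the same seed can only push every iteration's
$T^\*$ later (the draws are consumed before the ranking).

Degenerate inputs are resolved rather than errored: if $D(\tau) \ge D^\*$
the observed $D^\*$-th event date is returned with a zero-width interval;
if no iteration completes, $P(SIC) = 1$ with undefined point estimate and
limits. No monitoring horizon is imposed — an iteration is incomplete only
when the events genuinely cannot occur.

### The cure-assignment rule, and its known bias

The aggregate rule in step 2 — cure probability $\tilde\pi N/G(\tau)$ — is
the procedure's literal prescription and the package default. It has the
right expectation exactly when enrollment is complete ($N(\tau) = N$,
expected cured $= \tilde\pi N$). When enrollment is materially incomplete
it double-counts cure mass: the $\tilde\pi N$ expected cures include
patients who have not yet enrolled, and step 4 then assigns those future
patients cure status again. Predictions drift late and $P(SIC)$ inflates
in that regime (our calibration experiments under an incomplete-enrollment
snapshot showed one-sided interval misses). Because the risk set under
administrative censoring has follow-up determined by entry time alone —
independent of cure status — the uniform assignment within the risk set
is otherwise innocuous. The per-patient posterior rule
$\tilde\pi / \{\tilde\pi + (1-\tilde\pi) S_u(c_i)\}$ is available as
`cure_rule = "conditional"` for users who prefer the principled variant;
the default stays faithful to the published procedure.

## Power tracking

The Schoenfeld normal-approximation power of the two-sided log-rank test,
$\Phi\{|\log hr|\sqrt{d\,a(1-a)} - z_{1-\alpha/2}\}$, is evaluated at the
observed event count $d$ at each review, and inverted (with a ceiling) for
required-events queries. A "38 % increase in median survival" design
alternative maps to $hr = 1/1.38$, exact under exponential margins; this
reading reproduces both protocol-style anchors (about 90 % power at 416
events, 86 % at 361). The formula assumes proportional hazards and is
tracked *as the protocol assumption*, not as the truth under the cure
model — a cure plateau is precisely a non-proportional-hazards phenomenon,
which is why the power column and the $P(SIC)$ column can tell different
stories at the same review.

## Synthetic trials

The generator draws staggered entries from a Poisson process (first entry
shifted to day 0, fixing the calendar origin), assigns cure status
Bernoulli($\pi$), draws latency times by inverse CDF, and optionally
superimposes exponential loss to follow-up. Snapshots apply the
observation rule exactly, with measure-zero ties resolved in the order
event > loss-to-follow-up > administrative, matching the $\le$ in the
censoring-indicator convention. `true_analysis_time()` exposes the
ground-truth $D^\*$-event date for calibration studies. "Never" outcomes
are represented as `NA` times alongside an authoritative `cured` flag —
not as numeric infinities — so accidental arithmetic on them surfaces as
`NA` rather than silently ordering.

What the generator emulates: staggered accrual, a mixture-cure event
process, administrative cutoff, independent exponential dropout. What it
does not: time-varying accrual ramps, delayed treatment-effect onset
(survival-curve separation after a lag), per-arm effects (everything is
pooled, as blinding requires), or dependent censoring. Passing tests on
these trials therefore validate the machinery and its calibration under a
correctly specified model, not robustness to the many ways real trial
data can violate it; the longitudinal instability of $\hat\pi$ on real
immature data is expected to be worse than in simulation.

## Study sizes used in validation

The test and acceptance experiments use deliberately scaled-down problem
sizes chosen to be informative, not minimal: parameter recovery on a
2000-patient trial with administrative cutoff at day 60 (fully accrued by
day 30, latency median ~9.3 days, so the cure plateau is well resolved);
interval calibration on 100 trials of 300 patients whose accrual spans
about 1.9 times the median latency — the time structure of the
motivating application study, where enrollment completed well before the
60 %-information point; selection consistency at 3000 patients;
prediction-vs-oracle comparisons at $10^4$ Monte-Carlo runs; and the
monitoring default of 10,000 iterations reduced to hundreds where only
reproducibility, not precision, is at stake. At the calibration
conditions the 90 % interval covers the true event date at the nominal
rate (~90/100); in a deliberately immature variant (accrual compressed to
a third of that span) coverage degrades to ~75 % through boundary fits
with degenerate Wald covariance — the behaviour discussed under
*Estimation*.

## Numerical choices

* Objective convergence tolerance $10^{-8}$; Hessian step
  $10^{-5}(1+|\text{param}|)$; stationarity at the reported optimum is
  verified to $10^{-3}$ in the tests.
* Underflow of $S_u$ far in the tail is handled in log space for event
  terms; a censored term $\log\{\pi + (1-\pi)S_u\}$ is safe for $\pi > 0$.
* $-\infty$ is a legitimate log-likelihood value (an observed event under
  $\pi = 1$), never an exception; the optimizer sees a large finite
  penalty instead.
* The multivariate-normal square root uses an eigendecomposition, so a
  zero covariance (scenario analyses via `as_cure_fit()`) yields the
  point estimate exactly.
* Quantile-type confidence limits use the default sample-quantile
  definition; with one completed iteration both limits collapse onto it.

## Limitations

Beyond the generator's idealizations listed above: the Wald/MVN
uncertainty propagation is first-order and degrades at the $\pi$ boundary;
losses to follow-up are treated as fixed (no dropout-process model);
accrual is homogeneous; and the power column ignores the very
non-proportionality the cure model exists to capture. None of these are
defects of implementation — they delimit where the method's answers should
be trusted, and the package's own diagnostics ($P(SIC)$, the $\hat\pi$
trajectory, KM overlays) are the tools for judging that in practice.
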