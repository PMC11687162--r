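---
title: "Landmark dynamic prediction of kidney-graft health: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark dynamic prediction of kidney-graft health: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftland)
```

## The prediction problem

A kidney-transplant recipient who is alive with a functioning graft at some
time $s$ after transplantation faces two competing terminal events: graft
failure (return to dialysis or re-transplantation) and death with a
functioning graft. Clinically useful prognosis at $s$ means three numbers
per horizon $\Delta$: the cumulative incidence of graft failure
$F_1(\Delta\mid s, Z)$, of death $F_2(\Delta\mid s, Z)$, and — if neither
occurs — the expected graft function (eGFR, mL/min/1.73m²) at $s+\Delta$.
Treating death as censoring would overstate graft-failure risk, because
censoring asserts the event could still happen afterwards; death precludes
it. All times in the package are months since transplantation, with
*baseline* fixed at month 6 (recipients must have a functioning graft
there), and the default horizons are 12, 36 and 60 months.

## Landmark construction

For each landmark $s$ (default monthly grid 6–60) the at-risk set contains
every subject with follow-up beyond $s$, whatever the eventual status. Each
at-risk subject contributes one row: the baseline covariates and five
time-varying features —

- `egfr_current`: the last monthly-thinned eGFR at or before $s$;
- `egfr_slope`, `egfr_volatility`: OLS slope and residual SD of eGFR on time
  over the trailing two-year window $(s-24, s]$ (at least 3 observations;
  otherwise slope 0 and the training-set median volatility at that landmark);
- `n_hosp_12m`, `n_reject_12m`: hospitalization/rejection counts over
  $(s-12, s]$.

All windows are half-open on the left so an event exactly at $s$ belongs to
the trailing window and an eGFR measured exactly at $s$ is the current
value; this makes every boundary case testable. eGFR series are first
thinned to at most one measurement per month-bin $[6+k, 6+k+1)$, keeping the
observation closest to the bin mid-point (ties toward the earlier one), so
that frequently measured patients are not over-weighted. When thinning
displaces the month-6 measurement past a landmark at $s=6$, the baseline
eGFR covariate — which is that measurement — stands in for it.

Models are fitted **per landmark, independently**. A smoothed "supermodel"
across landmarks is a possible refinement, but per-landmark fitting is the
simplest construction whose coefficient curves over $s$ can still be
inspected (see `coefficient_curves()`); optional smoothing is left to
plotting. Administrative censoring of residual times at $s+\max(\Delta)$ is
applied at *fit* time, not at dataset-construction time, so one landmark
dataset serves all horizons.

## The three sub-models

**Cause-specific hazards.** Each cause $k$ is fitted by Cox partial
likelihood on residual time, treating the competing cause as censoring
(`survival::coxph`, Breslow ties by default; Efron selectable). Features are
centered at training means so the Breslow baseline refers to an average
at-risk recipient; predictions are invariant to the centering convention
(tested). The package computes the Breslow baseline-hazard increments
itself so the step functions used in prediction are exact.

**From hazards to incidences.** The discrete product-limit construction

$$S(u) = \prod_{v \le u}\bigl(1 - d\Lambda_1(v|Z) - d\Lambda_2(v|Z)\bigr),
\qquad
F_k(\Delta) = \sum_{u \le \Delta} S(u{-})\, d\Lambda_k(u|Z)$$

is used instead of the asymptotically equivalent exponential form
$S = \exp(-\Lambda_1-\Lambda_2)$. The discrete form has two exact finite-
sample properties the exponential form lacks: $F_1 + F_2 + S = 1$ at every
horizon and subject, and exact reduction to the Aalen–Johansen estimator
when there are no covariates — both are asserted in the test suite at
tolerances 1e-8 and 1e-10. Per-subject hazard increments larger than the
remaining survival mass are clipped at zero survival, which can only occur
for extreme linear predictors.

**eGFR mean model.** A marginal GEE with mean
$\mathrm{E}[\mathrm{eGFR}(t)] = \alpha'X + \gamma (t-s)$ is fitted to the
observations in $(s, s+\Delta]$, one fit per (landmark, horizon) pair. No
GEE solver in the package's dependency set fit this need, so the estimating
equations (working independence by default, exchangeable selectable) and
the robust sandwich covariance are implemented in-package; with working
independence and one observation per subject the fit provably equals OLS
(tested to 1e-10), and the independence sandwich is verified against a
hand-computed cluster sandwich. Working independence is the default because
its mean estimates are consistent under any true correlation structure.
Subjects who fail or die inside the window contribute their observations up
to the event; the prediction therefore targets eGFR among recipients for
whom the terminal events have not intervened, matching the "if no event
occurs" framing of concurrent prediction. No floor or ceiling is applied to
predicted eGFR.

**Static comparator (SPM).** One cause-specific pair and one GEE fitted at
baseline only, with baseline covariates. At a later prediction time $s$ the
only coherent way for a baseline model to produce predictions is analytic
conditioning on being event-free:
$F_k^{\mathrm{SPM}}(\Delta \mid s) =
\{F_k(s-6+\Delta) - F_k(s-6)\}/S(s-6)$. The SPM eGFR prediction is the
baseline marginal mean at elapsed time $(s-6)+\Delta$, *not* conditioned on
survival — a deliberate choice, flagged here, since the baseline GEE has no
survival model of its own.

## Predictor selection

`backward_select()` removes one candidate at a time. Under the
*conservative* rule a candidate qualifies for removal only when its Wald
p-value exceeds $\alpha$ (default 0.05) in **all three sub-models at every
selection landmark** — i.e. a predictor significant anywhere is kept. The
*parsimonious* rule relaxes "every landmark" to "at least half", and always
selects a subset of the conservative rule on the same data (tested). Among
qualifying candidates the one whose most significant p-value is least
significant is removed. Selection runs once on the full training split by
default (mirroring a single reported predictor set); per-fold selection is
available for stricter cross-validation. The default selection landmarks
are the coarse set {6, 12, 24, 36, 48, 60} to bound cost.

Two robustness guards apply before any Cox fit: binary features with a
zero-event level for either cause are dropped (they have no finite
estimate), and of any feature pair with $|r| > 0.95$ only the earlier-listed
one is kept. The latter matters at $s = 6$, where the recurrent-event
window $(s-12,s]$ nests the first-six-months history flags. Donor
cause-of-death indicators are excluded from the default candidate list
because they are nearly aliased with living-donor status plus KDPI.

## Accuracy assessment

Censoring is handled by inverse-probability-of-censoring weights computed
within the at-risk set at each landmark: $\hat G$ is the Kaplan–Meier of
the censoring distribution on residual time; subjects with an event at
$T \le \Delta$ weigh $1/\hat G(T-)$, subjects event-free at $\Delta$ weigh
$1/\hat G(\Delta)$, subjects censored earlier weigh 0. A landmark-local
$\hat G$ matches the conditional framing of landmarking. For the cause-$k$
AUC, cases are subjects with a cause-$k$ event by the horizon and controls
are the event-free *plus competing-cause* subjects (they verifiably lack the
index event); the AUC is the weighted Mann–Whitney statistic with ties
counted one half, verified against an $O(n^2)$ pair loop to 1e-12. The
Brier score is the weighted squared error of the predicted incidence
against the 0/1 outcome indicator. eGFR accuracy uses the observed
measurement closest to $s+\Delta$ within ±2 months (ties earlier):
RMSE, and P30/P50, the fractions of predictions within 30%/50% of the
observed value.

Cross-validation splits subjects (not rows) into 3 folds, fits everything —
including imputation values and the volatility fallback, which are frozen
on the training folds — on 2 folds and evaluates on the third, then
averages over folds and over 5 repeated splits. The bootstrap comparison
resamples training *subjects* with replacement (percentile intervals,
B = 500 at full scale), refits both models per resample and recomputes the
metric difference on the fixed test set; an interval excluding zero flags a
validated difference. No multiplicity adjustment is applied across
landmarks.

## The synthetic cohort

Real transplant-registry data are access-restricted, so the package ships a
generator whose defaults emulate the published cohort margins: n = 3,893;
recipient age 51.1 (SD 12.9); 39.4% female; 39.2% living donors; baseline
eGFR 55.6 (SD 18.6); outcome mix near 13.7% graft failure / 19.9% death
with functioning graft at an administrative cap of 126 months with
exponential dropout (0.005/month). Latent eGFR trajectories are linear with
subject-specific intercept and slope and measurement error
$\sigma_\varepsilon = 9$ mL/min/1.73m² — chosen so the best achievable
prediction RMSE sits near the 11–16 band that measurement error alone
implies; visits follow a Poisson process (0.9/month). Hospitalization and
rejection are homogeneous Poisson processes sharing a log-normal frailty
with the event hazards, which reproduces the rising hospitalization
fraction among survivors through selection. Event times come from two
Weibull cause-specific hazards multiplied by covariate, current-eGFR and
recent-event-count effects, sampled by inversion on a piecewise-constant
0.25-month grid — with constant covariates the discretization preserves
proportional hazards exactly, and the sampler is checked against
closed-form inversion by Kolmogorov–Smirnov tests across seeds.

What the generator deliberately does **not** emulate: nonlinear individual
eGFR trajectories, the registry's highly variable visit schedules (1–567
measurements per subject), informative visit timing, and time-varying
baseline labs. Passing tests on this synthetic cohort therefore demonstrate
the *estimators* are correct and the *pipeline* behaves as designed, not
that real-data accuracy will match the synthetic numbers.

Presets: `wisard_like` (defaults above), `null_covariates` (all effects
zero — the analytic-oracle case), `time_varying_effect` (the current-eGFR
effect on graft failure strengthens with time since baseline, making
dynamic updating genuinely better than a static model), and `no_censoring`.

## Numerical and design choices

- **Ties**: Breslow (matching the Breslow baseline); Efron optional.
- **Newton convergence**: partial-likelihood tolerance 1e-10, max 100
  iterations; GEE coefficient-change tolerance 1e-8, max 50 iterations.
- **Separation**: any fitted |coefficient| > 15 aborts the fit with the
  offending features named.
- **Sparse landmarks**: fewer than 10 events of either cause (configurable)
  at a landmark triggers fallback to the nearest earlier landmark's fit,
  with a warning.
- **Imputation**: single-value (mean for symmetric continuous labs, median
  for skewed counts, mode for categoricals — configurable), fitted on
  training subjects only and frozen for held-out folds.
- **Missing current eGFR** at a landmark drops the subject from that
  landmark with a logged count.
- **Degenerate inputs**: empty eGFR series pass through thinning unchanged;
  a null (covariate-free) cause-specific fit returns Nelson–Aalen baselines
  and Aalen–Johansen incidences.

Validation experiments in the test suite and the acceptance script use
deliberately scaled problem sizes — e.g. recovery over 20 cohorts of
n = 2,000; the RMSE-floor check at n = 5,000; five seeded cross-validation
runs at n = 1,200 with landmarks {6, 12, 24, 36, 48}; fifty bootstrap
null-coverage runs at n = 400 with B = 100 — sizes at which the checked
properties are statistically decidable while the whole suite stays
convenient to run. The parameter-recovery experiments fit the cause-specific
models on the *latent* generative covariates recorded by the simulator
(flat trajectories, frailty off) so that the fitted model is exactly the
generative one; fitting on noise-contaminated measured features would test
errors-in-variables attenuation rather than the estimator. Two experiment
scenarios raise the Weibull baseline scales so that modest cohorts contain
enough events for the checks to be well-posed.

## Known limitations

- Per-landmark refitting is statistically inefficient relative to a
  landmark supermodel, and the landmark GEE does not learn from each
  subject's full eGFR trajectory (no subject-specific random effects).
- The SPM eGFR comparator is an unconditional marginal mean.
- Single-value imputation understates covariate uncertainty; multiple
  imputation is out of scope.
- Internal (cross-validated) accuracy only; external validation tooling is
  out of scope, as are Fine–Gray subdistribution models, within-landmark
  time-varying coefficients, and frailty terms in the fitted models.
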