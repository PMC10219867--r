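---
title: "Methods: hourly ED crowding early warning with Holt-Winters models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hourly ED crowding early warning with Holt-Winters models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcast)
```

## The problem

Emergency department (ED) crowding is usually studied through continuous
forecast errors, but the operational question an administrator faces is
binary: *will the department be crowded, and how far ahead can we know?*
`edcast` frames hourly ED forecasting as a binary early-warning problem:
point forecasts of arrivals and occupancy feed a categorical crowding
definition, and performance is reported as the discrimination (AUC) of
those forecasts at every horizon and from every time of day.

## Forecasting models

Three seasonal Holt-Winters exponential-smoothing models are provided,
chosen for robustness and very low computational cost — properties that
matter when a model is refit every hour against a live hospital feed:

* **AHWM** — additive trend, additive seasonality;
* **MHWM** — additive trend, multiplicative seasonality;
* **HWDM** — damped additive trend, additive seasonality.

Each maintains a level $\ell_t$, trend $b_t$, and $m$ seasonal indices
$s_t$. For the additive model,

$$
\begin{aligned}
\ell_t &= \alpha\,(y_t - s_{t-m}) + (1-\alpha)(\ell_{t-1} + b_{t-1}),\\
b_t    &= \beta\,(\ell_t - \ell_{t-1}) + (1-\beta)\,b_{t-1},\\
s_t    &= \gamma\,(y_t - \ell_{t-1} - b_{t-1}) + (1-\gamma)\,s_{t-m},\\
\hat y_{t+k} &= \ell_t + k\,b_t + s_{t+k-m}.
\end{aligned}
$$

The multiplicative variant replaces the seasonal differences by ratios
($y_t/s_{t-m}$ in the level update, $y_t/(\ell_{t-1}+b_{t-1})$ in the
seasonal update, $(\ell_t + k b_t)\,s$ in the forecast); the damped
variant multiplies every appearance of $b_{t-1}$ by $\phi$ and forecasts
with $\sum_{i=1}^k \phi^i\,b_t$, which bounds long-horizon forecasts at
$\ell + b\,\phi/(1-\phi) + s$. The recursions run in compiled C++; an
independent plain-R transcription of the same equations arbitrates them
in the test suite to $10^{-8}$.

**Seasonal period.** $m = 24$ encodes the diurnal cycle, by far the
dominant seasonality in hourly ED data. Weekly seasonality ($m = 168$)
is not modelled: a single-seasonality Holt-Winters model cannot carry
both cycles, and the crowding signal of interest is intraday. This is a
deliberate scope decision, not a claim that weekday effects are absent
in real departments.

**Seasonal type of the damped model.** HWDM uses additive seasonality,
for symmetry with AHWM: damping addresses trend extrapolation, which is
orthogonal to how the seasonal term enters.

**Estimation.** Smoothing weights maximise the Gaussian one-step
likelihood, equivalently minimise the one-step squared-residual sum,
with $\alpha,\beta,\gamma \in [0,1]$ and $\phi \in [0.8, 0.98]$.
Optimisation is L-BFGS-B from a fixed grid of six starting points
spanning the box; a fixed grid gives bit-reproducible fits without any
seed plumbing. Initial states come from a heuristic seasonal-average
scheme (level = first-season mean; trend = difference of the first two
seasonal means per step; seasonal indices = average per-position
deviations, normalised to sum 0 or average 1). For training series of
months of hourly data the influence of the initial states is negligible
compared with state-of-the-art initial-state MLE, and the heuristic
keeps hourly refits cheap and deterministic.

**Counts, zeros, and flooring.** Overnight arrival counts of zero are
incompatible with multiplicative seasonality, so multiplicative fits on
series containing zeros add an offset of 0.5 to the training values and
remove it after forecasting. All forecasts are floored at 0 but *not*
rounded to integers: the evaluation uses forecasts as continuous scores,
and rounding would manufacture ties in the AUC.

## The crowding definition

The operational target is *mortality-associated* crowding, defined
categorically: compute each calendar day's peak occupancy (DPO), take
the nearest-rank 75th percentile of the DPO distribution over complete
days as the threshold $\theta$, and call an hour crowded when occupancy
$\ge \theta$. A 24-hour forecast window is crowded when one or more of
its hours is. Design details:

* **Nearest-rank percentile**, not interpolation: the threshold is then
  an observed occupancy value (an order statistic), which matches how an
  integer census threshold is used operationally.
* **"Reaches" ($\ge$)** rather than "exceeds" ($>$): the inclusive
  comparison is the operative wording of the evaluation phase.
* **Calendar-day boundary (00:00–23:00 UTC in the synthetic data).**
  Crowding concentrates in the afternoon and evening, far from the
  boundary, so the choice of day boundary is immaterial in practice.
* **One threshold for the whole evaluation period.** A rolling threshold
  would entangle the definition of the target with the evaluation; it is
  out of scope.
* **Missing hours.** Days with fewer than 24 observed hours are excluded
  from threshold estimation (their maximum may be understated). Windows
  containing missing hourly labels are labelled crowded if any observed
  hour is crowded, and *missing* otherwise — never "not crowded" — so
  downtime cannot create false negatives.

## The prospective harness

`run_prospective()` emulates deployment: at each hourly origin, each
model is trained on all history strictly up to the origin and issues 24
hourly point forecasts, persisted in an append-only store keyed by
(origin, model, target, horizon). Three design choices matter:

* **Refit stride.** The deployed pattern is a full refit every hour; the
  harness makes the stride configurable. Between full refits the
  smoothing *states* are still advanced with every new observation using
  the last fitted parameters, so forecasts always originate from the
  most recent state; only the parameter re-estimation is amortised.
  Desk-scale runs in this package use a stride of 24 h, which changes
  parameters at most once a day while preserving hourly responsiveness.
* **Warm-up.** The first 14 days are never used as origins — two full
  seasonal cycles are required for initialisation, and 14 days adds
  margin so early origins are not dominated by initialisation error.
* **Gap policy.** Training series are regularised before fitting: runs
  of up to 6 missing hours are linearly interpolated (keeping seasonal
  alignment intact), while longer outages truncate training to the
  longest contiguous trailing run. Origins whose own hour is unobserved
  are skipped with a reason code, mirroring how a live system simply
  fails to predict during downtime; skips are logged, never fatal.

The no-lookahead contract — no record ever depends on data after its
origin — is tested by corrupting post-origin values and asserting
byte-identical forecasts.

## Evaluation design

All binary metrics are built from (score, label) pairs.

* **AUC** is the midrank Mann-Whitney statistic,
  $P(\text{score}_+ > \text{score}_-) + \tfrac12 P(\text{tie})$,
  computed exactly from ranks. Single-class pair sets yield a *missing*
  AUC — never 0 or 0.5 — which is how undefined cells of the
  origin-by-horizon matrix are represented.
* **Class balance.** Crowded hours are rare (a few percent), so
  noncrowded pairs are downsampled without replacement to match the
  crowded count before AUC computation. The default is a single seeded
  draw; a `draws` argument averages the point estimate over several
  draws when draw noise matters. In the degenerate case of more crowded
  than noncrowded pairs the positives are downsampled instead, with a
  warning.
* **Bootstrap CIs.** Percentile intervals from 250 joint (score, label)
  resamples; resamples that lose a class are redrawn. The bootstrap is
  non-stratified, matching the simplest defensible reading of a
  pairs bootstrap.
* **PPH** pairs the forecast for hour $t+h$ with the crowding label of
  that hour, per horizon. **PPO** collapses each origin's 24 forecasts
  into a window score; the score is the *maximum* of the 24 point
  forecasts — the natural predicted analogue of daily peak occupancy —
  and the label is the window label above. **The AUC matrix** evaluates
  raw restricted (origin-hour, horizon) pair sets without downsampling;
  cells are small and the matrix is descriptive, so a sampling step
  would only add noise.
* **Threshold metrics.** Sensitivity, specificity, precision and F1 are
  reported at the unadjusted threshold "predicted occupancy $\ge
  \theta$" — the most literal decision rule; adjusting the threshold to
  a facility's sensitivity/specificity preferences is an operational
  decision left to the user.
* **No multiplicity adjustment** is applied across horizons or origins;
  the per-stratum CIs are descriptive.
* MAE, MSE and RMSE are all reported (RMSE $\ge$ MAE is asserted in the
  test suite as a standing sanity check on the error aggregation).

## The synthetic ED generator

Hospital census data cannot be shipped, so the package includes a
mechanistic generator whose *structure* — not merely its marginal
distributions — matches what large combined EDs report:

* **Arrivals**: a nonhomogeneous Poisson process with a 24-point diurnal
  intensity, anchored at ≈2 patients/h at 05:00–07:00 rising to a peak
  of 13 at 16:00.
* **Day surges**: each day draws one log-normal multiplier (mean 1,
  log-sd 0.15) applied to the intensities of hours 12:00–23:00,
  independently across days. This creates the day-to-day DPO variability
  that makes the top-quartile crowding definition non-degenerate, and it
  gives intraday information accrual a realistic mechanism: morning
  occupancy partially reveals the day's surge through stay carry-over.
* **Occupancy**: an infinite-server queue. Every arrival draws a
  uniform within-hour offset and a log-normal length of stay (median
  5 h, log-sd 0.8, capped at 48 h); occupancy at the top of each hour
  counts patients present. Occupancy is therefore *derived from*
  arrivals, so the two targets are mutually consistent and the
  occupancy peak lags the arrival peak naturally.

The defaults were calibrated once, before any evaluation run, against
the reference anchors (arrival trough/peak of 2/13; occupancy ≈23 at
06–08 h and ≈74 at 17–18 h; ≈3% of hours crowded, all after midday)
using the expected-occupancy convolution
$E[\mathrm{occ}(T)] = \sum_{j\ge1} \lambda(T-j)\,S(j-\tfrac12)$
and a one-year simulation; `scripts/calibrate_generator.R` re-derives
and reports these checks so the numbers are auditable rather than magic.
The surge dispersion 0.15 was selected from a coarse grid as the value
meeting the crowded-fraction anchor while keeping every crowded hour in
the afternoon/evening; larger values leak crowding into overnight
carry-over hours.

**The midnight no-skill property.** Because surges are i.i.d. across
days and touch only hours from noon onward, the history available at
midnight carries essentially no information about the coming day's
surge: direct measurement on long simulations (the latent day effect of
the previous day, or any pre-midnight occupancy summary, scored against
the next window label) gives AUC ≈ 0.50. The per-origin AUC of any
honest forecaster at origin 00:00 is therefore pinned to chance by
construction, while origins later in the day see progressively more of
the realised surge — the structural signature the evaluation framework
is designed to expose.

**What the generator does not emulate.** Weekday/weekend and holiday
effects, seasonal (annual) trends, autocorrelated multi-day surges
(e.g. influenza waves), capacity feedback (access block lengthening
stays when the department is full), and heterogeneous patient streams.
Passing the acceptance checks on this generator demonstrates that the
pipeline's mechanics and the evaluation's structural claims are correct;
it does not certify forecast accuracy on any real department.

## Problem sizes and numerical tolerances

The test suite exercises a 234-day prospective study (14-day warm-up,
daily refits, additive model) shared by the per-origin and per-horizon
checks, and smaller runs elsewhere; these sizes were chosen so the whole
suite completes in about a minute on a laptop while keeping ≥150
crowding events in the strata under test. The acceptance script
averages five independent 364-day replicate studies (350 evaluation
days each, ~0.016 standard error on the midnight PPO AUC). Oracle
equivalence of the smoothing recursions is asserted at $10^{-8}$;
parameter recovery at $n = 3000$ within $\pm 0.15$; the M/G/$\infty$
stationary mean within $\pm 3$ patients of $\lambda\,E[\mathrm{LOS}] =
50$.

## Known limitations

* Single-seasonality models: no weekly cycle, no exogenous covariates
  (weather, calendar, downstream bed availability).
* Point forecasts only; no prediction intervals or densities.
* The crowding threshold is estimated once on the full period, so very
  long deployments with census drift would need re-estimation policy.
* The multiplicative offset policy (add 0.5, subtract, floor) is a
  pragmatic fix for zero counts, not a count-data likelihood.
* PPO's window score is fixed to the maximum of the 24 forecasts; other
  scores (e.g. the forecast at a fixed afternoon hour) are plausible and
  can be computed from the same aligned rows.
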