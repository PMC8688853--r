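---
title: "Digital biomarkers of sobriety and compliance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital biomarkers of sobriety and compliance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Patients monitored for alcohol use disorder perform 2-5 scheduled
breathalyzer tests per day through a mobile device. Two signals carry
information about drinking: the breath alcohol readings themselves, and the
pattern of *omitted* scheduled tests, because poor compliance correlates
strongly with drinking. `amirei` turns these signals into a continuous
description of the clinical course — a level, a trend, and discrete
exacerbation events — replacing the binary sober/relapse construct with
quantities that can be tracked daily.

```{r, eval = FALSE}
library(amirei)
coh <- simulate_cohort(10, c(weekend_binger = 1), seed = 1, n_days = 180)
bundle <- run_pipeline(coh$tests, truth_covariates(coh$truth))
bundle$summary
```

## From scheduled tests to a daily raw score

Each scheduled test is scored on $[0, 1]$:

* performed with BAC $< \theta$: score 1 (sober). BAC is approximated as
  $2.0 \times$ BrAC; the default threshold $\theta = 0.05$ permille is backed
  by a level-of-quantification argument: over a large corpus of sober
  readings, median $+\,10\cdot\mathrm{IQR} = 0.006 + 10 \cdot 0.004 = 0.046$
  permille, so 0.05 permille separates quantifiable drinking from sensor
  noise.
* performed with BAC $\ge \theta$: score 0 (drinking detected).
* omitted: an imputed score that is lowered for each consecutive omitted
  test. With streak length $k$ (spanning day boundaries, reset by any
  performed test) the score is $\max(0, 1 - (k/K)^\gamma)$, where
  $K$ is the number of scheduled tests in the 48-hour omission horizon
  (i.e. twice the daily schedule). After 48 hours of silence an omission
  therefore carries exactly the weight of a positive test; before that, a
  positive test is penalized more than a missed one, which is the intended
  asymmetry: verified drinking is worse news than a missed test.

The decay *shape* between those two endpoints is not identifiable from the
published description, only its endpoints are. We default to linear
($\gamma = 1$), the minimal shape consistent with "lowered for each
consecutive omitted test" and the 48-hour endpoint; `decay_exponent` in
`ami_params()` exposes the family $\gamma > 0$ for sensitivity analysis.
All choices keep the endpoint fixed.

The day's raw value is $x_t = 100 \times$ the mean of its per-test scores.
The mean (rather than the sum) keeps days with different scheduled counts
comparable. Whole days with no scheduled windows between a patient's first
and last monitored day are expanded to all-omitted days, so the indices
decay during device silence rather than skipping it.

## The smoothed index family

The Addiction Monitoring Index is exponential smoothing of $x_t$:

$$s_0 = x_0, \qquad s_t = \alpha x_t + (1 - \alpha)\, s_{t-1},$$

with $\alpha \in (0, 1]$ the weight of the present day against history.
`AMI-N` denotes $\alpha = N/100$: AMI-6 is a slow baseline, AMI-45 a fast
tracker, AMI-21 the original therapist-facing compromise. There is no
burn-in: series start at $s_0 = x_0$. The recursion is evaluated with
`stats::filter(..., method = "recursive")`; the test suite verifies it
against the closed form
$s_t = (1-\alpha)^t x_0 + \alpha \sum_{k=0}^{t-1} (1-\alpha)^k x_{t-k}$
to $10^{-9}$ on a thousand random series up to length 400.

## Trend: the REI, and exacerbation events

The Recovery and Exacerbation Index is the ratio of the fast to the slow
index, $\mathrm{REI}_t = s^{(0.45)}_t / s^{(0.06)}_t$ — the short-term
perspective relative to the long-term one, independent of the absolute
level (the ratio is invariant to rescaling all $x_t$, which the tests
assert to $10^{-9}$). Since smoothing weights are positive, the denominator
can only vanish when the whole history is zero; that $0/0$ case is defined
as 1 ("no trend"). The ratio is capped at 10: after a deep dive followed by
rapid recovery it climbs far above 1, and the cap stabilizes plots and
scans without touching event detection, which only reads values below the
threshold.

An exacerbation event (EE) is a maximal run of consecutive days with
$\mathrm{REI}_t < 0.8$. The inequality is strict — a day exactly at the
threshold is out — which follows the "< 0.8" formulation; this matters only
on exact ties, which real-valued indices essentially never produce. Events
carry their length and the distance from the previous event's end to their
own start; the first event's distance is undefined and excluded from means
rather than measured from treatment start. Per-patient summaries report
%EE (percentage of monitored days inside events), event count, mean/max
length, mean distance, and AMI-21/MTBT/DDD/PEth means.

### Maximum time between tests

MTBT tracks compliance: for each calendar day, the longest interval between
consecutive performed tests among all intervals intersecting that day. A
day inside a multi-day gap carries the full gap length, so MTBT exceeds
24 h during omission streaks — patient-level means of a week or more are
meaningful for poorly compliant patients, which a within-day-only reading
could never produce. Intervals to the monitoring boundaries are not
counted (no penalty for enrollment day); days intersected by no interval
report `NA`, and a patient with zero performed tests reports the full
monitored span, flagged.

## Choosing the threshold: the ANOVA scan

`scan_thresholds()` reproduces the quantitative threshold-selection
procedure: on days with a drinks-per-drinking-day (DDD) observation, each
candidate threshold $\tau$ in a 17-point grid over $[0.05, 1.1]$ splits the
days into in-EE and out-of-EE bins, and the bins are compared by the ANOVA
F-ratio of DDD — one-way, and two-way with patient as a fixed (categorical)
factor. The grid spacing is equal (the published account fixes the range
and the count, not the spacing). Thresholds for which a bin is empty report
`NA` rather than erroring. `select_threshold()` returns the argmax
(patient-adjusted model preferred, ties toward the lower threshold)
together with the range of thresholds reaching 80% of the peak F, the
"plateau" a practitioner would inspect. On drinking-driven data the curve
is low at both extremes and peaks in the interior.

Two caveats are deliberate. First, whether DDD = 0 days count as
observations is a configuration option (`include_zero_ddd`, default
`TRUE`). Second, maximizing F over a grid is a selection procedure without
multiplicity control; the test suite includes a null simulation showing
that the best-threshold p-value rejects well above the nominal 5% level, so
the scan should be read as descriptive, not inferential.

## Periodicity with repeated measures

`cohort_day_table()` attaches to every patient-day its event indicator,
weekday, ISO-8601 week number, and a 30-day treatment bin (13 bins cover
days 0-389; the width is configurable). `percent_ee_by()` reports %EE per
level with a day-level Wald interval, which is a *visualization* aid — the
days of one patient are strongly serially dependent, so inference comes
from `cluster_logistic_test()`: a logistic model `in_ee ~ factor` with a
patient-clustered sandwich covariance and a joint Wald test of the factor.

"Repeated measures by patient" pins down neither the estimator nor the
reference distribution, so we use the standard small-cluster practice: a
$G/(G-1)$ (CR1) adjustment of the sandwich and an $F(q, G-1)$ reference,
$G$ the number of patients and $q$ the tested coefficients. With few
clusters the sandwich is rank-deficient; the joint test inverts it on its
positive eigenspace and reports the reduced rank as $q$. Levels with no
outcome variation cannot enter a logistic fit and are dropped from the
joint test with a warning. `vcov_type = "CR0"` gives the unadjusted
sandwich, under which (for a saturated one-factor model with one day per
patient) robust and model-based covariances coincide — a property the test
suite checks to $10^{-6}$. A GEE with exchangeable working correlation
would be an equally defensible realization; the sandwich route was chosen
because it makes the independence-case equivalence exact and keeps the fit
a plain `glm`.

Under the null (no weekday effect, 30 patients, 120 days, 100 replicates)
the joint test's empirical size sits inside 5% ± 3%; with a weekend odds
ratio of 4 injected (50 patients, 180 days) it rejects in effectively every
replicate and weekend %EE exceeds midweek %EE in all of them. These sizes
are the package's standing validation conditions, chosen to make each
Monte Carlo decisive yet quick.

## What the simulator emulates — and what it does not

`simulate_patient()` draws a daily drinking indicator from
$P(\text{drink}_t) = \mathrm{logit}^{-1}(\beta_0 + w_{d(t)} + v_{k(t)} +
r(t) + z_t)$: a base propensity, additive weekday and ISO-week effects, a
piecewise-linear treatment-time ramp (rising over the first ~3 months, then
easing), and a latent AR(1) state $z_t$ with persistence $\rho$ and
stationary standard deviation `episode_sd`, which produces multi-day to
month-long episodes as $\rho \to 1$. Drinking days draw a lognormal DDD,
place an above-threshold BAC at the last test window (and, with probability
0.5, at other windows in the later half of the day), and raise the
per-test omission probability — encoding the observation that events are
often triggered by compliance collapse rather than positive tests. Sober
readings are half-normal with a BAC-equivalent median near 0.006 permille,
matching the sober-noise statistics behind the LOQ argument. A pseudo-PEth
is a trailing 21-day mean of true daily drinks times a calibration constant
plus noise — the right time-scale and ordering, not a pharmacokinetic
model. DDD is recorded only on days with at least one performed test (the
value on drinking days, 0 on sober days), tying self-report availability to
engagement.

Five presets (`abstinent`, `controlled`, `weekend_binger`,
`periodic_heavy`, `chaotic`) span the patient phenotypes the indices must
distinguish. Cohort seeds derive from the master seed by
`(seed + 48271 * i) mod (2^31 - 1)`, so patient `i` is reproducible without
regenerating the cohort.

The simulator does **not** model within-day pharmacokinetics (it places
threshold-crossing values directly at windows, sufficient for an algorithm
that consumes per-test outcomes), identity fraud, device failure, schedule
changes mid-treatment, or informative dropout. Passing tests on simulated
cohorts therefore demonstrate algorithmic correctness and statistical
calibration under a plausible generative model — not clinical validity on
real patients, whose omission behavior need not follow any smooth
probability model.

## Numerical and degenerate-input choices

* Timestamps are naive local times handled in a fixed zone; day boundaries
  are patient-local calendar dates, ranges half-open, `treatment_day`
  0-based.
* A performed-test gap ending exactly at midnight does not reach into the
  next day.
* `rle` drives segmentation; an independent flag-and-group oracle checks it
  on a thousand random series.
* The scan's patient-adjusted F uses sequential ANOVA with the bin term
  last, which equals its added-last F in the two-way layout used here.
* Validation failures raise a dedicated condition class
  (`amirei_validation_error`), which the command-line wrapper maps to exit
  code 1 (internal faults map to 2).

## Limitations

The omission-imputation shape and the production system's exact imputation
table are not public; this implementation fixes only the endpoints that are
and documents the shape as configurable. %EE denominators include all
monitored days from the first scheduled window onward. The threshold scan
is descriptive. Cluster-robust logistic inference assumes enough clusters
for the sandwich to be stable — below ~20 patients, treat the joint test
with caution (the reduced-rank fallback keeps it defined, not well
calibrated).
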