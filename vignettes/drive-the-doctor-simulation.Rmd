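---
title: "Simulating drive-the-doctor stroke services: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating drive-the-doctor stroke services: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(strokesim)
```

## What is being modelled

`strokesim` is a per-patient Monte Carlo model of acute stroke services in a
rural region with one comprehensive stroke center (CSC) and eight primary
stroke centers (PSCs).  The cohort is restricted to large-vessel-occlusion
(LVO) patients who ultimately receive endovascular thrombectomy (EVT) and
who satisfy the usual registry inclusion rules (pre-stroke mRS of at most
2).  Two organizational models are compared:

* **Drip-and-ship (baseline)** — the patient reaches the nearest PSC,
  receives thrombolysis, is diagnosed by CT angiography, and is transferred
  to the CSC for EVT.  The onset-to-groin-puncture time (OTG) is the sum of
  thirteen interval times: onset to 911 call, EMS response, on-scene time,
  transport, door-to-CT, CT-to-thrombolysis, thrombolysis-to-CTA, the
  transfer call, EMS return, departure, inter-hospital transport, arrival
  to angiography suite, and suite to groin puncture.
* **Drive-the-doctor (DD)** — selected PSCs are upgraded to
  thrombectomy-capable centers (TSCs) and a mobile interventionalist (MI)
  travels from the CSC to the patient's TSC.  The patient's path and the
  MI's path run in parallel and synchronize at the angiography suite:
  whoever arrives first waits, and the procedure starts after the
  angio-to-groin interval from the moment both are present.

This is a *pathway* model, not a capacity model: one MI, one patient at a
time, no queueing, no diurnal arrival process, no interaction between
concurrent cases.  Stroke mimics, hemorrhages and IVT-only patients are out
of scope; consequences of that restriction are discussed under
*Limitations*.

## Interval-time distributions

Every pathway step is described by a `dist_spec`: a parametric family
(lognormal, gamma, Weibull, exponential, triangular, uniform, point mass or
empirical), an optional location shift, and optional truncation.  Service
times in this setting are positive and right-skewed, which is why the
default fitting set is lognormal/gamma/Weibull/exponential.  `fit_spec()`
fits each candidate family by maximum likelihood (delegating the per-family
optimization to `fitdistrplus`), selects by log-likelihood and reports a
Kolmogorov–Smirnov statistic; missing values are dropped before fitting.
Published summaries of the form *median (IQR)* are turned into specs by
`spec_from_median_iqr()`, which matches all three quantiles — using the
shift as a third free parameter, the lognormal case is solved exactly in
closed form, and gamma/Weibull numerically; fits with quantile residuals
above 1% are rejected rather than returned silently.

Sampling is inverse-CDF based under truncation, so truncated draws can
never escape their range, and all sampling uses the R random stream so a
single `set.seed()` reproduces everything.

## The synthetic region and cohort

The real inputs of such a study — registry interval times, EMS records,
route-planner travel times — are not shippable, so the package generates a
synthetic stand-in that carries the same statistical structure.  Everything
below is a *declared fixture*, chosen once for plausibility:

* **Region** (`make_default_region()`): one CSC and eight PSCs at 6–84 km,
  placed deterministically on a plane.  Travel times are straight-line
  distance divided by a per-modality speed: car 80 km/h, ground EMS 90
  km/h, helicopter 220 km/h.  Straight-line geometry guarantees the
  triangle inequality, which is what makes the monotonicity properties of
  the scenario grid provable.  The helicopter carries a fixed 24-minute
  overhead (fire-safety team on the helipad, 20 min, plus MI pick-up,
  4 min) and fails for weather 15% of the time, falling back to ground
  EMS.  The ground-EMS response spec reproduces a median (IQR) of
  9 (7–12) minutes exactly.
* **Interval calibration** (`default_intervals()`): lognormal steps whose
  means are plausible round figures summing to 241 minutes for the
  drip-and-ship chain — the OTG level reported for comparable drip-and-ship
  cohorts.  Only that total is calibrated; the individual step means are
  not fitted values.
* **Cohort** (`generate_cohort()`): age from a truncated normal
  (70 ± 12, 18–100), NIHSS from a discretized gamma (mean 16) clamped to
  0–42, collateral grades with probabilities (0.05, 0.30, 0.40, 0.25),
  pre-stroke mRS capped at 2 by construction, and a RACE screen that
  misses LVO with probability 0.05 (the 95% negative predictive value
  reported for prehospital triage scales).
* **Origins** are abstract rather than geographic: each patient gets a
  catchment PSC, and the drawn scene-to-hospital interval doubles as the
  travel leg to that catchment; travel to any other hospital is that leg
  plus the inter-hospital time.  Catchment weights give the three
  upgraded PSCs a combined 45% share — the fraction of patients whose
  nearest facility is thrombectomy-capable — so the share is set by
  construction, matching the regional figure, instead of emerging from an
  invented map.  Real catchment geometry is *not* emulated; what passing
  tests show is that the engine handles the stated routing fractions
  correctly, not that any particular map would produce them.
* **Upgrade set** (`default_tsc_ids()`): the three PSCs most distant from
  the CSC.  Which PSCs to upgrade is a genuine open design choice in any
  region; distance was chosen because remote PSCs gain most from avoiding
  the transfer, and the set is a plain argument everywhere.

## Routing, notification and the MI's path

Two routing strategies are implemented in `route_patient()`.  Under
`nearest_ivt` (current guidelines) the patient goes to the nearest
IVT-capable hospital and, if it cannot perform EVT, follows the combined
drip-and-ship/drive-the-doctor class: a secondary transfer to the nearest
TSC — deliberately the nearest TSC, never the CSC.  Under `race`, patients
whose nearest facility is already EVT-capable go there irrespective of the
screen; the rest go to the nearest EVT-capable center if RACE-positive and
to the nearest PSC if (falsely) RACE-negative.  With a 45% nearest-TSC
share and a 5% false-negative rate, the expected drip-and-ship/DD share is
0.55 × 0.05 ≈ 3%.

The MI is notified either at the CTA (LVO confirmation) or on scene by a
positive RACE screen; a false-negative screen falls back to notification
after CTA.  Preparation to leave takes 10 minutes when the MI reviews the
CTA by telemedicine (the default: `telemedicine_prob = 1`) and 5 minutes
otherwise — the two endpoints are modelled as a discrete choice, not a
uniform draw, because they correspond to a configuration decision rather
than noise.  Preparation runs in parallel with the transport response, so
`depart = notify + max(prep, response)`.  On arrival, reaching the suite
takes the hospital's `angio_transfer_minutes` (5 or 10, depending on where
the landing area is).

Ties in nearest-facility searches are broken by lexicographic hospital id,
so every routing decision is deterministic under a fixed seed.

## Outcome model

The 7-level modified Rankin Scale at 90 days follows a cumulative-logit
(proportional-odds) model, `P(mRS <= j) = plogis(alpha_{j+1} - x*beta)`,
with OTG (minutes), age, NIHSS and the 4-category collateral grade as
prognostic variables.  The sign convention is stated prominently because
formulas of this shape are often published without one: *positive slopes
are harmful*.  The predicted probability of favorable outcome (PPFO) is
`P(mRS <= 2)`.  `fit_ordinal()` wraps `MASS::polr`, which uses the same
parameterization, and refuses to return silently on degenerate or
separated data.  The shipped `default_coefficients()` are a labelled
non-fitted fixture (0.004 per-minute harm from delay, plausible magnitudes
elsewhere, cut points placing a typical cohort near 50% PPFO); a scale
factor (`otg_scale`) accommodates coefficients fitted on hours instead of
minutes.  Proportional odds is taken as given; no relaxation is offered.

## Common random numbers and the scenario grid

All stochastic quantities a scenario could need are drawn *once per
patient* by `generate_cohort()`: every interval, the EVT-preparation draw,
the MI's ground-EMS response draw, and the uniforms deciding helicopter
weather and telemedicine use.  A scenario run is then a deterministic
function of the cohort, so between-scenario contrasts in
`run_scenario_grid()` are common-random-number contrasts — the standard
variance-reduction choice for design comparisons, and the reason the grid
satisfies exact monotonicity: with draws held fixed, earlier notification,
a uniformly faster travel table, a larger upgrade set, and RACE routing
each weakly reduce OTG (the first per patient, the others in the mean).

Aggregation reports the mean OTG and mean PPFO with normal-approximation
95% confidence intervals of the Monte Carlo mean (no significance testing
between scenarios — these are simulated contrasts, not experiments).
Waiting times are reported as *conditional* means over the cases in which
that party actually waits, paired with the percentage of such cases; exact
ties (both waits zero) count in neither percentage, so MI-share +
patient-share + tie-share is exactly 100%.  Simulated OTG is never capped:
the 390-minute rule in registry studies is an input-data exclusion, so the
fraction of simulated patients above 390 minutes is reported as a
diagnostic instead.

The preparation interval at the TSC (CTA to angiography-suite readiness)
has no observable real-world counterpart, which is why it gets a dedicated
sensitivity analysis: `sensitivity_analysis()` rescales the draw by 0.75
and 1.25 (25% shorter or longer).  The default mean is 60 minutes, so "25%
shorter" equals 45 minutes; the published description of this benchmark is
ambiguous between 60 and 45 as the reference mean, and both readings are
expressible by editing the `cta_to_angio_at_tsc` spec in the configuration.
Note the max-operator consequence, which the tests pin down exactly: when
the patient is waiting for the MI, shortening preparation changes nothing;
when preparation is on the critical path, the full 15 minutes appear in
the OTG.

## Numerical and testing choices

* Problem sizes: the shipped analysis uses 100,000 patients per scenario
  (the full grid runs in seconds because the engine is vectorized); unit
  tests use 2,000–5,000 patients with correspondingly widened Monte Carlo
  tolerances, and statistical checks are phrased in standard errors
  wherever possible.
* The per-patient operations (`simulate_ds_baseline()`,
  `simulate_dd_patient()`, `simulate_mi_path()`, `synchronize()`) and the
  vectorized engine (`simulate_cohort()`) implement the same arithmetic
  twice; the test suite pins them together to machine precision on shared
  cohorts, and pins both against hand-computed point-mass event chains.
* Parameter-recovery tolerances follow the information content of the
  design: continuous slopes of the outcome model are recoverable to 10% at
  n = 5,000, while the smallest collateral contrast (|beta| = 0.6) has a
  sampling SE near 12% of its own size at that n, so it is held to the
  same 10% at n = 50,000 instead.
* Degenerate inputs fail loudly at construction time: unordered cut
  points, truncation windows without probability mass, missing travel
  entries, and missing interval draws all raise errors naming the
  offending quantity.

## Limitations

* The synthetic region reproduces stated *shares and levels*, not
  geography; travel times are straight-line, and origins collapse onto
  catchments.  Conclusions about a real region require its travel tables
  (`read_config()` accepts explicit per-modality matrices).
* The outcome coefficients are fixtures; PPFO *contrasts* between
  scenarios are meaningful under any harmful-delay coding, but PPFO
  *levels* are only as good as the coefficients supplied.
* Interval steps are drawn independently; correlations between steps
  (e.g. congested systems being slow everywhere) are not modelled, which
  understates the variance of OTG but leaves its mean unaffected.
* No resource contention: an MI serving two simultaneous patients, or TSC
  staffing constraints, would erode the reported gains and are outside
  the model.
* IVT is retained for every patient in every pathway; eligibility
  modelling and onset-to-needle effects for non-EVT patients are out of
  scope.
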