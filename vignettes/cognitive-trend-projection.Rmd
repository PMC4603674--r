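---
title: "Group-stratified cognitive trend projection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-stratified cognitive trend projection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogtrend)
library(dplyr)
```

## The problem

National assessments publish group-level mean scores by subject and survey
year, not microdata. Forecasting the national average from such summaries
requires stratification, because secular ability change (the FLynn effect)
differs sharply across demographic groups while the groups' population
shares shift at the same time. `cogtrend` models each group's trajectory as
a linear trend on a benchmark-standardized scale, projects the population
average as a share-weighted mean under time-varying composition, and
decomposes the projected change into interpretable components. This
vignette explains the model, its assumptions, the tunable parameters, and
the design decisions where more than one defensible choice existed.

## Standardization

Raw scale scores (0–500 for the motivating assessment) carry no intrinsic
location or unit, so all analysis happens on a standardized metric fixed by
a benchmark: the mean and dispersion of a reference group in a reference
year map to `target_mean = 100` and `target_sd = 15`. The default benchmark
is the largest group (White) in the earliest surveys reporting all
race-ethnic categories (mathematics 1978, reading 1980). The conversion is
affine, so nothing downstream depends on which group anchors the scale —
only the origin and unit do; `benchmark()` makes the choice fully
configurable.

Two conventions matter:

* **Per-subject first.** Standardization happens separately per subject
  (each subject has its own benchmark-year mean and SD); the combined
  cohort value is the arithmetic mean of the per-subject standardized
  values.
* **Offset survey years.** Subjects surveyed in alternating years within a
  configurable gap (`max_gap = 2`) are paired into one display cohort
  ("1978/80"), but every observation keeps its own calendar year for
  regression. Surveys that cannot be paired remain as singleton cohorts
  with a warning rather than being dropped.

Groups with insufficient data (in the motivating data, "American Indian or
Alaska Native" and "Unclassified", each 0–2% of participants) are removed
through an explicit exclusion list, never silently.

The benchmark's raw-scale anchors are normally resolved from the dataset
itself. `benchmark()` also accepts explicit raw mean/SD constants per
subject; the synthetic generator uses this form so that the generating
scale and the standardizing scale coincide exactly, which is what makes
noiseless round-trip tests exact rather than merely close.

## Anchored linear trends

Per (group, subject, period), the slope is the OLS coefficient of
standardized value on calendar year over the inclusive period window
(`fit_slope()`, via `stats::lm`); the group slope is the full-precision
arithmetic mean of its subject slopes. Fitting the combined cohort series
instead — with reading observations attributed to the mathematics display
year — is a tempting shortcut that gives visibly different answers on real
data (the combined-series slope for the benchmark group is about 0.07
points/year versus 0.0465 from the per-subject path); the test suite pins
this down as a negative control.

The trend model's intercept is deliberately **not** the regression
intercept: the projection is anchored at the observed value in the anchor
year (2012, the last survey), so every trajectory starts exactly at the
last measured level and `IQ(y) = IQ(2012) + m (y − 2012)`. A regression
intercept would shift the whole projection by the fit's residual at 2012
and make the 2012 "projection" disagree with the observation.

Two fitting windows are pre-configured, matching the published analysis:
the full 1978/80–2012 record (steeper average rise, hence more optimistic
projections) and the more recent 1992–2012 window (flatter, more
pessimistic). Both period bounds are inclusive, so the "1978/80–2012"
window contains the mathematics 1978 and reading 1980 observations.

A precision subtlety: the packaged slope table prints per-subject slopes
and their averages independently rounded to four decimals, and the two do
not always agree in the last digit (the 1992–2012 White average is
0.00565 unrounded, printed 0.0056). The pipeline always averages the
per-subject slopes at full precision. This choice reproduces every
published projection/effect cell within ±0.01 *and* the published economic
figures to the dollar, which the printed averages do not (they push the
pessimistic catch-up component from 2.034 to 2.035, across the 2.035
rounding boundary, and hence the catch-up dollars from $1,644 to $1,652).

## Projection and composition weighting

The population value in year *y* is the share-weighted mean of group
values. Composition shares come from census projections tabulated on a
5-year grid; `interpolate_shares()` returns exact grid rows and linear
interpolants between them, and refuses to extrapolate outside the table.
The 2012 baseline composition is its own tabulated row (a population
estimate, not part of the 5-yearly projection series).

Because small groups are excluded, the modeled shares sum to 0.94–0.97,
not 1. Weights are therefore **renormalized** over the modeled groups by
default, making the population value a convex combination of group values.
This is not cosmetic: only renormalized weighting reproduces the published
population rows (99.50 in 2012, 103.17 in 2060 under the optimistic
period), and the decomposition identity below algebraically requires
weights summing to one.

Group trajectories are linear in year by construction; the population
trajectory is not, because the share paths bend it.

Best/worst-case scenarios (`scenario_slopes()`) assign every group the
maximum/minimum group slope — the envelope of what the observed group
trends make plausible. Ties are broken deterministically by a configured
group order. Negative projected changes are legitimate outcomes and are
never clamped (the pessimistic worst case ends 1.09 points below its 2012
level).

## The four-term decomposition

With renormalized shares `p`, anchor levels `v`, slopes `m`, baseline
group slope `m_base`, and `Δt = y − y0`:

* `e_base = Δt · m_base`
* `e_minor = Δt · Σ_r p_{y0,r} (m_r − m_base)`
* `e_pop = Σ_r v_{y0,r} (p_{y,r} − p_{y0,r})`
* `e_pm = Δt · Σ_r (p_{y,r} − p_{y0,r}) (m_r − m_base)`

and `e_base + e_minor + e_pop + e_pm` equals the directly projected
population change exactly (floating-point tolerance), for arbitrary slopes
and share paths — a property the tests verify on a thousand random
instances, not just the study inputs.

The catch-up term uses **baseline-year** shares. Writing the weighted slope
sum as `Σ p_{y,r} m_r` and expanding `p_y = p_{y0} + (p_y − p_{y0})` and
`m_r = m_base + (m_r − m_base)` yields the four terms above with `p_{y0}`
in the catch-up term and the share *difference* in the interaction term;
using horizon-year shares in the catch-up term double-counts the
interaction and breaks additivity (at the 2060 horizon it would inflate
the optimistic catch-up component from ≈1.79 to ≈2.81). Degenerate cases
collapse correctly and exactly: frozen shares zero `e_pop` and `e_pm`;
homogeneous slopes zero `e_minor` and `e_pm`.

Per-decade rates divide components by `Δt/10` at full precision. Published
per-decade rows occasionally reflect division of the already-rounded
2-decimal component (0.465 printed as 0.46); both routes agree within the
±0.01 comparison tolerance used throughout.

## Economic conversion

`economic_gain()` converts ability change to per-capita yearly product at a
constant `dollars_per_point = 810` (2010/2011 USD PPP), explicitly ignoring
inflation and baseline growth — it prices only the ability-attributable
surplus. Reported dollar figures multiply the component values **as
reported** (rounded to two decimals) and round to whole dollars, matching
how such tables are conventionally derived from their printed inputs
(3.68 × 810 = 2980.8 → $2,981, where the unrounded total would give
$2,980).

## Rounding policy

All report-facing rounding is half-away-from-zero (`round_half_up()`) at
the printed precision of each quantity: two decimals on the IQ metric,
four on slopes, whole dollars. R's bankers' rounding would differ on exact
halves. Internally everything is full precision; "total increase" rows are
differences of unrounded endpoints, rounded last.

## The synthetic generator

`synthetic_scenario()` fixes a complete ground truth: per-(group, subject)
linear trends anchored at 2012, a raw-scale benchmark per subject, additive
Gaussian survey noise on the standardized scale (mapped back to raw units,
so `noise_sd` is interpretable in IQ-metric points), and linearly drifting
composition shares validated to sum to at most 1. The default calibration
(`paper_scenario()`) mirrors the study: four groups, two subjects offset by
two years, eleven survey cohorts 1978–2012, true slopes and anchor levels
from the packaged tables, shares drifting between the 2012 and 2060 census
rows. The raw-scale constants (mathematics 306/31, reading 286/39) are
synthetic plausible values — the source publishes no raw means or SDs,
which is also why the standardized score table ships as a fixture rather
than being re-derived.

What the generator emulates: the linear-trend signal structure, the
offset-year survey design, benchmark standardization, composition drift.
What it does not: sampling design and school clustering, scale drift or
equating error, non-Gaussian or serially correlated noise, nonlinear
trends. Passing recovery tests therefore certify the *pipeline arithmetic*
(estimator correctness, identity preservation), not robustness of the
linear model to real survey pathologies.

`recovery_experiment()` runs generate → standardize → fit → decompose per
replicate (replicate *r* seeds the generator with `seed + r − 1`) and
reports per-group slope bias and RMSE plus the largest additivity violation
observed. Under noise, the slope estimator's sampling SD has the
closed form `σ/√Σ(x−x̄)²` per subject; tests check the empirical RMSE
against this oracle within 20% at 200 replicates, and check monotonicity of
RMSE in `noise_sd` on a coarse grid. Simulation sizes in the test suite
(200 replicates for the sampling-distribution check, 60 per noise level for
monotonicity, 1000 random instances for the decomposition identity) were
chosen so Monte-Carlo error is several times smaller than the tolerance
each test asserts.

## Numerical and degenerate-input behaviour

* `fit_slope()` demands ≥ 2 observations with distinct years inside the
  window; constant series return slope 0; zero year-variance errors.
* `interpolate_shares()` errors outside the table range; no silent
  extrapolation.
* `weighted_population_mean()` errors on zero share sums and on group
  mismatches between values and weights.
* Scenario ties are broken by configured group order, so results are
  reproducible regardless of input row order.
* All validation failures are errors with stable message prefixes
  (`insufficient data`, `degenerate design`, `anchor missing`,
  `extrapolation`, `inconsistent period`, `invalid scenario`, …).

## Known limitations

* Trends are linear with no uncertainty quantification — no standard
  errors, prediction intervals, or probabilistic projections; the
  best/worst envelope is the only spread measure.
* The analysis consumes published group summaries; no item-level
  psychometrics (IRT, equating) and no re-derivation of the standardized
  score table from raw scale data, which is unpublished.
* The participation-weighted "Average" column of the standardized score
  table uses per-subject student shares in a way not fully reconstructible
  from the printed tables (recomputation gives ≈98.9–99.0 against a
  printed 98.88 for 2012); it is loaded for reference but excluded from
  golden comparisons, and the derived student-vs-total-population
  weighting contrast is likewise out of scope.
* Census share projections are consumed as given; their fertility,
  mortality and migration assumptions are not modeled, and only the main
  immigration series ships as a fixture.
* The economic conversion is a constant-price cross-sectional coefficient,
  not a growth model.
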