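---
title: "Modelling hospital capacity and quality gains from subcutaneous rituximab and trastuzumab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hospital capacity and quality gains from subcutaneous rituximab and trastuzumab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccapacity)
```

## The problem

Intravenous (IV) rituximab and trastuzumab require weight-based doses
compounded in a vertical laminar flow hood and infused over hours in an
administration chair of an onco-hematology day unit. Their subcutaneous
(SC) formulations are fixed doses injected in minutes, need no hood
compounding and (for trastuzumab) no loading dose. Converting patients from
IV to SC therefore frees two scarce resources — chair time and hood time —
and shortens the patient's stay in hospital. `sccapacity` is a
deterministic resource-utilization model that quantifies both effects for a
hospital (or a cohort of hospitals) from a small set of observable inputs:
per-visit stage times, yearly regimen schedules, a case mix, unit resources
and current conversion rates.

## Patient time in hospital

A visit decomposes into three stages: waiting room, administration chair
and medical consultation. For a drug $d$ and route $r$, the annual time of
an indication $i$ with $n^{(i)}_{p}$ cycles of phase $p$ is

$$T^{(i)}_{s}(d, r) = \sum_{p} n^{(i)}_{p} \, t_{s}(d, r, p),$$

per stage $s$, where $t_s$ are the per-cycle stage times. Two route rules
apply: every rituximab regimen administers its first cycle IV even on the
SC pathway, and the trastuzumab year starts with a distinct first cycle
(`loading_combo`; the IV form carries the loading dose). The monthly time
is the case-mix-weighted mean of $T^{(i)}_{s}/12$.

**Rounding convention.** Reported stage values are rounded half to even
(banker's rounding, R's `round()`), and the monthly total is the *sum of
the rounded stages*, not the rounded sum. This is the only convention
jointly consistent with the packaged reference table: the rituximab SC
stages 77.7, 117.8 and 21.9 print as 78 + 118 + 22 = 218 while the
unrounded total is 217.44, and the trastuzumab SC waiting stage 106.5
rounds down to 106 while the IV consultation stage 25.5 rounds up to 26.
All internal arithmetic is double precision; rounding happens once, at
reporting.

With the packaged inputs the model reproduces the reference monthly table
exactly:

```{r monthly}
reference_monthly_times()
```

and the headline reductions follow from the rounded totals:
$100 \times (411-218)/411 = 46.96\%$ for rituximab and
$100 \times (316-212)/316 = 32.91\%$ for trastuzumab. (Recomputing the
trastuzumab figure from unrounded totals gives 32.86%; the published
intermediate values are rounded, so anything in roughly 32.86–32.91 is the
same number at the source's precision.)

## Capacity parameters

Four parameters convert freed minutes into additional treatments:

* **P1 — IV-to-SC conversion.** Chair minutes freed per month:
  $\sum_{d,p} \Delta_{\text{chair}}(d,p) \times n_{\text{conv}}(d,p)
  \times v(d,p)$, with $\Delta_{\text{chair}}$ the IV-minus-SC chair time
  per visit and $v$ monthly visits.
* **P2 — premedication in the waiting room.** Rituximab premedication
  chair minutes moved out of the chair, for SC maintenance patients.
* **P3 — regional referral.** SC patients treated at their regional
  hospital free both chair time (IV-vs-SC difference per visit, as the
  parameter is defined — a deliberately conservative accounting that does
  not credit the whole freed slot) and hood time for doses prepared
  regionally.
* **P4 — hood preparation.** (a) SC doses take less preparation time than
  IV doses; (b) when SC preparation is relocated to the treatment unit,
  its entire preparation time leaves the hood.

Each minutes-saved quantity is divided by the *average unit time* — total
open chair-minutes per day divided by daily treatments for administration,
weekly hood-minutes divided by weekly preparations for the pharmacy — and
expressed as a percentage of the current period volume. Administration
parameters are monthly, preparation parameters weekly; the two bases are
kept separate and never added silently (the reported `capacity_pct_sum`
sums the percentage components the way the headline capacity figure is
conventionally composed: P1 + P2 + P3 + P4b).

The average-unit-time definition is not printed anywhere in the source
material; dividing open capacity by throughput is the only formula
consistent with its stated inputs ("opening hours, number of positions and
volume of daily treatments"), and the occupancy simulation below confirms
it behaves as the marginal treatment time at saturation.

Premedication chair time is never published; it is a required input with no
default. Negative deltas (SC slower than IV) are accepted and propagate to
negative impacts, with a warning.

## Quality parameters

* **Time in hospital** — the monthly reduction above, reported in percent
  with its stage decomposition.
* **Labor productivity** — minutes saved valued at the professional cost
  per minute, `salary / (12 × hours × 60)`. With no salary details the
  model uses the Spanish labor-market constant 0.205464 EUR/min (the
  constant derives from EUR 23,022.20/year at 155.6 h/month; deriving it
  from those printed inputs gives 0.20550 — the published constant kept
  more decimals of the hours figure). A productivity *percentage* needs a
  baseline of productive minutes; no published denominator exists, so the
  percentage is only computed when the user supplies one.
* **Venous access devices** — SC trastuzumab lets early breast-cancer
  patients use a PICC (removed at maintenance) instead of an implanted
  port-a-cath; the model reports rate and device-time reductions from the
  hospital's device counts.

## Scenario engine

A scenario is a per-drug target SC dose share plus the five process flags
(dedicated SC chair, waiting-room premedication, regional referral,
preparation outside the hood, device avoidance). The maximal scenario sets
the shares to the SmPC eligibility caps — 45% of rituximab doses, 91% of
trastuzumab doses — and enables every flag.

Converted patient counts scale *linearly* with the scenario share relative
to the hospital's current share, per phase, capped at the treated
population; no dose-level heterogeneity data exist that would justify
anything richer. One asymmetry is deliberate: observed hospital shares can
*exceed* the SmPC cap (the cap counts all label doses; an individual
hospital's case mix may be skewed toward eligible indications — observed
overall rituximab conversion reaches 68%). An at-cap scenario applied to
such a hospital is treated as a no-op (conversion never moves backwards),
whereas an explicitly sub-cap scenario below current practice is an error,
since it would silently model de-conversion.

Aggregation across hospitals is the unweighted arithmetic mean of each
parameter's percentage variation over the hospitals that contribute it; a
hospital without a drug contributes nothing to that drug's parameters.

## Synthetic hospitals

The study's per-hospital questionnaire data are unpublished, so the package
generates synthetic cohorts with the reported statistical structure:

* **Conversion rates** uniform within the published per-phase observed
  ranges (rituximab combination 0–53.3%, maintenance 36.2–100%;
  trastuzumab combination 0–91.7%, maintenance 39.8–100%). Only ranges are
  published, so the uniform is the maximum-entropy choice.
* **Stage times** from zero-truncated normal distributions centered on the
  reference per-cycle values with a configurable coefficient of variation
  (default 0.10, a typical between-hospital spread for process times; at
  CV 0 the reference table is reproduced exactly).
* **Resources** uniform within ranges chosen once as typical of Spanish
  reference-hospital day units: opening 540–720 min/day, 10–30 chairs,
  20–22 administration days/month, 40–120 treatments/day, 1–3 hoods at
  420–600 min/day × 5 days, 100–300 preparations/week. The preparation
  volume was set jointly with hood capacity so the implied average
  preparation time (≈7–30 min) is consistent with 15–30 min IV monoclonal
  preparations.
* **Process flags** Bernoulli with the observed prevalences (80% dedicated
  chair, 87.5% premedication, 10% referral, 20% preparation outside the
  hood, 77.8% device avoidance).
* The `study_mix` preset reproduces the observed service mix: of 10
  hospitals, 7 treat both drugs, 2 only trastuzumab, 1 only rituximab.

One master seed drives the cohort; each hospital draws from a substream
derived deterministically from (seed, index), so cohorts are reproducible
and order-stable (hospital *i* is the same hospital in a longer cohort).

What the generator does **not** emulate: correlations between hospital size
and conversion rate (unknown, assumed independent), within-hospital
correlations between stage times, seasonal or day-of-week structure, and
the actual unpublished site data. Passing tests on synthetic cohorts
therefore demonstrate internal consistency and parameter recovery, not
agreement with any real hospital's books; cohort-level capacity
percentages can sit well away from the published site averages because
they depend on the sampled volume scales.

## The occupancy oracle

The analytic capacity formulas are fluid approximations. To check they
behave like real packing, `simulate_occupancy()` packs jobs onto identical
servers minute by minute (greedy earliest-free assignment within the
opening window) and `simulated_capacity_gain()` measures how many extra
jobs fit when some jobs are shortened. The cross-check uses a busy
mixed-duration day — 15 chairs, 900 operating minutes, visit durations
normal(30, 6) truncated at 5 min, 250 visits shortened by 20 min, an
unlimited offered stream — where packing residuals are small relative to
the gain; there the analytic estimate tracks the simulated gain within
±10% in every tested replicate (gaps typically under 6%). With few long
jobs per chair (e.g. 100-minute infusions in a 600-minute day) integer
packing residuals dominate and the fluid estimate can deviate by 20% or
more in either direction; the analytic percentages should be read as
saturation-regime estimates.

## Numerical choices and edge cases

* Half-to-even rounding, once, at reporting; totals are sums of rounded
  stages (see above).
* Case-mix shares must sum to 1 within 1e-9; validation errors carry
  distinct condition classes (`sccapacity_parse_error`,
  `sccapacity_config_error`, `sccapacity_invariant_error`) with field
  context.
* Zero denominators (no treatments, no working hours, no baseline devices,
  zero IV monthly total) are explicit errors, never NaN.
* Percentages in output files are formatted to two decimals, matching the
  precision of the published figures; euro values to cents; times as
  integers.
* Test and example problem sizes (3,000 hospitals for moment checks, 200
  for noisy recovery, 20 replicates × 1,500 jobs for the occupancy
  cross-check) were chosen so each property is measured with comfortable
  statistical margin while the whole suite runs in well under a minute of
  compute per module.

## Known limitations

* The model is deterministic and cross-sectional: no queueing dynamics, no
  per-patient scheduling calendar, no demand growth.
* Visit frequencies are inputs, not derived from dosing intervals (the
  source material implies every-3-weeks trastuzumab but never states the
  rituximab maintenance interval).
* The published site-level capacity percentages, the productivity
  percentages and the hypothetical-hospital time reductions rest on
  unpublished per-hospital data or unstated denominators; the package
  reproduces their *formulas* and validates them by property, not by
  value.
* No cost-effectiveness analysis, discounting, or national extrapolation.
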