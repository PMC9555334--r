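---
title: "Valuing primary-care engagement in a diabetes population: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing primary-care engagement in a diabetes population: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcvalue)
```

## The model

`dpcvalue` implements a deterministic budget-impact model that answers one
question for a health system: *what is an attended primary-care visit by a
previously unengaged patient with diabetes worth, in annual dollars?* The
calculation chain is

1. **Segmentation.** The diabetes population is split by the most recent
   HbA1c value using HEDIS thresholds: controlled (HbA1c < 7), moderately
   controlled (7 ≤ HbA1c < 9), uncontrolled (HbA1c ≥ 9). The intervals are
   half-open upward, so 7.0 and 9.0 classify into the more severe segment.
   Patients with no recorded HbA1c are treated as moderately controlled —
   their provider would order the test at a first visit, and the middle
   cadence is the sensible interim assignment.
2. **Eligibility funnel.** ADA guidelines recommend 1, 2 or 4 visits per
   year by segment. A patient is *overdue* when the last visit is strictly
   more than 11, 5 or 2 calendar months ago respectively (one inter-visit
   interval minus a month), and *unengaged* when additionally no visit is
   scheduled within the next 3 months. Applied at the count level
   (`engagement_funnel()`) this is a three-stage multiplication of rates;
   applied at the record level (`aggregate_registry()`) it is an exact
   census.
3. **Professional revenue.** A 10-code service catalog assigns each
   billable service an allocation fraction (the comorbidity-derived share
   of patients needing it per visit, e.g. 44% for a lipid panel). Patients
   are split across commercial/Medicare/Medicaid payers, allocated to
   codes, billed at the segment cadence, and priced from a per-payer fee
   schedule. Bundled codes (urinalysis, diabetic foot exam) and non-covered
   codes (Medicaid blood-pressure-monitor education) contribute zero
   revenue.
4. **Provider compensation.** Work RVUs for the codes a provider personally
   performs, times the engaged patients allocated to each, times a dollar
   conversion factor (default $41.94/RVU, the MGMA median). Subtracted from
   revenue.
5. **Inpatient margin.** 33.9% of people with diabetes need inpatient care
   in a year (CDC); the engaged cohort therefore brings expected admission
   revenue, weighted across payers by the population payer mix.
6. **Waterfall.** total margin = professional + inpatient − compensation,
   divided by attended appointments.

## Rounding as a model contract

Planning tables of this kind round counts at every stage, and the rounding
rule changes final dollar figures, so it is an explicit parameter
(`rounding_policy()`). The default is half-up (ties away from zero),
applied stage by stage — each rounded count feeds the next multiplication.
Ties are detected with a 1e-9 absolute tolerance so decimal products stored
inexactly in binary (14,500 × 0.663 = 9613.4999…) still round as decimal
arithmetic would. Mode `"none"` keeps fractional counts and yields the
closed-form model; it is what the sensitivity machinery and the
record-level oracle compare against, since integer jitter there is noise.
Admission counts floor by default (the "approximately N patients"
convention).

Payer splits round independently per payer by default, which can overshoot
the input (9614 + 2973 + 1914 = 14,501 from 14,500); that is how such
tables are conventionally built and is kept for replication. An exact
largest-remainder apportionment (`apportion = TRUE`) is available when
conservation matters.

Dollars are carried as full-precision doubles end to end and only formatted
to whole dollars for presentation. We deliberately did not integerise
currency to cents: the calibrated unit fees are non-terminating decimals,
and the waterfall identity holds exactly by construction because the margin
is computed as the literal sum of its three components.

## The packaged reference scenario and its calibration

`reference_config()` loads a complete scenario for a hypothetical
100,000-patient population: CDC national-average segment fractions
(50/35.5/14.5%), health-system engagement rates (13.1/29.8/61.1% overdue;
96.2/86.7/75.6% with no scheduled visit), a 66.3/20.5/13.2% payer mix, 10%
uptake, and national inpatient parameters ($2700/$2000/$1280 per admission).

Unit fees and per-code work RVUs are **calibration fixtures**, not CMS
ground truth: the scenario's planning tables publish annual dollar totals
and RVU component totals but not unit prices, so
`data-raw/calibrate_fixtures.R` back-derives
`fee = annual revenue / (allocated patients × 4 visits)` and
`work RVU = RVU component / allocated patients` at full precision. Recomputing
the tables from these fixtures reproduces every printed integer, which is
the property the test suite asserts. Two consequences are worth knowing:

* Per-visit recurrence is assumed — an allocated code bills at each of the
  1/2/4 annual visits. Back-division of the published revenue by
  (allocated × 4) yields stable unit fees, which supports this reading; a
  per-code `billing = "per_year"` flag is available for codes that should
  bill once.
* The RVU-bearing rows are internally inconsistent under any single
  two-decimal RVU (1508 × 0.18 = 271.44, not the published 271.36), so the
  full-precision back-derived values are the only ones that reproduce the
  published component sum of 5006.87 exactly.

The reference scenario's inpatient stage uses an externally supplied
engaged-cohort figure of 2235 (via `engaged_override`) while the
uptake-gated computation gives half-up(10% × 22,171) = 2217; the scenario
source uses both figures in different places without deriving 2235, so the
package computes 2217 and exposes the override rather than guessing.
Similarly, the published inpatient total of $1,796,506 is not exactly
recoverable from any stated combination of admission count and per-payer
rates; the payer-proportional reconstruction lands within 0.2%, and the
regression tests assert a 0.5% band rather than equality. The published
summary's own components are mutually inconsistent (they sum to $2,899,695,
not the printed $3,050,957, and neither division equals the printed per-visit
value), so the suite asserts the recomputed $1307.94 from those components
and the engine never hard-codes the printed figure.

"Even mix of hospitalization across payer type" is ambiguous between
payer-proportional weighting and equal thirds; payer-proportional is the
default because it reconstructs the published inpatient total to within
0.2% while equal thirds misses by ~16%. Both are selectable (`mix_mode`).

## Revenue basis and the attended denominator

Three billing bases are supported for professional revenue
(`revenue_basis`): the engaged cohort (default — the visits the
intervention actually produces), the full unengaged population (potential
if everyone re-engaged), and the full population (the planning-table view,
which is what the per-segment revenue tables use). The attended denominator
defaults to one valued appointment per engaged patient per year
(`attended_basis = "engaged_patients"`), matching the convention of
dividing by the engaged count; `"engaged_visits"` (engaged × cadence) is
available but non-default.

Under exact arithmetic the default model is structurally insensitive to the
uptake fraction: professional revenue, compensation, inpatient margin and
the attended denominator all scale linearly with the engaged cohort, so the
per-appointment value cancels uptake exactly (the test suite demonstrates
this with a one-way run at 5% vs 20% under `rounding = "none"`). Uptake
still scales the total margin — and therefore ROI — linearly. This is why
sensitivity runs (`one_way_sensitivity()`, `probabilistic_sensitivity()`)
clear any `engaged_override` first: overrides pin the cohort and would
silently decouple the stages being varied.

## The synthetic registry

`generate_registry()` emulates an EHR diabetes-registry extract
(one row per patient: HbA1c to one decimal, last and next visit dates,
payer, diabetes type; gestational/medication-induced diabetes excluded by
construction). Latent segment, overdue and no-future-visit statuses are
drawn at the requested rates and visit dates are then placed inside or
outside the segment's calendar windows, so the record-level tests recover
the latent statuses exactly and marginal frequencies converge to the
requested rates with pure binomial error. Month arithmetic is
calendar-month, day-anchored, clamped to month-end (July 31 minus 5 months
is February 28/29), with strict inequality at the lookback boundary.

What the generator does *not* emulate: correlation between payer and
segment, seasonality in scheduling, visit-history depth beyond the last
visit, churn, or measurement error in HbA1c. Passing oracle-equivalence
tests therefore show that the aggregate and record-level engines agree on
the funnel arithmetic — not that either captures real registry structure.
Distributional choices that do not affect the funnel (10% of overdue
patients have no visit on record; 20% of unengaged patients hold a
far-future booking; non-overdue patients are 50% scheduled) are fixed
plausible values, documented here once.

Test problem sizes: the oracle-equivalence census uses one 50,000-record
registry checked cell-by-cell within 3 binomial standard errors;
rate recovery pools 20 seeds × 10,000 records; the waterfall identity is
checked on 1000 randomly perturbed configurations. These sizes give
standard errors a factor ≳3 below the tolerances being asserted.

## Degenerate inputs and error surfaces

* `attended = 0` (zero uptake or an empty population): the value per
  appointment is undefined; `value_per_appointment()` raises an explicit
  error, while `run_scenario()` reports `NA` with a warning so that an
  empty scenario can still render an all-zero report without any division.
* Absent last visit ⇒ overdue (a never-seen patient is maximally
  unengaged); absent next visit ⇒ no scheduled appointment.
* Configuration validation is aggregated: a failed `load_config()` lists
  every problem found and no partially constructed configuration escapes.
* Missing fee for a payable (payer, code) pair errors naming both.

## Limitations

The model is a revenue-side planning tool, not a cost-effectiveness
analysis: no QALYs, no patient out-of-pocket costs, no claims adjudication
(modifiers, denials, deductibles), no DRG/length-of-stay modelling, and no
geographic adjustment of the conversion factor. Engagement rates are inputs,
not estimates — any real deployment should replace the reference rates with
the health system's own registry rates. The inpatient term applies the flat
national admission rate to the engaged cohort; if engagement succeeds in
reducing admissions, that term should shrink (`rate_multiplier` exists for
exactly that scenario analysis).
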