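# dpcvalue

**What is a primary-care visit by an unengaged patient with diabetes worth
to a health system?**

Health systems weighing interventions that nudge unengaged patients with
diabetes back into primary care need a dollar value per recovered
appointment — for pricing, prioritisation and ROI. `dpcvalue` is a
deterministic budget-impact engine that computes that value from first
principles, for analysts in health-system finance, population health and
digital-health vendors.

The calculation chain:

1. **Segment** a diabetes population by HbA1c control (HEDIS thresholds:
   `<7` controlled, `7–<9` moderately controlled, `≥9` uncontrolled) and
   apply the ADA visit cadence (1/2/4 visits per year).
2. **Funnel** to the unengaged: overdue for a visit (last visit > 11/5/2
   calendar months ago by segment) *and* nothing scheduled within 3 months.
3. **Professional revenue**: split patients by payer mix
   (commercial/Medicare/Medicaid), allocate them to a 10-code CPT-style
   service catalog by comorbidity rates, bill at the segment cadence
   against a per-payer fee schedule (bundled and non-covered codes earn
   zero).
4. **Provider compensation**: work RVUs × a conversion factor
   ($/RVU, default the MGMA median $41.94), for the uptake-gated engaged
   cohort (default 10% of the unengaged).
5. **Inpatient margin**: the CDC 339-per-1000 annual hospitalization rate
   applied to the engaged cohort, reimbursed per payer.
6. **Waterfall**:

   ```
   value per appointment = (professional revenue + inpatient revenue
                            − provider compensation) / attended appointments
   ```

It ships with a record-level synthetic EHR registry generator (the oracle
for the aggregate arithmetic), one-way and probabilistic sensitivity
analysis, ROI, YAML configuration, CSV reporting and a small CLI
(`exec/dpcvalue`).

## Worked example

The packaged reference scenario is a hypothetical 100,000-patient US
population with CDC national-average segment fractions, a 66.3/20.5/13.2%
payer mix and a calibrated fee schedule:

```r
library(dpcvalue)
res <- run_scenario(reference_config())
res
#> Engagement funnel (patients)
#>                segment population overdue unengaged
#>             controlled      50000    6550      6301
#>  moderately_controlled      35500   10579      9172
#>           uncontrolled      14500    8860      6698
#>                  total     100000   25989     22171
#>
#> Engaged cohort (uptake-gated): 2217
#> Professional revenue (annual): $1,020,122
#> Provider compensation
#>   office_visit                    4256.64 RVU
#>   bp_setup_education               271.36 RVU
#>   bp_monitor_education             361.81 RVU
#>   tobacco_cessation                117.06 RVU
#>   RVU total: 5006.87  x  $41.94/RVU
#>   Annual: $209,988   Monthly: $17,499
#> Hospitalized (expected): 757  ->  inpatient revenue $1,793,378
#>
#> Value waterfall (annual)
#>   Professional revenue:       $1,020,122
#>   Inpatient revenue:          $1,793,378
#>   Provider compensation:       $-209,988
#>   Total margin:               $2,603,513
#>   Attended appointments:           2,217
#>   Value per appointment:          $1,174
```

Reading this: of 100,000 patients, 22,171 are unengaged with their diabetes
care; at 10% uptake, 2,217 attend a visit. Valuing the visits that cohort
actually attends, each recovered appointment is worth about $1,174/year to
the system — professional billing plus expected inpatient margin, net of
what the providers are paid. The revenue-*potential* view is also
available: the uncontrolled segment alone (14,500 patients at 4 visits/yr)
carries $11.5M of annual billing potential:

```r
cfg <- reference_config()
attr(professional_revenue(14500, cfg$payer_mix, cfg$catalog, cfg$fees,
                          cfg$policies$uncontrolled), "payer_totals")
#> commercial   medicare   medicaid
#>    8986351    1852541     670742
```

Sensitivity and ROI:

```r
one_way_sensitivity(reference_config(), "hospitalization_rate", 0, 0.339)
#> One-way sensitivity on 'hospitalization_rate'
#>   low  0 -> value/appt $365
#>   high 0.339 -> value/appt $1,168
roi(run_scenario(reference_config())$waterfall, 1e6)
#> [1] 1.603513
```

The synthetic registry generator emulates the EHR extract the funnel would
be computed from, and `aggregate_registry()` is its exact record-level
census:

```r
reg <- generate_registry(registry_params(
  50000, cfg$cohort$segment_fractions, cfg$cohort$overdue_rate,
  cfg$cohort$no_future_visit_rate, cfg$payer_mix, random_seed = 2022))
aggregate_registry(reg, as_of = as.Date("2022-07-01"))
```

See `vignettes/value-model.Rmd` for the model's assumptions, the rounding
contract, the fee/RVU calibration, and known limitations.

## CLI

```sh
exec/dpcvalue segment --config inst/extdata/reference_config.yaml
exec/dpcvalue value --config inst/extdata/reference_config.yaml --format csv --out out/
exec/dpcvalue simulate-registry --config inst/extdata/reference_config.yaml --n 10000 --seed 7 --out registry.csv
exec/dpcvalue sensitivity --config inst/extdata/reference_config.yaml --psa "uptake_fraction:uniform,0.05,0.2" --draws 500 --seed 1
exec/dpcvalue reference-case
```
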