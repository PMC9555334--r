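# Packaged reference valuation scenario: a hypothetical US health-system
# population of 100,000 patients with diabetes. Segment fractions are CDC
# national averages; engagement rates are health-system registry rates; the
# fee schedule and work RVUs are calibrated fixtures (see
# data-raw/calibrate_fixtures.R), not authoritative CMS data.
cohort:
  total_population: 100000
  segment_fractions: {controlled: 0.50, moderately_controlled: 0.355, uncontrolled: 0.145}
  overdue_rate: {controlled: 0.131, moderately_controlled: 0.298, uncontrolled: 0.611}
  no_future_visit_rate: {controlled: 0.962, moderately_controlled: 0.867, uncontrolled: 0.756}
payer_mix: {commercial: 0.663, medicare: 0.205, medicaid: 0.132}
policies:
  controlled: {visits_per_year: 1, overdue_lookback_months: 11, future_window_months: 3}
  moderately_controlled: {visits_per_year: 2, overdue_lookback_months: 5, future_window_months: 3}
  uncontrolled: {visits_per_year: 4, overdue_lookback_months: 2, future_window_months: 3}
catalog_path: reference_catalog.csv
fee_schedule_path: reference_fees.csv
uptake:
  uptake_fraction: 0.10
conversion_factor: 41.94
inpatient:
  hospitalization_rate: 0.339
  reimbursement: {commercial: 2700, medicare: 2000, medicaid: 1280}
  mix_mode: payer_proportional
  count_rounding: floor
  # externally supplied engaged-cohort figure used for the inpatient stage
  # of the reference scenario (the uptake-gated computation gives 2217)
  engaged_override: 2235
rounding: half_up
revenue_basis: engaged
attended_basis: engaged_patients
fee_scale: 1.0
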