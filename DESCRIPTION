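Package: dpcvalue
Title: Economic Impact Modelling of Primary-Care Engagement for Diabetes Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A deterministic budget-impact engine that assigns a dollar value to
    primary-care visits attended by previously unengaged patients with diabetes.
    The model segments a diabetes population by glycemic control (HbA1c), applies
    HEDIS/ADA visit-cadence eligibility rules to identify unengaged patients,
    projects professional-practice revenue per payer from a CPT-style service
    catalog and fee schedule, subtracts RVU-based provider compensation, adds
    expected inpatient margin, and divides the resulting annual margin by
    attended appointments. Includes a synthetic patient-registry generator that
    serves as a record-level oracle for the aggregate model, one-way and
    probabilistic sensitivity analysis, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    lubridate
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
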