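# Shared fixtures: the reference-scenario inputs, built in code.

ref_fractions <- c(controlled = 0.50, moderately_controlled = 0.355,
                   uncontrolled = 0.145)
ref_overdue <- c(controlled = 0.131, moderately_controlled = 0.298,
                 uncontrolled = 0.611)
ref_no_future <- c(controlled = 0.962, moderately_controlled = 0.867,
                   uncontrolled = 0.756)
ref_mix_fracs <- c(commercial = 0.663, medicare = 0.205, medicaid = 0.132)

ref_spec <- function(total = 100000) {
  cohort_spec(total, ref_fractions, ref_overdue, ref_no_future)
}

ref_mix <- function() payer_mix(ref_mix_fracs)

# A tiny two-code catalog for property tests: one universal visit code and
# one partially allocated, partially covered lab code.
toy_catalog <- function(allocation2 = 0.5, rvu1 = 2, billing = "per_visit") {
  cpt_catalog(data.frame(
    code_key = c("visit", "lab"),
    description = c("Office visit", "Lab test"),
    allocation = c(1, allocation2),
    work_rvu = c(rvu1, NA),
    billing = billing,
    payable_commercial = c("payable", "payable"),
    payable_medicare = c("payable", "bundled"),
    payable_medicaid = c("payable", "not_covered"),
    stringsAsFactors = FALSE))
}

toy_fees <- function(scale = 1) {
  fee_schedule(data.frame(
    payer = c("commercial", "commercial", "medicare", "medicaid"),
    code_key = c("visit", "lab", "visit", "visit"),
    fee_usd = scale * c(100, 25, 80, 60),
    stringsAsFactors = FALSE))
}

ref_registry_params <- function(n, seed, missing = 0.05) {
  registry_params(n, ref_fractions, ref_overdue, ref_no_future,
                  ref_mix_fracs, missing_hba1c_fraction = missing,
                  evaluation_date = as.Date("2022-07-01"),
                  random_seed = seed)
}

strip_overrides_for_test <- function(cfg) {
  cfg$uptake$engaged_override <- NULL
  cfg$inpatient$engaged_override <- NULL
  cfg
}

# Random valid cohort specs for property tests (caller seeds the RNG).
random_spec <- function() {
  f <- stats::runif(3); f <- f / sum(f)
  names(f) <- control_segments()
  cohort_spec(sample(0:50000, 1), f,
              stats::setNames(stats::runif(3), control_segments()),
              stats::setNames(stats::runif(3), control_segments()))
}
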