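ref_catalog <- read_cpt_catalog(system.file("extdata", "reference_catalog.csv",
                                            package = "dpcvalue"))
ref_fees <- read_fee_schedule(system.file("extdata", "reference_fees.csv",
                                          package = "dpcvalue"))

test_that("patient allocation rounds the comorbidity share of each payer count", {
  expect_equal(allocate_patients(9614, 0.44), 4230)
  expect_equal(allocate_patients(1914, 0.68), 1302)  # 1301.52 rounds up... to 1302
  expect_equal(allocate_patients(9614, 0.25), 2404)  # 2403.5 half-up
  expect_equal(allocate_patients(123, 1.0), 123)
  entry <- ref_catalog[ref_catalog$code_key == "lipid_panel", ]
  expect_equal(allocate_patients(2973, entry), 1308)
})

test_that("annual service volume is allocation times cadence", {
  expect_equal(annual_service_volume(9614, 4), 38456)
  expect_equal(annual_service_volume(77, 1), 77)
  expect_equal(annual_service_volume(0, 4), 0)
})

test_that("uncontrolled-segment revenue reproduces every payable cell and total", {
  rev <- professional_revenue(14500, ref_mix(), ref_catalog, ref_fees,
                              default_policies()$uncontrolled)
  cell <- function(payer, code)
    rev$revenue[rev$payer == payer & rev$code_key == code]
  expected_commercial <- c(office_visit = 5669134, hba1c_test = 743081,
                           lipid_panel = 450869, cbc_auto_diff = 297309,
                           bp_setup_education = 92552,
                           bp_monitor_education = 1585158,
                           tobacco_cessation = 87894,
                           depression_screen = 60354)
  for (code in names(expected_commercial))
    expect_equal(round(cell("commercial", code)), expected_commercial[[code]],
                 label = paste("commercial", code))
  expected_medicare <- c(office_visit = 1225946, hba1c_test = 115471,
                         lipid_panel = 70063, cbc_auto_diff = 46200,
                         bp_setup_education = 20014,
                         bp_monitor_education = 342789,
                         tobacco_cessation = 19007, depression_screen = 13051)
  for (code in names(expected_medicare))
    expect_equal(round(cell("medicare", code)), expected_medicare[[code]],
                 label = paste("medicare", code))
  expected_medicaid <- c(office_visit = 506368, hba1c_test = 68827,
                         lipid_panel = 41771, cbc_auto_diff = 27523,
                         bp_setup_education = 10712, bp_monitor_education = 0,
                         tobacco_cessation = 7942, depression_screen = 7599)
  for (code in names(expected_medicaid))
    expect_equal(round(cell("medicaid", code)), expected_medicaid[[code]],
                 label = paste("medicaid", code))

  totals <- attr(rev, "payer_totals")
  expect_equal(round(totals[["commercial"]]), 8986351)
  expect_equal(round(totals[["medicare"]]), 1852541)
  expect_equal(round(totals[["medicaid"]]), 670742)
  expect_equal(attr(rev, "grand_total"), sum(rev$revenue))
})

test_that("bundled and non-covered cells carry zero revenue but keep their patients", {
  rev <- professional_revenue(14500, ref_mix(), ref_catalog, ref_fees,
                              default_policies()$uncontrolled)
  bundled <- rev[rev$code_key %in% c("urinalysis", "foot_exam"), ]
  expect_true(all(bundled$revenue == 0))
  expect_equal(bundled$allocated_patients[bundled$payer == "commercial"],
               c(9614, 9614))
  medicaid_bp <- rev[rev$payer == "medicaid" &
                       rev$code_key == "bp_monitor_education", ]
  expect_equal(medicaid_bp$revenue, 0)
  expect_equal(medicaid_bp$status, "not_covered")
  expect_equal(medicaid_bp$allocated_patients, 1302)
})

test_that("revenue is linear in fees and zero when fees vanish", {
  base <- professional_revenue(4000, ref_mix(), toy_catalog(), toy_fees(),
                               default_policies()$moderately_controlled)
  scaled <- professional_revenue(4000, ref_mix(), toy_catalog(), toy_fees(3),
                                 default_policies()$moderately_controlled)
  expect_equal(scaled$revenue, 3 * base$revenue)
  expect_equal(attr(scaled, "grand_total"), 3 * attr(base, "grand_total"))
  zero <- professional_revenue(4000, ref_mix(), toy_catalog(), toy_fees(0),
                               default_policies()$moderately_controlled)
  expect_true(all(zero$revenue == 0))
})

test_that("revenue grows with population, allocation and cadence", {
  pol2 <- default_policies()$moderately_controlled
  pol4 <- default_policies()$uncontrolled
  g <- function(pop, alloc, pol)
    attr(professional_revenue(pop, ref_mix(), toy_catalog(alloc), toy_fees(),
                              pol), "grand_total")
  expect_lt(g(1000, 0.5, pol2), g(2000, 0.5, pol2))
  expect_lt(g(1000, 0.2, pol2), g(1000, 0.9, pol2))
  expect_lt(g(1000, 0.5, pol2), g(1000, 0.5, pol4))
})

test_that("a missing fee for a payable pair names the payer and code", {
  fees <- toy_fees()
  fees <- fees[!(fees$payer == "commercial" & fees$code_key == "lab"), ]
  expect_error(
    professional_revenue(1000, ref_mix(), toy_catalog(),
                         fee_schedule(as.data.frame(fees)),
                         default_policies()$controlled),
    "commercial.*lab")
})

test_that("per-year billing bills once regardless of cadence", {
  cat_year <- toy_catalog(billing = "per_year")
  rev <- professional_revenue(1000, ref_mix(), cat_year, toy_fees(),
                              default_policies()$uncontrolled)
  expect_equal(rev$services_per_year, rev$allocated_patients)
})
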