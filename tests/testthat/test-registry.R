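test_that("HbA1c classification uses half-open HEDIS intervals, missing maps to moderate", {
  expect_equal(classify_control(c(5.1, 6.9, 7.0, 8.9, 9.0, 12.4, NA)),
               c("controlled", "controlled", "moderately_controlled",
                 "moderately_controlled", "uncontrolled", "uncontrolled",
                 "moderately_controlled"))
  expect_error(classify_control(0), "positive")
  expect_error(classify_control(-6.5), "positive")
})

test_that("overdue test uses strict calendar-month arithmetic with month-end clamping", {
  as_of <- as.Date("2022-01-15")
  ctrl <- default_policies()$controlled     # 11-month lookback
  unc <- default_policies()$uncontrolled    # 2-month lookback
  expect_true(is_overdue(as.Date("2021-01-15"), ctrl, as_of))    # 12 months ago
  expect_false(is_overdue(as.Date("2021-02-15"), ctrl, as_of))   # exactly 11
  expect_false(is_overdue(as.Date("2021-11-15"), unc, as_of))    # exactly 2
  expect_true(is_overdue(as.Date(NA), ctrl, as_of))              # never seen
  # Jul 31 census, 5-month lookback: cutoff clamps to Feb 28
  mod <- default_policies()$moderately_controlled
  expect_false(is_overdue(as.Date("2022-02-28"), mod, as.Date("2022-07-31")))
  expect_true(is_overdue(as.Date("2022-02-27"), mod, as.Date("2022-07-31")))
})

test_that("unengaged is the conjunction of overdue and no near-term appointment", {
  as_of <- as.Date("2022-01-15")
  pol <- default_policies()$controlled
  old <- as.Date("2020-06-01")
  recent <- as.Date("2021-12-01")
  expect_true(is_unengaged(old, as.Date(NA), pol, as_of))
  expect_false(is_unengaged(old, as.Date("2022-03-10"), pol, as_of))   # 2 mo out
  expect_false(is_unengaged(recent, as.Date(NA), pol, as_of))          # not overdue
  # boundary: appointment exactly at the 3-month edge still counts as engaged
  expect_false(is_unengaged(old, as.Date("2022-04-15"), pol, as_of))
  expect_true(is_unengaged(old, as.Date("2022-04-16"), pol, as_of))
})

test_that("registry generation is deterministic, sized, and empty at n = 0", {
  expect_equal(nrow(generate_registry(ref_registry_params(0, 1))), 0)
  a <- generate_registry(ref_registry_params(2000, 11))
  b <- generate_registry(ref_registry_params(2000, 11))
  expect_identical(a, b)
  c <- generate_registry(ref_registry_params(2000, 12))
  expect_false(identical(a, c))
  expect_equal(nrow(a), 2000)
  expect_true(all(c("patient_id", "hba1c", "last_pcp_visit_date",
                    "next_scheduled_visit_date", "payer", "diabetes_type")
                  %in% names(a)))
  expect_true(all(is.na(a$hba1c) | a$hba1c > 0))
})

test_that("generated unengaged proportion sits within binomial error of the composite rate", {
  n <- 10000
  reg <- generate_registry(ref_registry_params(n, 301))
  funnel <- aggregate_registry(reg, as_of = as.Date("2022-07-01"))
  p <- sum(ref_fractions * ref_overdue * ref_no_future)  # 0.22171 composite
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(funnel$unengaged[4] / n - p), 3 * se)
})

test_that("missing HbA1c patients land in the moderately controlled census", {
  reg <- generate_registry(ref_registry_params(5000, 5, missing = 0.05))
  expect_gt(sum(is.na(reg$hba1c)), 0)
  seg <- classify_control(reg$hba1c)
  expect_true(all(seg[is.na(reg$hba1c)] == "moderately_controlled"))
  # missing cannot exceed the moderate segment fraction
  expect_error(ref_registry_params(100, 1, missing = 0.5), "exceed")
})

test_that("record-level census counts single patients and scheduled cohorts exactly", {
  as_of <- as.Date("2022-07-01")
  one <- data.frame(patient_id = "P1", hba1c = 6.2,
                    last_pcp_visit_date = as.Date(NA),
                    next_scheduled_visit_date = as.Date(NA),
                    payer = "commercial", diabetes_type = "type2",
                    stringsAsFactors = FALSE)
  f <- aggregate_registry(one, as_of = as_of)
  expect_equal(unlist(f[f$segment == "controlled", 2:4]),
               c(population = 1, overdue = 1, unengaged = 1))

  # everyone has an appointment tomorrow -> nobody is unengaged
  reg <- generate_registry(ref_registry_params(500, 77))
  reg$next_scheduled_visit_date <- as_of + 1
  f2 <- aggregate_registry(reg, as_of = as_of)
  expect_equal(f2$unengaged[4], 0)
})

test_that("registry round-trips through CSV with ISO dates and blank absences", {
  reg <- generate_registry(ref_registry_params(300, 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(back, reg)
  first <- readLines(path, n = 2)
  expect_match(first[2], "\\d{4}-\\d{2}-\\d{2}|,,")
})
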