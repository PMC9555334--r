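test_that("value per appointment divides the margin, with an explicit zero guard", {
  expect_equal(value_per_appointment(1313177, 1796506, 209988, 2217),
               2899695 / 2217)
  expect_equal(value_per_appointment(100, 0, 100, 5), 0)
  expect_equal(value_per_appointment(0, 0, 0, 10), 0)
  expect_error(value_per_appointment(1, 1, 1, 0), "undefined")
})

test_that("the reference scenario reproduces the headline intermediates end to end", {
  res <- run_scenario(reference_config())
  expect_equal(res$funnel$unengaged[res$funnel$segment == "total"], 22171)
  expect_equal(res$engaged_total, 2217)
  expect_equal(round(res$compensation$annual), 209988)
  expect_equal(res$hospitalized, 757)
  wf <- res$waterfall
  expect_equal(wf$total_margin_annual,
               wf$professional_revenue_annual + wf$inpatient_revenue_annual -
                 wf$provider_compensation_annual)
  expect_gt(wf$professional_revenue_annual, wf$provider_compensation_annual)
  # deterministic: same config twice gives the identical waterfall
  res2 <- run_scenario(reference_config())
  expect_identical(res$waterfall, res2$waterfall)
})

test_that("zero uptake yields zero compensation and an explicit undefined value", {
  cfg <- reference_config()
  cfg <- set_model_parameter(cfg, "uptake_fraction", 0)
  cfg$inpatient$engaged_override <- NULL
  expect_warning(res <- run_scenario(cfg), "undefined")
  expect_equal(res$compensation$annual, 0)
  expect_equal(res$inpatient_revenue, 0)
  expect_true(is.na(res$waterfall$value_per_appointment))
})

test_that("roi relates margin to intervention cost", {
  expect_equal(roi(2899695, 1e6), 1.899695)
  expect_equal(roi(5e5, 5e5), 0)
  expect_equal(roi(0, 123), -1)
  wf <- run_scenario(reference_config())$waterfall
  expect_equal(roi(wf, 1e6), (wf$total_margin_annual - 1e6) / 1e6)
  expect_error(roi(1e6, 0), "positive")
})

test_that("unknown sensitivity parameters are rejected with the registry listed", {
  expect_error(one_way_sensitivity(reference_config(), "bogus", 0, 1),
               "uptake_fraction")
  expect_error(
    probabilistic_sensitivity(reference_config(),
                              list(bogus = list(dist = "point", value = 1)),
                              n_draws = 2),
    "registered")
})

test_that("per-visit value is structurally insensitive to uptake", {
  # professional revenue, compensation and inpatient margin all scale with
  # the engaged cohort, as does the attended denominator, so the per-visit
  # value cancels uptake exactly under exact arithmetic
  cfg <- reference_config()
  cfg$rounding <- rounding_policy("none")
  cfg$inpatient$count_rounding <- "none"
  res <- one_way_sensitivity(cfg, "uptake_fraction", 0.05, 0.20)
  expect_equal(res$value_low, res$value_high)
  # and the margin itself scales linearly: 4x uptake, 4x margin
  expect_equal(res$margin_high, 4 * res$margin_low)
})

test_that("one-way bounds order the value when the input is monotone", {
  res <- one_way_sensitivity(reference_config(), "hospitalization_rate",
                             0, 0.339)
  expect_lt(res$value_low, res$value_high)
  same <- one_way_sensitivity(reference_config(), "conversion_factor",
                              41.94, 41.94)
  expect_equal(same$value_low, same$value_high)
})

test_that("payer-share sensitivity renormalizes the mix", {
  cfg <- set_model_parameter(reference_config(), "payer_commercial", 0.5)
  mix <- unclass(cfg$payer_mix)
  expect_equal(sum(mix), 1)
  expect_equal(mix[["commercial"]], 0.5)
  expect_equal(mix[["medicare"]] / mix[["medicaid"]], 0.205 / 0.132)
})

test_that("point-mass PSA reproduces the deterministic scenario on every draw", {
  cfg <- reference_config()
  det <- run_scenario(strip_overrides_for_test(cfg))$waterfall
  psa <- probabilistic_sensitivity(
    cfg, list(uptake_fraction = list(dist = "point", value = 0.10)),
    n_draws = 5, seed = 3)
  expect_true(all(psa$draws$value_per_appointment ==
                    det$value_per_appointment))
})

test_that("PSA is reproducible for a fixed seed and leaves the RNG stream alone", {
  cfg <- reference_config()
  dists <- list(uptake_fraction = list(dist = "uniform", min = 0.05,
                                       max = 0.2),
                hospitalization_rate = list(dist = "triangular", min = 0.1,
                                            mode = 0.339, max = 0.45))
  set.seed(2024); before <- stats::runif(1)
  a <- probabilistic_sensitivity(cfg, dists, n_draws = 40, seed = 9)
  b <- probabilistic_sensitivity(cfg, dists, n_draws = 40, seed = 9)
  expect_identical(a$quantiles, b$quantiles)
  expect_identical(a$draws, b$draws)
  set.seed(2024); expect_identical(stats::runif(1), before)
})

test_that("a symmetric hospitalization-rate distribution below the fixed rate pulls the median down", {
  cfg <- reference_config()
  det <- run_scenario(cfg)$waterfall$value_per_appointment
  psa <- probabilistic_sensitivity(
    cfg, list(hospitalization_rate = list(dist = "uniform", min = 0,
                                          max = 0.339)),
    n_draws = 150, seed = 21)
  expect_lt(unname(psa$quantiles[["50%"]]), det)
})

test_that("invalid distribution specifications are named in the error", {
  cfg <- reference_config()
  expect_error(probabilistic_sensitivity(
    cfg, list(uptake_fraction = list(dist = "uniform", min = 1, max = 0)),
    n_draws = 2), "min <= max")
  expect_error(probabilistic_sensitivity(
    cfg, list(uptake_fraction = list(dist = "cauchy", scale = 1)),
    n_draws = 2), "unsupported")
  expect_error(probabilistic_sensitivity(
    cfg, list(uptake_fraction = list(dist = "beta", shape1 = -1,
                                     shape2 = 2)),
    n_draws = 2), "positive")
})
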