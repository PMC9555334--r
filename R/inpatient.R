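#' Inpatient-care parameters
#'
#' People with diabetes are hospitalized at roughly 339 per 1000 per year
#' (CDC national rate), and an engaged patient who returns to care brings
#' that expected inpatient margin with them. Per-payer reimbursements
#' default to the reference scenario's values: Medicare $2000 (CMS FY2023
#' national adjusted operating standardized amount, non-labor), Medicaid
#' $1280 (64% of Medicare, proportional to the office-visit ratio),
#' commercial $2700 (135% of Medicare).
#'
#' `mix_mode` resolves how admissions distribute across payers:
#' `payer_proportional` (default) weights reimbursements by the population
#' payer mix; `equal_thirds` averages the three rates. `rate_multiplier`
#' scales the hospitalization rate for scenario analysis (e.g. to model
#' engagement reducing admissions); default 1, i.e. the flat national rate.
#'
#' @param hospitalization_rate Annual admission probability; default 0.339.
#' @param reimbursement Named dollars per admission per payer.
#' @param mix_mode `"payer_proportional"` or `"equal_thirds"`.
#' @param count_rounding Rounding for the admission count; default `"floor"`.
#' @param engaged_override Optional count replacing the engaged cohort for
#'   the inpatient calculation only.
#' @param rate_multiplier Scalar on the hospitalization rate; default 1.
#' @return An object of class `inpatient_params`.
#' @export
inpatient_params <- function(hospitalization_rate = 0.339,
                             reimbursement = c(commercial = 2700,
                                               medicare = 2000,
                                               medicaid = 1280),
                             mix_mode = c("payer_proportional",
                                          "equal_thirds"),
                             count_rounding = c("floor", "half_up", "none"),
                             engaged_override = NULL,
                             rate_multiplier = 1) {
  mix_mode <- match.arg(mix_mode)
  count_rounding <- match.arg(count_rounding)
  errors <- character()
  if (hospitalization_rate < 0 || hospitalization_rate > 1)
    errors <- c(errors, "hospitalization_rate must be in [0, 1]")
  if (is.null(names(reimbursement)) || !setequal(names(reimbursement), PAYERS))
    errors <- c(errors, "reimbursement must be named over all payers")
  else if (any(reimbursement[PAYERS] < 0))
    errors <- c(errors, "reimbursements must be non-negative")
  if (rate_multiplier < 0)
    errors <- c(errors, "rate_multiplier must be non-negative")
  if (length(errors)) stop_validation(errors, "inpatient_params")
  structure(list(hospitalization_rate = hospitalization_rate,
                 reimbursement = reimbursement[PAYERS],
                 mix_mode = mix_mode, count_rounding = count_rounding,
                 engaged_override = engaged_override,
                 rate_multiplier = rate_multiplier),
            class = "inpatient_params")
}

#' Expected hospitalized patients in the engaged cohort
#'
#' `engaged * hospitalization_rate * rate_multiplier`, rounded per
#' `count_rounding` (default floor, matching the "approximately N patients"
#' planning convention).
#'
#' @param engaged Engaged patient count.
#' @param params An [inpatient_params()].
#' @return Admission count.
#' @export
#' @examples
#' hospitalized_count(2235, inpatient_params())  # floor(757.665) = 757
hospitalized_count <- function(engaged, params = inpatient_params()) {
  stopifnot(inherits(params, "inpatient_params"), engaged >= 0)
  apply_rounding(engaged * params$hospitalization_rate * params$rate_multiplier,
                 params$count_rounding)
}

#' Annual inpatient revenue
#'
#' Under `payer_proportional`, admissions are apportioned by the population
#' payer mix: `sum_payer hospitalized * mix(payer) * reimbursement(payer)`.
#' Under `equal_thirds`, each payer covers a third of admissions, i.e.
#' `hospitalized * mean(reimbursement)`. The two agree exactly whenever all
#' per-payer rates are equal. Dollars at full precision.
#'
#' @param hospitalized Admission count.
#' @param mix A [payer_mix()].
#' @param params An [inpatient_params()].
#' @return Dollars.
#' @export
inpatient_revenue <- function(hospitalized, mix,
                              params = inpatient_params()) {
  stopifnot(inherits(params, "inpatient_params"), hospitalized >= 0)
  if (!inherits(mix, "payer_mix")) mix <- payer_mix(mix)
  per_admission <- switch(params$mix_mode,
    payer_proportional = sum(unclass(mix) * params$reimbursement),
    equal_thirds = mean(params$reimbursement)
  )
  hospitalized * per_admission
}
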