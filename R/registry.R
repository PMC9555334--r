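#' Classify glycemic control from HbA1c
#'
#' HEDIS-style thresholds with half-open intervals: HbA1c < 7 is controlled,
#' 7 <= HbA1c < 9 moderately controlled, HbA1c >= 9 uncontrolled — boundary
#' values 7.0 and 9.0 classify upward. Patients with no recorded HbA1c are
#' treated as moderately controlled: their provider would order the test at
#' a first visit, and the 2-visit cadence is the sensible interim default.
#'
#' @param hba1c Numeric vector of HbA1c percentages (> 0), `NA` for absent.
#' @return Character vector of segment labels (see [control_segments()]).
#' @export
#' @examples
#' classify_control(c(6.9, 7.0, 8.9, 9.0, NA))
classify_control <- function(hba1c) {
  if (!is.numeric(hba1c) && !all(is.na(hba1c)))
    stop("hba1c must be numeric (NA for absent)", call. = FALSE)
  if (any(!is.na(hba1c) & hba1c <= 0))
    stop("hba1c values must be positive (use NA for absent)", call. = FALSE)
  out <- rep("moderately_controlled", length(hba1c))
  out[!is.na(hba1c) & hba1c < 7] <- "controlled"
  out[!is.na(hba1c) & hba1c >= 9] <- "uncontrolled"
  out
}

# Calendar-month subtraction anchored to the day of month, clamping to the
# end of shorter months (Jul 31 minus 5 months -> Feb 28/29). lubridate's
# rollback arithmetic implements exactly this convention.
months_before <- function(as_of, months) {
  lubridate::`%m-%`(as_of, lubridate::period(month = months))
}

months_after <- function(as_of, months) {
  lubridate::`%m+%`(as_of, lubridate::period(month = months))
}

#' Record-level engagement tests
#'
#' `is_overdue()` is `TRUE` when the last primary-care visit is strictly more
#' than the segment's lookback months before `as_of` (calendar-month
#' arithmetic, day-anchored with month-end clamping), or when no visit is on
#' record — a never-seen patient is maximally overdue. `is_unengaged()`
#' additionally requires that no visit is scheduled within the forward
#' window: `TRUE` when the patient is overdue and the next scheduled visit is
#' absent or strictly later than `as_of` plus `future_window_months`.
#'
#' Both functions are vectorised over dates; the policy supplies the
#' windows.
#'
#' @param last_visit_date,next_visit_date `Date` vectors, `NA` for absent.
#' @param policy A [segment_policy()].
#' @param as_of Evaluation (census) date.
#' @return Logical vector.
#' @export
#' @examples
#' pol <- default_policies()$controlled
#' is_overdue(as.Date("2021-01-15"), pol, as_of = as.Date("2022-01-15"))  # TRUE
#' is_overdue(as.Date("2021-02-15"), pol, as_of = as.Date("2022-01-15"))  # FALSE
is_overdue <- function(last_visit_date, policy, as_of) {
  stopifnot(inherits(policy, "segment_policy"), inherits(as_of, "Date"))
  cutoff <- months_before(as_of, policy$overdue_lookback_months)
  is.na(last_visit_date) | last_visit_date < cutoff
}

#' @rdname is_overdue
#' @export
is_unengaged <- function(last_visit_date, next_visit_date, policy, as_of) {
  window_end <- months_after(as_of, policy$future_window_months)
  is_overdue(last_visit_date, policy, as_of) &
    (is.na(next_visit_date) | next_visit_date > window_end)
}

#' Parameters for the synthetic registry generator
#'
#' Describes the EHR-style diabetes registry to simulate: size, segment
#' composition, per-segment engagement rates, payer mix, the fraction of
#' patients with no HbA1c on record, and the census date. The seed fully
#' determines the output.
#'
#' Patients without an HbA1c are classified moderately controlled, so the
#' missing fraction is carved out of the moderately-controlled segment and
#' must not exceed that segment's fraction.
#'
#' @param n_patients Number of records to generate.
#' @param segment_fractions,overdue_rate,no_future_visit_rate As in
#'   [cohort_spec()].
#' @param payer_mix A [payer_mix()] or named fraction vector.
#' @param missing_hba1c_fraction Fraction of all patients with no HbA1c value
#'   (default 0.05).
#' @param evaluation_date Census date for engagement status.
#' @param random_seed Integer seed.
#' @return An object of class `registry_params`.
#' @export
registry_params <- function(n_patients, segment_fractions, overdue_rate,
                            no_future_visit_rate, payer_mix,
                            missing_hba1c_fraction = 0.05,
                            evaluation_date = as.Date("2022-07-01"),
                            random_seed = 1L) {
  spec <- cohort_spec(n_patients, segment_fractions, overdue_rate,
                      no_future_visit_rate)
  if (!inherits(payer_mix, "payer_mix"))
    payer_mix <- payer_mix(payer_mix)
  errors <- character()
  if (missing_hba1c_fraction < 0 || missing_hba1c_fraction > 1)
    errors <- c(errors, "missing_hba1c_fraction must be in [0, 1]")
  if (missing_hba1c_fraction >
        spec$segment_fractions[["moderately_controlled"]] + 1e-12)
    errors <- c(errors, paste(
      "missing_hba1c_fraction cannot exceed the moderately_controlled",
      "segment fraction (missing HbA1c classifies as moderately controlled)"))
  if (!inherits(evaluation_date, "Date"))
    errors <- c(errors, "evaluation_date must be a Date")
  if (length(errors)) stop_validation(errors, "registry_params")
  structure(list(n_patients = as.integer(n_patients),
                 segment_fractions = spec$segment_fractions,
                 overdue_rate = spec$overdue_rate,
                 no_future_visit_rate = spec$no_future_visit_rate,
                 payer_mix = payer_mix,
                 missing_hba1c_fraction = missing_hba1c_fraction,
                 evaluation_date = evaluation_date,
                 random_seed = as.integer(random_seed)),
            class = "registry_params")
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic diabetes registry
#'
#' Simulates an EHR diabetes-registry extract: one row per patient with
#' HbA1c, last primary-care visit date, next scheduled visit date, payer and
#' diabetes type (gestational/medication-induced diabetes is excluded by
#' construction). Latent segment, overdue and no-future-visit statuses are
#' drawn per patient at the requested rates, and visit dates are then placed
#' inside or outside the segment's calendar windows so that the record-level
#' eligibility tests ([is_overdue()], [is_unengaged()]) recover exactly those
#' latent statuses. Marginal frequencies therefore converge to the requested
#' rates as `n_patients` grows (binomial sampling error only).
#'
#' Dates: overdue patients get a last visit uniformly in the year before the
#' lookback cutoff, or none at all (10% of the overdue); engaged-future
#' patients are scheduled uniformly within the forward window; unengaged
#' patients have no scheduled visit (80%) or one beyond the window. HbA1c is
#' reported to one decimal, uniform over each segment's band (9.0–13.0 for
#' uncontrolled). Payer is assigned independently of segment.
#'
#' @param params A [registry_params()].
#' @return A data.frame with columns `patient_id`, `hba1c`,
#'   `last_pcp_visit_date`, `next_scheduled_visit_date`, `payer`,
#'   `diabetes_type`; `NA` marks absent values. Deterministic for a fixed
#'   seed.
#' @export
#' @examples
#' p <- registry_params(500,
#'   c(controlled = 0.5, moderately_controlled = 0.355, uncontrolled = 0.145),
#'   c(controlled = 0.131, moderately_controlled = 0.298, uncontrolled = 0.611),
#'   c(controlled = 0.962, moderately_controlled = 0.867, uncontrolled = 0.756),
#'   c(commercial = 0.663, medicare = 0.205, medicaid = 0.132),
#'   random_seed = 42)
#' reg <- generate_registry(p)
#' head(reg)
generate_registry <- function(params) {
  stopifnot(inherits(params, "registry_params"))
  n <- params$n_patients
  if (n == 0) {
    return(data.frame(patient_id = character(), hba1c = numeric(),
                      last_pcp_visit_date = as.Date(character()),
                      next_scheduled_visit_date = as.Date(character()),
                      payer = character(), diabetes_type = character(),
                      stringsAsFactors = FALSE))
  }
  as_of <- params$evaluation_date
  policies <- default_policies()
  with_local_seed(params$random_seed, {
    segment <- sample(SEGMENTS, n, replace = TRUE,
                      prob = params$segment_fractions)
    # HbA1c to one decimal within each band; a share of the moderately
    # controlled carry no value (they classify there anyway)
    hba1c <- numeric(n)
    bands <- list(controlled = seq(5.0, 6.9, by = 0.1),
                  moderately_controlled = seq(7.0, 8.9, by = 0.1),
                  uncontrolled = seq(9.0, 13.0, by = 0.1))
    for (seg in SEGMENTS) {
      idx <- which(segment == seg)
      hba1c[idx] <- sample(bands[[seg]], length(idx), replace = TRUE)
    }
    f_mod <- params$segment_fractions[["moderately_controlled"]]
    if (params$missing_hba1c_fraction > 0 && f_mod > 0) {
      p_miss <- min(1, params$missing_hba1c_fraction / f_mod)
      mod_idx <- which(segment == "moderately_controlled")
      miss <- mod_idx[stats::runif(length(mod_idx)) < p_miss]
      hba1c[miss] <- NA_real_
    }

    overdue <- stats::runif(n) < params$overdue_rate[segment]
    no_future <- overdue & (stats::runif(n) <
                              params$no_future_visit_rate[segment])

    lookback <- vapply(policies, `[[`, integer(1),
                       "overdue_lookback_months")[segment]
    cutoff <- months_before(as_of, lookback)
    window_end <- months_after(as_of, policies[[1]]$future_window_months)

    last_visit <- rep(as_of, n)
    # overdue: strictly before the cutoff, within the prior year; 10% have
    # no visit on record at all
    never_seen <- overdue & stats::runif(n) < 0.10
    days_back <- 1L + floor(stats::runif(n) * 364)
    last_visit[overdue] <- cutoff[overdue] - days_back[overdue]
    # current: on or after the cutoff, up to the census date
    span <- as.numeric(as_of - cutoff)
    last_visit[!overdue] <- cutoff[!overdue] +
      floor(stats::runif(n) * (span + 1))[!overdue]
    last_visit[never_seen] <- NA

    next_visit <- rep(as.Date(NA), n)
    # overdue but engaged-future: scheduled inside the 3-month window
    sched_in <- overdue & !no_future
    win_span <- as.numeric(window_end - as_of)
    next_visit[sched_in] <- as_of + (1L + floor(stats::runif(n) * win_span))[sched_in]
    # unengaged: 20% scheduled, but beyond the window
    sched_far <- no_future & stats::runif(n) < 0.20
    next_visit[sched_far] <- window_end + (1L + floor(stats::runif(n) * 180))[sched_far]
    # non-overdue patients: half have some future appointment on the books
    sched_any <- !overdue & stats::runif(n) < 0.50
    next_visit[sched_any] <- as_of + (1L + floor(stats::runif(n) * 270))[sched_any]

    payer <- sample(PAYERS, n, replace = TRUE, prob = params$payer_mix)
    diabetes_type <- sample(c("type1", "type2"), n, replace = TRUE,
                            prob = c(0.05, 0.95))

    data.frame(
      patient_id = sprintf("P%07d", seq_len(n)),
      hba1c = hba1c,
      last_pcp_visit_date = last_visit,
      next_scheduled_visit_date = next_visit,
      payer = payer,
      diabetes_type = diabetes_type,
      stringsAsFactors = FALSE
    )
  })
}

#' Census a registry into an engagement funnel
#'
#' The record-level oracle for [engagement_funnel()]: classifies every record
#' by HbA1c, applies the segment's overdue and unengaged tests as of the
#' census date, and tabulates exact counts — no rounding is involved.
#'
#' @param records A registry data.frame as produced by [generate_registry()]
#'   or [read_registry()].
#' @param policies Named list of [segment_policy()] per segment
#'   (default [default_policies()]).
#' @param as_of Census date.
#' @return A `funnel_table` of exact counts.
#' @export
aggregate_registry <- function(records, policies = default_policies(),
                               as_of) {
  stopifnot(is.data.frame(records), inherits(as_of, "Date"))
  segment <- classify_control(records$hba1c)
  population <- overdue <- unengaged <- stats::setNames(numeric(3), SEGMENTS)
  for (seg in SEGMENTS) {
    idx <- segment == seg
    pol <- policies[[seg]]
    population[seg] <- sum(idx)
    od <- is_overdue(records$last_pcp_visit_date[idx], pol, as_of)
    un <- is_unengaged(records$last_pcp_visit_date[idx],
                       records$next_scheduled_visit_date[idx], pol, as_of)
    overdue[seg] <- sum(od)
    unengaged[seg] <- sum(un)
  }
  funnel_table(population, overdue, unengaged)
}

#' Read and write registry files
#'
#' Plain CSV with a header row, ISO-8601 dates and empty fields for absent
#' values; byte-stable across runs for identical input.
#'
#' @param records Registry data.frame.
#' @param path File path.
#' @return `read_registry()` returns the registry data.frame;
#'   `write_registry()` returns `path` invisibly.
#' @export
write_registry <- function(records, path) {
  out <- records
  out$last_pcp_visit_date <- format(out$last_pcp_visit_date, "%Y-%m-%d")
  out$next_scheduled_visit_date <- format(out$next_scheduled_visit_date,
                                          "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                   eol = "\n")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"),
                         na.strings = "")
  out$last_pcp_visit_date <- as.Date(out$last_pcp_visit_date)
  out$next_scheduled_visit_date <- as.Date(out$next_scheduled_visit_date)
  out
}
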