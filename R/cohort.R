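#' Segment visit policy
#'
#' Per-segment engagement rules following HEDIS control thresholds and the
#' ADA visit cadence: well-controlled patients are expected at 1 primary-care
#' visit per year, moderately controlled at 2, and uncontrolled at 4. A
#' patient is *overdue* when their last visit is strictly more than
#' `overdue_lookback_months` calendar months ago, and *unengaged* when, in
#' addition, no visit is scheduled within the next `future_window_months`
#' months.
#'
#' @param segment One of [control_segments()].
#' @param visits_per_year Recommended annual visits (1, 2 or 4).
#' @param overdue_lookback_months Months since last visit beyond which the
#'   patient is overdue (strict inequality).
#' @param future_window_months Scheduling window; default 3 months.
#' @return An object of class `segment_policy`.
#' @export
segment_policy <- function(segment, visits_per_year, overdue_lookback_months,
                           future_window_months = 3) {
  errors <- character()
  if (!is.character(segment) || length(segment) != 1 || !segment %in% SEGMENTS)
    errors <- c(errors, "segment must be one of control_segments()")
  if (!visits_per_year %in% c(1L, 2L, 4L))
    errors <- c(errors, "visits_per_year must be 1, 2 or 4")
  if (!is.numeric(overdue_lookback_months) || overdue_lookback_months <= 0)
    errors <- c(errors, "overdue_lookback_months must be a positive integer")
  if (!is.numeric(future_window_months) || future_window_months <= 0)
    errors <- c(errors, "future_window_months must be positive")
  if (length(errors)) stop_validation(errors, "segment_policy")
  structure(list(segment = segment,
                 visits_per_year = as.integer(visits_per_year),
                 overdue_lookback_months = as.integer(overdue_lookback_months),
                 future_window_months = as.integer(future_window_months)),
            class = "segment_policy")
}

#' Default visit policies by control segment
#'
#' The guideline cadence: controlled 1 visit/yr with an 11-month lookback,
#' moderately controlled 2 visits/yr with a 5-month lookback, uncontrolled
#' 4 visits/yr with a 2-month lookback; a 3-month forward scheduling window
#' for all segments. The lookback is one inter-visit interval minus one
#' month, so a patient becomes overdue one month before their next
#' recommended visit would be due.
#'
#' @param future_window_months Forward scheduling window (months).
#' @return Named list of [segment_policy()] objects, one per segment.
#' @export
#' @examples
#' default_policies()$uncontrolled$visits_per_year  # 4
default_policies <- function(future_window_months = 3) {
  list(
    controlled = segment_policy("controlled", 1L, 11L, future_window_months),
    moderately_controlled =
      segment_policy("moderately_controlled", 2L, 5L, future_window_months),
    uncontrolled = segment_policy("uncontrolled", 4L, 2L, future_window_months)
  )
}

#' Aggregate cohort specification
#'
#' Describes a diabetes population at the count level: total size, the split
#' across HbA1c control segments, and per-segment engagement rates (fraction
#' overdue for a visit; fraction of the overdue with no visit scheduled in
#' the forward window).
#'
#' @param total_population Non-negative patient count.
#' @param segment_fractions Named fractions over [control_segments()],
#'   summing to 1 (tolerance 1e-9).
#' @param overdue_rate,no_future_visit_rate Named per-segment rates in
#'   \[0, 1\].
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(100000,
#'   segment_fractions = c(controlled = 0.50, moderately_controlled = 0.355,
#'                         uncontrolled = 0.145),
#'   overdue_rate = c(controlled = 0.131, moderately_controlled = 0.298,
#'                    uncontrolled = 0.611),
#'   no_future_visit_rate = c(controlled = 0.962,
#'                            moderately_controlled = 0.867,
#'                            uncontrolled = 0.756))
cohort_spec <- function(total_population, segment_fractions, overdue_rate,
                        no_future_visit_rate) {
  errors <- character()
  if (!is.numeric(total_population) || length(total_population) != 1 ||
      !is.finite(total_population) || total_population < 0)
    errors <- c(errors, "total_population must be a non-negative count")
  chk <- check_named_fractions(segment_fractions, SEGMENTS,
                               "segment_fractions", errors, must_sum = TRUE)
  segment_fractions <- chk$x; errors <- chk$errors
  chk <- check_named_fractions(overdue_rate, SEGMENTS, "overdue_rate", errors)
  overdue_rate <- chk$x; errors <- chk$errors
  chk <- check_named_fractions(no_future_visit_rate, SEGMENTS,
                               "no_future_visit_rate", errors)
  no_future_visit_rate <- chk$x; errors <- chk$errors
  if (length(errors)) stop_validation(errors, "cohort_spec")
  structure(list(total_population = total_population,
                 segment_fractions = segment_fractions,
                 overdue_rate = overdue_rate,
                 no_future_visit_rate = no_future_visit_rate),
            class = "cohort_spec")
}

#' Payer mix
#'
#' Fractional insurance coverage split across commercial, Medicare and
#' Medicaid; must sum to 1.
#'
#' @param fractions Named numeric over [payer_levels()], summing to 1.
#' @return An object of class `payer_mix` (a validated named vector).
#' @export
#' @examples
#' payer_mix(c(commercial = 0.663, medicare = 0.205, medicaid = 0.132))
payer_mix <- function(fractions) {
  chk <- check_named_fractions(fractions, PAYERS, "payer mix fractions",
                               must_sum = TRUE)
  if (length(chk$errors)) stop_validation(chk$errors, "payer_mix")
  structure(chk$x, class = "payer_mix")
}

#' Split a total population across control segments
#'
#' Each segment count is `rounded(total * fraction)` under the given policy.
#' Because segments are rounded independently, the counts can sum to one
#' more or less than `total` when several products tie at .5; this mirrors
#' how health-system planning tables are typically built and is the
#' replication default.
#'
#' @param total Non-negative population count.
#' @param fractions Named segment fractions summing to 1.
#' @param rounding A [rounding_policy()] or mode string.
#' @return Named numeric vector of per-segment counts.
#' @export
#' @examples
#' segment_counts(100000, c(controlled = 0.50, moderately_controlled = 0.355,
#'                          uncontrolled = 0.145))
segment_counts <- function(total, fractions, rounding = rounding_policy()) {
  chk <- check_named_fractions(fractions, SEGMENTS, "segment_fractions",
                               must_sum = TRUE)
  if (length(chk$errors)) stop_validation(chk$errors, "segment_counts")
  if (!is.numeric(total) || length(total) != 1 || total < 0)
    stop("total must be a non-negative count", call. = FALSE)
  apply_rounding(total * chk$x, rounding)
}

#' Engagement funnel: population, overdue, unengaged per segment
#'
#' Applies the three-stage eligibility funnel at the count level: segment
#' populations, then the overdue subset (`population * overdue_rate`), then
#' the unengaged subset (`overdue * no_future_visit_rate`). Rounding is
#' applied at each stage in sequence, so each rounded count feeds the next
#' multiplication — the convention under which the reference scenario's
#' published-style tables reproduce integer for integer.
#'
#' @param spec A [cohort_spec()].
#' @param rounding A [rounding_policy()] or mode string.
#' @return A `funnel_table`: data.frame with columns `segment`, `population`,
#'   `overdue`, `unengaged`; one row per segment plus a `total` row.
#' @export
#' @examples
#' spec <- cohort_spec(100000,
#'   c(controlled = 0.50, moderately_controlled = 0.355, uncontrolled = 0.145),
#'   c(controlled = 0.131, moderately_controlled = 0.298, uncontrolled = 0.611),
#'   c(controlled = 0.962, moderately_controlled = 0.867, uncontrolled = 0.756))
#' engagement_funnel(spec)
engagement_funnel <- function(spec, rounding = rounding_policy()) {
  stopifnot(inherits(spec, "cohort_spec"))
  population <- segment_counts(spec$total_population, spec$segment_fractions,
                               rounding)
  overdue <- apply_rounding(population * spec$overdue_rate, rounding)
  unengaged <- apply_rounding(overdue * spec$no_future_visit_rate, rounding)
  funnel_table(population, overdue, unengaged)
}

# Shared constructor for count-level and census funnels.
funnel_table <- function(population, overdue, unengaged) {
  out <- data.frame(
    segment = c(SEGMENTS, "total"),
    population = c(population, sum(population)),
    overdue = c(overdue, sum(overdue)),
    unengaged = c(unengaged, sum(unengaged)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("funnel_table", "data.frame")
  out
}

#' @export
print.funnel_table <- function(x, ...) {
  cat("Engagement funnel (patients)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Split a count across payers
#'
#' Two modes. In replication mode (`apportion = FALSE`, the default) each
#' payer count is rounded independently, so the three counts can differ from
#' the input by up to (payers - 1); e.g. 14,500 at a 66.3/20.5/13.2 mix
#' gives 9614 + 2973 + 1914 = 14,501. With `apportion = TRUE` the
#' largest-remainder (Hamilton) method is used and the counts sum exactly to
#' the input.
#'
#' @param count Non-negative count to split.
#' @param mix A [payer_mix()] or named fraction vector.
#' @param rounding A [rounding_policy()] or mode string (ignored when
#'   apportioning, which is inherently integral).
#' @param apportion Use exact largest-remainder apportionment.
#' @return Named numeric vector of per-payer counts.
#' @export
#' @examples
#' mix <- payer_mix(c(commercial = 0.663, medicare = 0.205, medicaid = 0.132))
#' payer_split(14500, mix)                    # 9614 2973 1914 (sums to 14501)
#' payer_split(14500, mix, apportion = TRUE)  # sums to exactly 14500
payer_split <- function(count, mix, rounding = rounding_policy(),
                        apportion = FALSE) {
  if (!inherits(mix, "payer_mix")) mix <- payer_mix(mix)
  if (!is.numeric(count) || length(count) != 1 || count < 0)
    stop("count must be a non-negative scalar", call. = FALSE)
  if (!apportion) return(apply_rounding(count * unclass(mix), rounding))
  exact <- count * unclass(mix)
  base <- floor(exact + 1e-9)
  short <- round(count) - sum(base)
  if (short > 0) {
    # hand leftover units to the largest fractional remainders; ties go to
    # the earlier payer in canonical order (stable)
    rem <- exact - base
    extra <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}
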