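#' Patients allocated to a service code
#'
#' The share of a payer's patient count expected to receive a given service,
#' `rounded(payer_count * allocation)`.
#'
#' @param payer_count Non-negative patient count for one payer.
#' @param entry One catalog row (or a bare allocation fraction).
#' @param rounding A [rounding_policy()] or mode string.
#' @return Allocated patient count.
#' @export
#' @examples
#' allocate_patients(9614, 0.44)  # 4230 lipid panels
allocate_patients <- function(payer_count, entry, rounding = rounding_policy()) {
  allocation <- if (is.numeric(entry)) entry else entry$allocation
  stopifnot(payer_count >= 0, allocation >= 0, allocation <= 1)
  apply_rounding(payer_count * allocation, rounding)
}

#' Annual service volume
#'
#' Services billed per year: allocated patients receive the service at every
#' recommended visit (so a 4-visit cadence bills the code four times a
#' year). Codes flagged `per_year` in the catalog bill once regardless of
#' cadence.
#'
#' @param allocated Allocated patient count.
#' @param visits_per_year Recommended visits for the segment.
#' @return Service count.
#' @export
annual_service_volume <- function(allocated, visits_per_year) {
  stopifnot(allocated >= 0, visits_per_year >= 0)
  allocated * visits_per_year
}

#' Annual professional-practice revenue for one segment
#'
#' Splits the segment population across payers, allocates each payer's
#' patients to every catalog code, multiplies by the segment's annual visit
#' cadence and the payer's fee. Bundled and non-covered (payer, code) cells
#' contribute zero revenue but retain their allocated patient counts.
#' Dollar amounts are carried at full precision and never re-rounded when
#' summed; totals are exact sums of cells.
#'
#' @param segment_population Patient count forming the billing base.
#' @param mix A [payer_mix()].
#' @param catalog A [cpt_catalog()].
#' @param fees A [fee_schedule()]; must cover every payable (payer, code)
#'   pair or an error names the gap.
#' @param policy The segment's [segment_policy()] (supplies the cadence).
#' @param rounding A [rounding_policy()] or mode string.
#' @param apportion Use exact payer apportionment (see [payer_split()]).
#' @return A `revenue_table`: data.frame with one row per (payer, code) —
#'   columns `payer`, `code_key`, `status`, `allocated_patients`,
#'   `services_per_year`, `revenue` — with attributes `payer_totals` (named
#'   vector) and `grand_total`.
#' @export
professional_revenue <- function(segment_population, mix, catalog, fees,
                                 policy, rounding = rounding_policy(),
                                 apportion = FALSE) {
  stopifnot(inherits(policy, "segment_policy"))
  if (!inherits(catalog, "cpt_catalog")) catalog <- cpt_catalog(catalog)
  if (!inherits(fees, "fee_schedule")) fees <- fee_schedule(fees)
  counts <- payer_split(segment_population, mix, rounding, apportion)
  rows <- vector("list", length(PAYERS))
  for (i in seq_along(PAYERS)) {
    payer <- PAYERS[i]
    fee <- fees_for_payer(fees, payer, catalog)
    status <- catalog[[paste0("payable_", payer)]]
    allocated <- allocate_patients(counts[[payer]], catalog, rounding)
    visits <- ifelse(catalog$billing == "per_year", 1L,
                     policy$visits_per_year)
    services <- annual_service_volume(allocated, visits)
    unit <- ifelse(status == "payable", fee[catalog$code_key], 0)
    unit[is.na(unit)] <- 0
    rows[[i]] <- data.frame(
      payer = payer, code_key = catalog$code_key, status = status,
      allocated_patients = allocated, services_per_year = services,
      revenue = services * unit, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  payer_totals <- vapply(PAYERS, function(p) sum(out$revenue[out$payer == p]),
                         numeric(1))
  attr(out, "payer_totals") <- payer_totals
  attr(out, "grand_total") <- sum(payer_totals)
  attr(out, "segment") <- policy$segment
  class(out) <- c("revenue_table", "data.frame")
  out
}

#' @export
print.revenue_table <- function(x, ...) {
  cat(sprintf("Professional revenue — segment: %s\n",
              attr(x, "segment") %||% "?"))
  df <- as.data.frame(x)
  df$revenue <- format_dollars(df$revenue)
  print.data.frame(df, row.names = FALSE)
  tot <- attr(x, "payer_totals")
  cat("Payer totals:",
      paste(sprintf("%s %s", names(tot), format_dollars(tot)),
            collapse = ", "), "\n")
  cat("Grand total:", format_dollars(attr(x, "grand_total")), "\n")
  invisible(x)
}

# Whole-dollar presentation with thousands separators; storage stays at full
# precision.
format_dollars <- function(x) {
  paste0("$", formatC(round(x), format = "d", big.mark = ","))
}
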