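#' Service (CPT-style) catalog
#'
#' The catalog lists what can be billed at a diabetes primary-care visit:
#' one row per service code with a description, an allocation fraction (the
#' comorbidity-derived share of patients expected to receive the service at
#' a visit — e.g. 44% of patients with diabetes need a lipid panel, from the
#' national hypercholesterolemia rate), an optional provider work RVU, a
#' billing cadence, and a payability status per payer:
#'
#' * `payable` — reimbursed separately at the fee-schedule rate;
#' * `bundled` — included in the office-visit payment, zero separate revenue
#'   (urinalysis and the diabetic foot examination are bundled for all
#'   payers);
#' * `not_covered` — the payer does not reimburse the service at all.
#'
#' Codes are opaque keys with free-text descriptions; no authoritative CPT
#' text is shipped.
#'
#' @param df A data.frame with columns `code_key`, `description`,
#'   `allocation`, `work_rvu` (NA when the code carries no provider RVU),
#'   `billing` (`"per_visit"` or `"per_year"`), and
#'   `payable_commercial`, `payable_medicare`, `payable_medicaid`.
#' @return A validated `cpt_catalog` data.frame.
#' @export
cpt_catalog <- function(df) {
  required <- c("code_key", "description", "allocation", "work_rvu",
                "billing", paste0("payable_", PAYERS))
  errors <- character()
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    errors <- c(errors, paste("missing catalog columns:",
                              paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols)) {
    if (anyDuplicated(df$code_key))
      errors <- c(errors, "duplicate code_key values")
    if (any(df$allocation < 0 | df$allocation > 1))
      errors <- c(errors, "allocation fractions must lie in [0, 1]")
    if (any(!is.na(df$work_rvu) & df$work_rvu < 0))
      errors <- c(errors, "work_rvu must be non-negative or NA")
    if (!all(df$billing %in% c("per_visit", "per_year")))
      errors <- c(errors, "billing must be 'per_visit' or 'per_year'")
    for (p in PAYERS) {
      col <- df[[paste0("payable_", p)]]
      if (!all(col %in% c("payable", "bundled", "not_covered")))
        errors <- c(errors, sprintf(
          "payable_%s must be one of payable/bundled/not_covered", p))
    }
  }
  if (length(errors)) stop_validation(errors, "cpt_catalog")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("cpt_catalog", "data.frame")
  df
}

#' @rdname cpt_catalog
#' @param path CSV file with the columns above (`work_rvu` empty for NA).
#' @export
read_cpt_catalog <- function(path) {
  cpt_catalog(utils::read.csv(path, stringsAsFactors = FALSE,
                              na.strings = ""))
}

#' @rdname cpt_catalog
#' @export
write_cpt_catalog <- function(df, path) {
  out <- as.data.frame(df)
  out$allocation <- format(out$allocation, digits = 17, scientific = FALSE,
                           trim = TRUE)
  out$work_rvu <- ifelse(is.na(out$work_rvu), "",
                         format(out$work_rvu, digits = 17,
                                scientific = FALSE, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                   eol = "\n")
  invisible(path)
}

#' Per-payer fee schedule
#'
#' Dollars reimbursed per service, keyed by (payer, code). Fees must be
#' defined for every (payer, code) pair the catalog marks `payable`; bundled
#' and non-covered pairs need no fee. Typical provenance, recorded in
#' `provenance_note`: Medicare from the regional MAC (e.g. Palmetto GBA)
#' schedule, Medicaid from the state schedule, commercial as a multiple
#' (~135%) of Medicare.
#'
#' @param df Data.frame with columns `payer`, `code_key`, `fee_usd`.
#' @param provenance_note Optional named character vector (per payer)
#'   documenting where each schedule came from.
#' @return A validated `fee_schedule` data.frame.
#' @export
fee_schedule <- function(df, provenance_note = NULL) {
  errors <- character()
  required <- c("payer", "code_key", "fee_usd")
  if (!all(required %in% names(df))) {
    errors <- c(errors, paste("fee schedule needs columns:",
                              paste(required, collapse = ", ")))
  } else {
    if (!all(df$payer %in% PAYERS))
      errors <- c(errors, "payer must be commercial/medicare/medicaid")
    if (any(!is.finite(df$fee_usd) | df$fee_usd < 0))
      errors <- c(errors, "fees must be non-negative dollars")
    if (anyDuplicated(df[c("payer", "code_key")]))
      errors <- c(errors, "duplicate (payer, code_key) fee entries")
  }
  if (length(errors)) stop_validation(errors, "fee_schedule")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  attr(df, "provenance_note") <- provenance_note
  class(df) <- c("fee_schedule", "data.frame")
  df
}

#' @rdname fee_schedule
#' @param path CSV file with columns `payer`, `code_key`, `fee_usd`.
#' @export
read_fee_schedule <- function(path) {
  fee_schedule(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname fee_schedule
#' @export
write_fee_schedule <- function(df, path) {
  out <- as.data.frame(df)
  out$fee_usd <- format(out$fee_usd, digits = 17, scientific = FALSE,
                        trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

# Fee lookup: named vector fee[code] for one payer; stops naming the payer
# and code when a payable pair has no fee.
fees_for_payer <- function(fees, payer, catalog) {
  sub <- fees[fees$payer == payer, , drop = FALSE]
  lookup <- stats::setNames(sub$fee_usd, sub$code_key)
  payable <- catalog$code_key[catalog[[paste0("payable_", payer)]] == "payable"]
  missing <- setdiff(payable, names(lookup))
  if (length(missing))
    stop(sprintf("fee schedule is missing payable entries for payer '%s': %s",
                 payer, paste(missing, collapse = ", ")), call. = FALSE)
  lookup
}
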