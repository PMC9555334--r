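#' Uptake parameters
#'
#' The fraction of the unengaged population expected to actually attend a
#' primary-care visit in response to outreach. The default, 10%, is a
#' conservative engagement rate for digital nudging interventions.
#' `engaged_override`, when set, replaces the computed engaged count — useful
#' for pinning the cohort to an externally supplied figure.
#'
#' @param uptake_fraction Fraction in \[0, 1\]; default 0.10.
#' @param engaged_override Optional count overriding the computed cohort.
#' @return An object of class `uptake_params`.
#' @export
uptake_params <- function(uptake_fraction = 0.10, engaged_override = NULL) {
  errors <- character()
  if (!is.numeric(uptake_fraction) || uptake_fraction < 0 ||
      uptake_fraction > 1)
    errors <- c(errors, "uptake_fraction must be in [0, 1]")
  if (!is.null(engaged_override) &&
      (!is.numeric(engaged_override) || engaged_override < 0))
    errors <- c(errors, "engaged_override must be a non-negative count")
  if (length(errors)) stop_validation(errors, "uptake_params")
  structure(list(uptake_fraction = uptake_fraction,
                 engaged_override = engaged_override),
            class = "uptake_params")
}

#' Engaged cohort size
#'
#' `rounded(unengaged_total * uptake_fraction)`, unless an override is set.
#'
#' @param unengaged_total Unengaged patient count (funnel total).
#' @param uptake An [uptake_params()].
#' @param rounding A [rounding_policy()] or mode string.
#' @return Engaged patient count.
#' @export
#' @examples
#' engaged_cohort(22171, uptake_params(0.10))  # 2217
engaged_cohort <- function(unengaged_total, uptake = uptake_params(),
                           rounding = rounding_policy()) {
  stopifnot(inherits(uptake, "uptake_params"), unengaged_total >= 0)
  if (!is.null(uptake$engaged_override)) return(uptake$engaged_override)
  apply_rounding(unengaged_total * uptake$uptake_fraction, rounding)
}

#' Provider work-RVU totals for the engaged cohort
#'
#' For every RVU-bearing catalog code, the engaged patients allocated to the
#' code times its work RVU. Codes without a work RVU (lab work the provider
#' does not personally perform) contribute nothing. The RVU basis is annual.
#'
#' @param engaged Engaged patient count.
#' @param catalog A [cpt_catalog()].
#' @param rounding A [rounding_policy()] or mode string (applied to the
#'   allocated counts, as in the revenue engine).
#' @return Named numeric vector of RVU components per RVU-bearing code.
#' @export
rvu_totals <- function(engaged, catalog, rounding = rounding_policy()) {
  if (!inherits(catalog, "cpt_catalog")) catalog <- cpt_catalog(catalog)
  stopifnot(engaged >= 0)
  bearing <- catalog[!is.na(catalog$work_rvu), , drop = FALSE]
  allocated <- allocate_patients(engaged, bearing, rounding)
  stats::setNames(allocated * bearing$work_rvu, bearing$code_key)
}

#' Provider compensation from RVUs
#'
#' Annual compensation is the RVU total times the dollar conversion factor
#' (default in the reference scenario: the MGMA median, $41.94/RVU); monthly
#' is one twelfth. Dollars are carried at full precision and presented
#' rounded to the dollar.
#'
#' @param rvu_total Total annual work RVUs (or the vector of components,
#'   which will be summed).
#' @param conversion_factor Dollars per RVU.
#' @return An object of class `compensation_result` with fields
#'   `rvu_components`, `rvu_total`, `conversion_factor`, `annual`, `monthly`.
#' @export
#' @examples
#' provider_compensation(5006.87, 41.94)
provider_compensation <- function(rvu_total, conversion_factor) {
  stopifnot(all(rvu_total >= 0), conversion_factor >= 0)
  components <- if (length(rvu_total) > 1 || !is.null(names(rvu_total)))
    rvu_total else NULL
  total <- sum(rvu_total)
  annual <- total * conversion_factor
  structure(list(rvu_components = components, rvu_total = total,
                 conversion_factor = conversion_factor,
                 annual = annual, monthly = annual / 12),
            class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  cat("Provider compensation\n")
  if (!is.null(x$rvu_components)) {
    for (k in names(x$rvu_components))
      cat(sprintf("  %-28s %10.2f RVU\n", k, x$rvu_components[[k]]))
  }
  cat(sprintf("  RVU total: %.2f  x  $%.2f/RVU\n", x$rvu_total,
              x$conversion_factor))
  cat(sprintf("  Annual: %s   Monthly: %s\n", format_dollars(x$annual),
              format_dollars(x$monthly)))
  invisible(x)
}
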