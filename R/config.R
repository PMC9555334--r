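#' Full model configuration
#'
#' Bundles every input the scenario engine needs. Usually built by
#' [load_config()] from a YAML file; the constructor validates an in-memory
#' assembly and reports *all* failures at once, not just the first.
#'
#' @param cohort A [cohort_spec()].
#' @param policies Named list of [segment_policy()] per segment.
#' @param payer_mix A [payer_mix()].
#' @param catalog A [cpt_catalog()].
#' @param fees A [fee_schedule()].
#' @param uptake An [uptake_params()].
#' @param conversion_factor Dollars per work RVU.
#' @param inpatient An [inpatient_params()].
#' @param rounding A [rounding_policy()] or mode string.
#' @param revenue_basis Billing base for professional revenue:
#'   `"engaged"` (default), `"unengaged"` or `"full_population"`.
#' @param attended_basis `"engaged_patients"` (default: one valued
#'   appointment per engaged patient per year) or `"engaged_visits"`
#'   (engaged patients times their segment cadence).
#' @param fee_scale Global multiplier on the fee schedule; default 1.
#' @param apportion Use exact payer apportionment in splits; default FALSE.
#' @param catalog_path,fee_schedule_path Optional source-file paths,
#'   retained for [write_config()].
#' @return An object of class `model_config`.
#' @export
model_config <- function(cohort, policies = default_policies(), payer_mix,
                         catalog, fees, uptake = uptake_params(),
                         conversion_factor, inpatient = inpatient_params(),
                         rounding = rounding_policy(),
                         revenue_basis = c("engaged", "unengaged",
                                           "full_population"),
                         attended_basis = c("engaged_patients",
                                            "engaged_visits"),
                         fee_scale = 1, apportion = FALSE,
                         catalog_path = NULL, fee_schedule_path = NULL) {
  revenue_basis <- match.arg(revenue_basis)
  attended_basis <- match.arg(attended_basis)
  errors <- character()
  if (!inherits(cohort, "cohort_spec"))
    errors <- c(errors, "cohort must be a cohort_spec")
  if (!is.list(policies) || !setequal(names(policies), SEGMENTS) ||
      !all(vapply(policies, inherits, logical(1), "segment_policy")))
    errors <- c(errors, "policies must be a segment_policy per segment")
  if (!inherits(payer_mix, "payer_mix"))
    errors <- c(errors, "payer_mix must be a payer_mix")
  if (!inherits(catalog, "cpt_catalog"))
    errors <- c(errors, "catalog must be a cpt_catalog")
  if (!inherits(fees, "fee_schedule"))
    errors <- c(errors, "fees must be a fee_schedule")
  if (!inherits(uptake, "uptake_params"))
    errors <- c(errors, "uptake must be uptake_params")
  if (!is.numeric(conversion_factor) || conversion_factor < 0)
    errors <- c(errors, "conversion_factor must be non-negative dollars/RVU")
  if (!inherits(inpatient, "inpatient_params"))
    errors <- c(errors, "inpatient must be inpatient_params")
  if (!is.numeric(fee_scale) || fee_scale < 0)
    errors <- c(errors, "fee_scale must be non-negative")
  rounding <- tryCatch(as_rounding_policy(rounding), error = function(e) {
    errors <<- c(errors, conditionMessage(e)); NULL
  })
  if (length(errors)) stop_validation(errors, "model_config")
  structure(list(cohort = cohort, policies = policies[SEGMENTS],
                 payer_mix = payer_mix, catalog = catalog, fees = fees,
                 uptake = uptake, conversion_factor = conversion_factor,
                 inpatient = inpatient, rounding = rounding,
                 revenue_basis = revenue_basis,
                 attended_basis = attended_basis, fee_scale = fee_scale,
                 apportion = apportion, catalog_path = catalog_path,
                 fee_schedule_path = fee_schedule_path),
            class = "model_config")
}

# Coerce a YAML map (list) to a named numeric vector.
yaml_fractions <- function(x) {
  if (is.null(x)) return(NULL)
  vapply(x, as.numeric, numeric(1))
}

#' Load and validate a model configuration from YAML
#'
#' Reads a structured configuration file, resolves the catalog and
#' fee-schedule CSV paths relative to the configuration file's directory,
#' fills documented defaults for omitted optional fields (logging each
#' default via `message()`), and validates everything. Semantic failures
#' are aggregated: the error lists every problem found, and no partially
#' constructed configuration escapes a failed load.
#'
#' @param path Path to a YAML configuration file.
#' @param quiet Suppress defaulting messages.
#' @return A validated `model_config`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "reference_config.yaml",
#'                                package = "dpcvalue"))
#' cfg$uptake$uptake_fraction  # 0.10
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  errors <- character()
  note <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  grab <- function(expr) tryCatch(expr, error = function(e) {
    errors <<- c(errors, conditionMessage(e)); NULL
  })

  cohort <- grab({
    co <- raw$cohort
    if (is.null(co)) stop("missing 'cohort' section", call. = FALSE)
    cohort_spec(co$total_population, yaml_fractions(co$segment_fractions),
                yaml_fractions(co$overdue_rate),
                yaml_fractions(co$no_future_visit_rate))
  })
  mix <- grab({
    if (is.null(raw$payer_mix)) stop("missing 'payer_mix' section",
                                     call. = FALSE)
    payer_mix(yaml_fractions(raw$payer_mix))
  })
  policies <- grab({
    if (is.null(raw$policies)) {
      note("policies not specified; using guideline defaults (1/2/4 visits)")
      default_policies()
    } else {
      out <- lapply(SEGMENTS, function(s) {
        p <- raw$policies[[s]]
        if (is.null(p)) stop(sprintf("policies section missing segment '%s'", s),
                             call. = FALSE)
        segment_policy(s, p$visits_per_year, p$overdue_lookback_months,
                       p$future_window_months %||% 3)
      })
      stats::setNames(out, SEGMENTS)
    }
  })
  resolve <- function(p) if (!is.null(p) && !file.exists(p))
    file.path(dir, p) else p
  catalog_path <- resolve(raw$catalog_path)
  fee_path <- resolve(raw$fee_schedule_path)
  catalog <- grab({
    if (is.null(catalog_path)) stop("missing 'catalog_path'", call. = FALSE)
    read_cpt_catalog(catalog_path)
  })
  fees <- grab({
    if (is.null(fee_path)) stop("missing 'fee_schedule_path'", call. = FALSE)
    read_fee_schedule(fee_path)
  })
  uptake <- grab({
    if (is.null(raw$uptake)) {
      note("uptake not specified; defaulting to 10%% attendance")
      uptake_params()
    } else {
      uptake_params(raw$uptake$uptake_fraction %||% 0.10,
                    raw$uptake$engaged_override)
    }
  })
  conversion_factor <- grab({
    if (is.null(raw$conversion_factor))
      stop("missing 'conversion_factor' (dollars per RVU)", call. = FALSE)
    as.numeric(raw$conversion_factor)
  })
  inpatient <- grab({
    ip <- raw$inpatient
    if (is.null(ip)) {
      note("inpatient section not specified; using national-rate defaults")
      inpatient_params()
    } else {
      inpatient_params(
        hospitalization_rate = ip$hospitalization_rate %||% 0.339,
        reimbursement = if (is.null(ip$reimbursement))
          c(commercial = 2700, medicare = 2000, medicaid = 1280)
          else yaml_fractions(ip$reimbursement) * 1,
        mix_mode = ip$mix_mode %||% "payer_proportional",
        count_rounding = ip$count_rounding %||% "floor",
        engaged_override = ip$engaged_override,
        rate_multiplier = ip$rate_multiplier %||% 1)
    }
  })
  rounding <- grab({
    if (is.null(raw$rounding)) {
      note("rounding not specified; defaulting to half_up")
      rounding_policy("half_up")
    } else as_rounding_policy(raw$rounding)
  })
  if (length(errors)) stop_validation(errors, sprintf("config '%s'", path))
  model_config(cohort = cohort, policies = policies, payer_mix = mix,
               catalog = catalog, fees = fees, uptake = uptake,
               conversion_factor = conversion_factor, inpatient = inpatient,
               rounding = rounding,
               revenue_basis = raw$revenue_basis %||% "engaged",
               attended_basis = raw$attended_basis %||% "engaged_patients",
               fee_scale = raw$fee_scale %||% 1,
               apportion = raw$apportion %||% FALSE,
               catalog_path = catalog_path, fee_schedule_path = fee_path)
}

#' Write a model configuration back to YAML
#'
#' Serialises the scalar configuration (the catalog and fee schedule stay in
#' their CSV files, referenced by path). A written configuration reloads to
#' an equivalent in-memory structure.
#'
#' @param config A `model_config` whose `catalog_path`/`fee_schedule_path`
#'   are set.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(config$catalog_path) || is.null(config$fee_schedule_path))
    stop("config has no catalog/fee file paths to reference", call. = FALSE)
  as_map <- function(x) as.list(stats::setNames(as.numeric(x), names(x)))
  out <- list(
    cohort = list(
      total_population = config$cohort$total_population,
      segment_fractions = as_map(config$cohort$segment_fractions),
      overdue_rate = as_map(config$cohort$overdue_rate),
      no_future_visit_rate = as_map(config$cohort$no_future_visit_rate)),
    payer_mix = as_map(config$payer_mix),
    policies = lapply(config$policies, function(p)
      list(visits_per_year = p$visits_per_year,
           overdue_lookback_months = p$overdue_lookback_months,
           future_window_months = p$future_window_months)),
    catalog_path = config$catalog_path,
    fee_schedule_path = config$fee_schedule_path,
    uptake = c(list(uptake_fraction = config$uptake$uptake_fraction),
               if (!is.null(config$uptake$engaged_override))
                 list(engaged_override = config$uptake$engaged_override)),
    conversion_factor = config$conversion_factor,
    inpatient = c(list(
      hospitalization_rate = config$inpatient$hospitalization_rate,
      reimbursement = as_map(config$inpatient$reimbursement),
      mix_mode = config$inpatient$mix_mode,
      count_rounding = config$inpatient$count_rounding,
      rate_multiplier = config$inpatient$rate_multiplier),
      if (!is.null(config$inpatient$engaged_override))
        list(engaged_override = config$inpatient$engaged_override)),
    rounding = config$rounding$mode,
    revenue_basis = config$revenue_basis,
    attended_basis = config$attended_basis,
    fee_scale = config$fee_scale,
    apportion = config$apportion
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The packaged reference scenario
#'
#' A complete, calibrated configuration for a hypothetical US health-system
#' population of 100,000 patients with diabetes: CDC national-average
#' segment fractions (50 / 35.5 / 14.5%), health-system engagement rates,
#' a 66.3 / 20.5 / 13.2% payer mix, a 10-code service catalog with
#' comorbidity-based allocations, a calibrated fee schedule and work RVUs,
#' 10% uptake, the MGMA median conversion factor ($41.94/RVU) and national
#' inpatient parameters. The fee schedule and RVUs are calibration fixtures
#' (back-derived so the scenario's planning tables reproduce exactly), not
#' authoritative CMS data.
#'
#' @return A validated `model_config`.
#' @export
#' @examples
#' cfg <- reference_config()
#' engagement_funnel(cfg$cohort)
reference_config <- function() {
  load_config(system.file("extdata", "reference_config.yaml",
                          package = "dpcvalue"), quiet = TRUE)
}

#' Render a completed scenario as a report or CSV tables
#'
#' `format = "report"` returns (and prints) a human-readable summary with
#' the funnel, per-payer revenue totals, RVU components and the value
#' waterfall. `format = "csv"` writes four machine-readable tables —
#' `funnel.csv`, `revenue.csv`, `rvu.csv`, `waterfall.csv` — to `out`
#' (a directory, created if needed); output is byte-stable across runs for
#' the same scenario. An empty scenario renders as all zeros with the value
#' per appointment left blank; no division is attempted.
#'
#' @param scenario A `scenario_result` from [run_scenario()].
#' @param format `"report"` or `"csv"`.
#' @param out Output directory (required for `"csv"`).
#' @return Report lines (character, invisibly) or the written file paths.
#' @export
render_report <- function(scenario, format = c("report", "csv"), out = NULL) {
  stopifnot(inherits(scenario, "scenario_result"))
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(out)) stop("csv format needs an output directory ('out')",
                           call. = FALSE)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    paths <- c(funnel = file.path(out, "funnel.csv"),
               revenue = file.path(out, "revenue.csv"),
               rvu = file.path(out, "rvu.csv"),
               waterfall = file.path(out, "waterfall.csv"))
    utils::write.csv(as.data.frame(scenario$funnel), paths["funnel"],
                     row.names = FALSE, quote = FALSE, eol = "\n")
    rev <- do.call(rbind, lapply(names(scenario$revenue), function(s) {
      cbind(segment = s, as.data.frame(scenario$revenue[[s]]))
    }))
    utils::write.csv(rev, paths["revenue"], row.names = FALSE, quote = FALSE,
                     eol = "\n")
    comp <- scenario$compensation
    rvu <- data.frame(code_key = names(comp$rvu_components %||% numeric()),
                      work_rvus = as.numeric(comp$rvu_components %||% numeric()))
    utils::write.csv(rvu, paths["rvu"], row.names = FALSE, quote = FALSE,
                     eol = "\n")
    wf <- scenario$waterfall
    wfd <- data.frame(
      quantity = c("professional_revenue_annual", "inpatient_revenue_annual",
                   "provider_compensation_annual", "total_margin_annual",
                   "attended_appointments", "value_per_appointment"),
      value = c(wf$professional_revenue_annual, wf$inpatient_revenue_annual,
                wf$provider_compensation_annual, wf$total_margin_annual,
                wf$attended_appointments, wf$value_per_appointment))
    utils::write.csv(wfd, paths["waterfall"], row.names = FALSE,
                     quote = FALSE, eol = "\n", na = "")
    return(invisible(paths))
  }
  lines <- utils::capture.output({
    print(scenario)
  })
  cat(lines, sep = "\n")
  invisible(lines)
}
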