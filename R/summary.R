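#' Dollar value per attended appointment
#'
#' The model's headline quantity: annual professional revenue plus annual
#' inpatient revenue minus annual provider compensation, divided by attended
#' appointments. Full precision; present rounded to the dollar.
#'
#' @param prof,inpat,comp Annual dollars.
#' @param attended Attended appointment count; must be positive — a zero
#'   count raises an explicit undefined-value error, never a silent
#'   infinity.
#' @return Dollars per appointment.
#' @export
#' @examples
#' value_per_appointment(1313177, 1796506, 209988, 2217)  # 1307.936...
value_per_appointment <- function(prof, inpat, comp, attended) {
  stopifnot(is.numeric(prof), is.numeric(inpat), is.numeric(comp))
  if (!is.numeric(attended) || length(attended) != 1 || attended <= 0)
    stop("value per appointment is undefined: attended appointments must be > 0",
         call. = FALSE)
  (prof + inpat - comp) / attended
}

# The assembled annual result. total_margin is computed as the literal sum
# prof + inpat - comp so the waterfall identity holds by construction.
value_waterfall <- function(prof, inpat, comp, attended) {
  margin <- prof + inpat - comp
  vpa <- if (attended > 0) margin / attended else NA_real_
  structure(list(professional_revenue_annual = prof,
                 inpatient_revenue_annual = inpat,
                 provider_compensation_annual = comp,
                 total_margin_annual = margin,
                 attended_appointments = attended,
                 value_per_appointment = vpa),
            class = "value_waterfall")
}

#' @export
print.value_waterfall <- function(x, ...) {
  cat("Value waterfall (annual)\n")
  cat(sprintf("  Professional revenue:   %14s\n",
              format_dollars(x$professional_revenue_annual)))
  cat(sprintf("  Inpatient revenue:      %14s\n",
              format_dollars(x$inpatient_revenue_annual)))
  cat(sprintf("  Provider compensation:  %14s\n",
              format_dollars(-x$provider_compensation_annual)))
  cat(sprintf("  Total margin:           %14s\n",
              format_dollars(x$total_margin_annual)))
  cat(sprintf("  Attended appointments:  %14s\n",
              formatC(x$attended_appointments, format = "d", big.mark = ",")))
  if (is.na(x$value_per_appointment)) {
    cat("  Value per appointment:   undefined (no attended appointments)\n")
  } else {
    cat(sprintf("  Value per appointment:  %14s\n",
                format_dollars(x$value_per_appointment)))
  }
  invisible(x)
}

#' Run the full valuation scenario
#'
#' Executes the whole chain on one configuration: engagement funnel ->
#' professional revenue per segment (summed) -> uptake-gated provider
#' compensation -> inpatient revenue -> value waterfall. Deterministic: two
#' runs of the same configuration yield identical results.
#'
#' The professional-revenue billing base is set by `config$revenue_basis`:
#' `"engaged"` (default) values the visits the engaged cohort will actually
#' attend; `"unengaged"` values the full unengaged population's recommended
#' care; `"full_population"` values every patient's recommended care (the
#' revenue-potential view used in per-segment planning tables).
#'
#' When the engaged cohort is empty (uptake 0 or an empty population) the
#' value per appointment is undefined: it is reported as `NA` with a
#' warning, and no division is attempted.
#'
#' @param config A `model_config` from [load_config()], [model_config()] or
#'   [reference_config()].
#' @return An object of class `scenario_result`: list with `funnel`,
#'   `revenue` (named list of `revenue_table` per segment),
#'   `revenue_by_basis` counts, `compensation`, `hospitalized`,
#'   `inpatient_revenue`, `waterfall`, and the `config` used.
#' @export
#' @examples
#' res <- run_scenario(reference_config())
#' res$waterfall
run_scenario <- function(config) {
  stopifnot(inherits(config, "model_config"))
  rounding <- config$rounding
  funnel <- engagement_funnel(config$cohort, rounding)
  seg <- funnel[match(SEGMENTS, funnel$segment), ]
  unengaged_total <- sum(seg$unengaged)
  engaged_total <- engaged_cohort(unengaged_total, config$uptake, rounding)

  base <- switch(config$revenue_basis,
    full_population = stats::setNames(seg$population, SEGMENTS),
    unengaged = stats::setNames(seg$unengaged, SEGMENTS),
    engaged = stats::setNames(
      apply_rounding(seg$unengaged * config$uptake$uptake_fraction, rounding),
      SEGMENTS)
  )

  fees <- config$fees
  if (config$fee_scale != 1) fees$fee_usd <- fees$fee_usd * config$fee_scale

  revenue <- lapply(SEGMENTS, function(s)
    professional_revenue(base[[s]], config$payer_mix, config$catalog, fees,
                         config$policies[[s]], rounding, config$apportion))
  names(revenue) <- SEGMENTS
  prof_total <- sum(vapply(revenue, attr, numeric(1), "grand_total"))

  rvu <- rvu_totals(engaged_total, config$catalog, rounding)
  comp <- provider_compensation(rvu, config$conversion_factor)

  inpat_engaged <- config$inpatient$engaged_override %||% engaged_total
  hospitalized <- hospitalized_count(inpat_engaged, config$inpatient)
  inpat_rev <- inpatient_revenue(hospitalized, config$payer_mix,
                                 config$inpatient)

  attended <- switch(config$attended_basis,
    engaged_patients = engaged_total,
    engaged_visits = sum(
      apply_rounding(seg$unengaged * config$uptake$uptake_fraction, rounding) *
        vapply(config$policies[SEGMENTS], `[[`, integer(1), "visits_per_year"))
  )
  if (attended == 0)
    warning("value per appointment undefined: attended appointments = 0",
            call. = FALSE)

  structure(list(funnel = funnel, revenue = revenue, revenue_base = base,
                 engaged_total = engaged_total, compensation = comp,
                 hospitalized = hospitalized, inpatient_revenue = inpat_rev,
                 waterfall = value_waterfall(prof_total, inpat_rev,
                                             comp$annual, attended),
                 config = config),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$funnel)
  cat(sprintf("\nEngaged cohort (uptake-gated): %d\n", as.integer(x$engaged_total)))
  cat(sprintf("Professional revenue (annual): %s\n",
              format_dollars(x$waterfall$professional_revenue_annual)))
  print(x$compensation)
  cat(sprintf("Hospitalized (expected): %d  ->  inpatient revenue %s\n",
              as.integer(x$hospitalized),
              format_dollars(x$inpatient_revenue)))
  cat("\n")
  print(x$waterfall)
  invisible(x)
}

#' Return on investment
#'
#' `(total margin - cost) / cost` for a given annual intervention cost.
#'
#' @param waterfall A `value_waterfall` (e.g. from
#'   `run_scenario(...)$waterfall`) or a numeric total margin.
#' @param intervention_cost_annual Positive annual cost in dollars.
#' @return ROI as a ratio (e.g. 1.9 means $1.90 returned per $1 beyond
#'   break-even).
#' @export
#' @examples
#' roi(2899695, 1e6)
roi <- function(waterfall, intervention_cost_annual) {
  margin <- if (inherits(waterfall, "value_waterfall"))
    waterfall$total_margin_annual else waterfall
  if (!is.numeric(intervention_cost_annual) ||
      length(intervention_cost_annual) != 1 || intervention_cost_annual <= 0)
    stop("intervention_cost_annual must be a positive dollar amount",
         call. = FALSE)
  (margin - intervention_cost_annual) / intervention_cost_annual
}

#' Registered sensitivity parameters
#'
#' Scalar model inputs that [one_way_sensitivity()] and
#' [probabilistic_sensitivity()] can vary: the uptake fraction, the
#' hospitalization rate, the RVU conversion factor, a global fee scale, and
#' the three payer-mix shares (setting one share rescales the other two
#' proportionally so the mix still sums to 1).
#'
#' @return Character vector of parameter names.
#' @export
registered_parameters <- function() {
  c("uptake_fraction", "hospitalization_rate", "conversion_factor",
    "fee_scale", paste0("payer_", PAYERS))
}

#' Set a registered scalar parameter on a configuration
#'
#' @param config A `model_config`.
#' @param name One of [registered_parameters()].
#' @param value New value.
#' @return The modified configuration.
#' @export
set_model_parameter <- function(config, name, value) {
  stopifnot(inherits(config, "model_config"), is.numeric(value),
            length(value) == 1)
  if (!name %in% registered_parameters())
    stop(sprintf("unknown parameter '%s'; registered parameters: %s", name,
                 paste(registered_parameters(), collapse = ", ")),
         call. = FALSE)
  if (name == "uptake_fraction") {
    config$uptake <- uptake_params(value, config$uptake$engaged_override)
  } else if (name == "hospitalization_rate") {
    config$inpatient$hospitalization_rate <- value
    if (value < 0 || value > 1)
      stop("hospitalization_rate must be in [0, 1]", call. = FALSE)
  } else if (name == "conversion_factor") {
    if (value < 0) stop("conversion_factor must be >= 0", call. = FALSE)
    config$conversion_factor <- value
  } else if (name == "fee_scale") {
    if (value < 0) stop("fee_scale must be >= 0", call. = FALSE)
    config$fee_scale <- value
  } else {
    payer <- sub("^payer_", "", name)
    if (value < 0 || value >= 1)
      stop("a payer share must lie in [0, 1)", call. = FALSE)
    mix <- unclass(config$payer_mix)
    others <- setdiff(PAYERS, payer)
    rest_old <- sum(mix[others])
    if (rest_old <= 0)
      stop("cannot renormalize: remaining payer shares are zero",
           call. = FALSE)
    mix[others] <- mix[others] * (1 - value) / rest_old
    mix[payer] <- value
    config$payer_mix <- payer_mix(mix)
  }
  config
}

# Sensitivity runs explore the structural (uptake-gated) model, so fixed
# cohort overrides are cleared before varying inputs.
strip_overrides <- function(config) {
  config$uptake$engaged_override <- NULL
  config$inpatient$engaged_override <- NULL
  config
}

#' One-way (tornado-style) sensitivity analysis
#'
#' Reruns the full scenario with one registered parameter at a low and a
#' high value, everything else fixed, and records the value per appointment
#' at both bounds. Engaged-cohort overrides are cleared so the bound truly
#' flows through the uptake-gated model.
#'
#' @param config A `model_config`.
#' @param parameter One of [registered_parameters()].
#' @param low,high Bound values.
#' @return An object of class `sensitivity_result` with the bound inputs and
#'   the value per appointment at each.
#' @export
#' @examples
#' one_way_sensitivity(reference_config(), "hospitalization_rate", 0, 0.339)
one_way_sensitivity <- function(config, parameter, low, high) {
  config <- strip_overrides(config)
  res_low <- run_scenario(set_model_parameter(config, parameter, low))
  res_high <- run_scenario(set_model_parameter(config, parameter, high))
  structure(list(type = "one_way", parameter = parameter,
                 low = low, high = high,
                 value_low = res_low$waterfall$value_per_appointment,
                 value_high = res_high$waterfall$value_per_appointment,
                 margin_low = res_low$waterfall$total_margin_annual,
                 margin_high = res_high$waterfall$total_margin_annual),
            class = "sensitivity_result")
}

# Supported PSA input distributions. A spec is list(dist = ..., <params>).
draw_distribution <- function(spec, n) {
  if (!is.list(spec) || is.null(spec$dist))
    stop("a distribution spec must be a list with a 'dist' field",
         call. = FALSE)
  switch(spec$dist,
    point = {
      if (is.null(spec$value)) stop("point distribution needs 'value'",
                                    call. = FALSE)
      rep(spec$value, n)
    },
    uniform = {
      if (is.null(spec$min) || is.null(spec$max) || spec$min > spec$max)
        stop("uniform distribution needs min <= max", call. = FALSE)
      stats::runif(n, spec$min, spec$max)
    },
    triangular = {
      ok <- !is.null(spec$min) && !is.null(spec$mode) && !is.null(spec$max) &&
        spec$min <= spec$mode && spec$mode <= spec$max
      if (!ok) stop("triangular distribution needs min <= mode <= max",
                    call. = FALSE)
      u <- stats::runif(n)
      a <- spec$min; m <- spec$mode; b <- spec$max
      if (a == b) return(rep(a, n))
      c0 <- (m - a) / (b - a)
      ifelse(u < c0, a + sqrt(u * (b - a) * (m - a)),
             b - sqrt((1 - u) * (b - a) * (b - m)))
    },
    beta = {
      if (is.null(spec$shape1) || is.null(spec$shape2) ||
          spec$shape1 <= 0 || spec$shape2 <= 0)
        stop("beta distribution needs positive shape1 and shape2",
             call. = FALSE)
      stats::rbeta(n, spec$shape1, spec$shape2)
    },
    stop(sprintf(
      "unsupported distribution '%s' (supported: point, uniform, triangular, beta)",
      spec$dist), call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation: draws each named parameter from its input
#' distribution, reruns the scenario per draw, and summarises the value per
#' appointment. Reproducible for a fixed seed; the caller's RNG stream is
#' left untouched.
#'
#' @param config A `model_config`.
#' @param distributions Named list (over [registered_parameters()]) of
#'   distribution specs: `list(dist = "uniform", min=, max=)`,
#'   `list(dist = "triangular", min=, mode=, max=)`,
#'   `list(dist = "beta", shape1=, shape2=)` (for \[0,1\] inputs), or
#'   `list(dist = "point", value=)`.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @return A `sensitivity_result` with the per-draw table (`draws`), summary
#'   `quantiles` (2.5/25/50/75/97.5%) of value per appointment, and the
#'   seed.
#' @export
probabilistic_sensitivity <- function(config, distributions, n_draws = 1000,
                                      seed = 1L) {
  stopifnot(inherits(config, "model_config"), n_draws >= 1)
  bad <- setdiff(names(distributions), registered_parameters())
  if (length(bad) || is.null(names(distributions)))
    stop(sprintf("unknown parameter(s) %s; registered parameters: %s",
                 paste(bad, collapse = ", "),
                 paste(registered_parameters(), collapse = ", ")),
         call. = FALSE)
  config <- strip_overrides(config)
  samples <- with_local_seed(seed, {
    lapply(distributions, draw_distribution, n = n_draws)
  })
  values <- numeric(n_draws)
  margins <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    cfg_i <- config
    for (p in names(samples))
      cfg_i <- set_model_parameter(cfg_i, p, samples[[p]][i])
    wf <- run_scenario(cfg_i)$waterfall
    values[i] <- wf$value_per_appointment
    margins[i] <- wf$total_margin_annual
  }
  draws <- data.frame(draw = seq_len(n_draws),
                      as.data.frame(samples, optional = TRUE),
                      value_per_appointment = values,
                      total_margin_annual = margins)
  structure(list(type = "psa", n_draws = n_draws, seed = seed,
                 draws = draws,
                 quantiles = stats::quantile(
                   values, c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  if (x$type == "one_way") {
    cat(sprintf("One-way sensitivity on '%s'\n", x$parameter))
    cat(sprintf("  low  %g -> value/appt %s\n", x$low,
                format_dollars(x$value_low)))
    cat(sprintf("  high %g -> value/appt %s\n", x$high,
                format_dollars(x$value_high)))
  } else {
    cat(sprintf("Probabilistic sensitivity: %d draws (seed %d)\n",
                x$n_draws, x$seed))
    print(round(x$quantiles, 2))
  }
  invisible(x)
}
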