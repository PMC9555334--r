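# Builds the packaged reference-scenario fixtures in inst/extdata/.
#
# The reference scenario's uncontrolled-segment revenue table prints annual
# dollar totals per (payer, code) but not unit fees, and its provider-RVU
# table prints RVU component totals but not per-code work RVUs. Both are
# back-derived here at full precision:
#   fee(payer, code) = annual revenue / (allocated patients * 4 visits)
#   work_rvu(code)   = RVU component / allocated patients
# so that recomputing the tables from the calibrated fixtures reproduces
# every printed integer. These are calibration artifacts, not authoritative
# CMS fee/RVU data.
#
# Run from the package root: Rscript data-raw/calibrate_fixtures.R

codes <- c("office_visit", "hba1c_test", "urinalysis", "lipid_panel",
           "cbc_auto_diff", "bp_setup_education", "bp_monitor_education",
           "tobacco_cessation", "foot_exam", "depression_screen")
descriptions <- c(
  "Physician office visit", "Hemoglobin A1c level", "Urinalysis",
  "Lipid panel", "Complete blood count with auto-differential",
  "Education on self-managed blood pressure setup",
  "Education on self-managed blood pressure monitor",
  "Tobacco cessation", "Diabetic foot examination", "Depression screening")
allocation <- c(1.00, 1.00, 1.00, 0.44, 1.00, 0.68, 0.68, 0.22, 1.00, 0.25)

# Payability: urinalysis and the diabetic foot exam are bundled with the
# office visit for every payer; Medicaid does not cover blood-pressure
# monitor education.
payable <- function(payer) {
  out <- rep("payable", length(codes))
  out[codes %in% c("urinalysis", "foot_exam")] <- "bundled"
  if (payer == "medicaid") out[codes == "bp_monitor_education"] <- "not_covered"
  out
}

# Annual revenue (USD) per payable (payer, code) cell for the uncontrolled
# segment (N = 14,500; payer counts 9614 / 2973 / 1914; 4 visits/yr).
revenue <- list(
  commercial = c(office_visit = 5669134, hba1c_test = 743081,
                 lipid_panel = 450869, cbc_auto_diff = 297309,
                 bp_setup_education = 92552, bp_monitor_education = 1585158,
                 tobacco_cessation = 87894, depression_screen = 60354),
  medicare = c(office_visit = 1225946, hba1c_test = 115471,
               lipid_panel = 70063, cbc_auto_diff = 46200,
               bp_setup_education = 20014, bp_monitor_education = 342789,
               tobacco_cessation = 19007, depression_screen = 13051),
  medicaid = c(office_visit = 506368, hba1c_test = 68827,
               lipid_panel = 41771, cbc_auto_diff = 27523,
               bp_setup_education = 10712,
               tobacco_cessation = 7942, depression_screen = 7599)
)
payer_counts <- c(commercial = 9614, medicare = 2973, medicaid = 1914)
visits <- 4

half_up <- function(x) floor(x + 0.5 + 1e-9)

fees <- do.call(rbind, lapply(names(revenue), function(p) {
  rev <- revenue[[p]]
  allocated <- half_up(payer_counts[[p]] * allocation[match(names(rev), codes)])
  data.frame(payer = p, code_key = names(rev),
             fee_usd = as.numeric(rev) / (allocated * visits))
}))

# Work RVUs from the provider-compensation table (engaged cohort n = 2217):
# component / allocated count. Codes shown without an RVU contribute none.
rvu_components <- c(office_visit = 4256.64, bp_setup_education = 271.36,
                    bp_monitor_education = 361.81, tobacco_cessation = 117.06)
engaged <- 2217
work_rvu <- rep(NA_real_, length(codes))
for (k in names(rvu_components)) {
  allocated <- half_up(engaged * allocation[codes == k])
  work_rvu[codes == k] <- rvu_components[[k]] / allocated
}

catalog <- data.frame(
  code_key = codes, description = descriptions, allocation = allocation,
  work_rvu = work_rvu, billing = "per_visit",
  payable_commercial = payable("commercial"),
  payable_medicare = payable("medicare"),
  payable_medicaid = payable("medicaid"),
  stringsAsFactors = FALSE)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
library(dpcvalue)
write_cpt_catalog(cpt_catalog(catalog), "inst/extdata/reference_catalog.csv")
write_fee_schedule(fee_schedule(fees), "inst/extdata/reference_fees.csv")
cat("wrote inst/extdata/reference_catalog.csv and reference_fees.csv\n")
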