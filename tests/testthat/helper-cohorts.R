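# small in-code cohorts for unit tests
toy_cohort <- function(doses, indication = "other") {
  ironcma:::new_cohort(data.frame(
    patient_id = sprintf("T%02d", seq_along(doses)),
    indication = rep_len(indication, length(doses)),
    annual_dose_mg = doses,
    stringsAsFactors = FALSE))
}

baseline <- cost_parameters()
table_bounds <- parameter_bounds()

# bounds collapsed onto the baseline: PSA must reduce to the base case
degenerate_bounds <- function(params = baseline) {
  do.call(parameter_bounds, c(
    stats::setNames(lapply(ironcma:::VARIED_PARAMETERS,
                           function(nm) c(params[[nm]], params[[nm]])),
                    ironcma:::VARIED_PARAMETERS),
    list(baseline = params)))
}
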