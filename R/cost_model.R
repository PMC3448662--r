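#' Unit-cost parameters of the infusion model
#'
#' The model's theta: 2009 euro unit costs determined by the hospital
#' accounting department (full-cost model) and the drug regulatory price
#' list, plus the chair-time each infusion occupies. Baselines: IS vial
#' (200 mg) EUR 23; FCM vial (1000 mg) EUR 200; staff EUR 18/h; indirect
#' (structural/administrative) EUR 6/h; infusion devices EUR 7/infusion;
#' non-hospital direct costs (travel, missed work) EUR 10/session.
#'
#' @param drug_price_is EUR per 200 mg IS vial.
#' @param drug_price_fcm EUR per 1000 mg FCM vial.
#' @param staff_rate Day-care unit staff cost, EUR/h.
#' @param indirect_rate Indirect hospital cost, EUR/h.
#' @param device_cost Infusion material, EUR per infusion.
#' @param nonhospital_cost Non-hospital direct cost, EUR per session
#'   (societal perspective only).
#' @param duration_is_h,duration_fcm_h Infusion durations in hours.
#' @param currency_year Price year (costs are undiscounted).
#' @return A `cost_parameters` list.
#' @export
cost_parameters <- function(drug_price_is = 23, drug_price_fcm = 200,
                            staff_rate = 18, indirect_rate = 6,
                            device_cost = 7, nonhospital_cost = 10,
                            duration_is_h = 1.25, duration_fcm_h = 0.75,
                            currency_year = 2009) {
  p <- list(drug_price_is = drug_price_is, drug_price_fcm = drug_price_fcm,
            staff_rate = staff_rate, indirect_rate = indirect_rate,
            device_cost = device_cost, nonhospital_cost = nonhospital_cost,
            duration_is_h = duration_is_h, duration_fcm_h = duration_fcm_h,
            currency_year = currency_year)
  money <- unlist(p[VARIED_PARAMETERS])
  if (any(!is.finite(money)) || any(money < 0)) {
    stop("monetary parameters must be non-negative and finite", call. = FALSE)
  }
  if (duration_is_h <= 0 || duration_fcm_h <= 0) {
    stop("infusion durations must be positive", call. = FALSE)
  }
  structure(p, class = "cost_parameters")
}

#' Sensitivity bounds per cost parameter
#'
#' Lower/upper plausible ranges for the six varied unit costs, used by the
#' deterministic sensitivity analyses and the Monte Carlo PSA. Defaults are
#' the published ranges: IS vial 5-23, FCM vial 80-200, staff 12-24,
#' indirect 2-10, devices 5-10, non-hospital 2-20 (EUR).
#'
#' @param ... Named `c(lower, upper)` pairs overriding the defaults; names
#'   must belong to the varied-parameter set.
#' @param baseline Optional [cost_parameters()] to validate
#'   `lower <= baseline <= upper` against.
#' @return A `parameter_bounds` object: a data frame with columns
#'   `parameter`, `lower`, `upper`.
#' @export
parameter_bounds <- function(..., baseline = cost_parameters()) {
  b <- list(drug_price_is = c(5, 23), drug_price_fcm = c(80, 200),
            staff_rate = c(12, 24), indirect_rate = c(2, 10),
            device_cost = c(5, 10), nonhospital_cost = c(2, 20))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(b))
    if (length(bad)) {
      stop("unknown bound parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    b[names(over)] <- over
  }
  df <- data.frame(parameter = names(b),
                   lower = vapply(b, `[`, numeric(1), 1L),
                   upper = vapply(b, `[`, numeric(1), 2L),
                   row.names = NULL, stringsAsFactors = FALSE)
  if (any(df$lower > df$upper)) {
    stop("each lower bound must not exceed its upper bound", call. = FALSE)
  }
  if (!is.null(baseline)) {
    base <- unlist(baseline[df$parameter])
    off <- df$parameter[base < df$lower | base > df$upper]
    if (length(off)) {
      stop("baseline outside bounds for: ", paste(off, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(df, class = c("parameter_bounds", "data.frame"))
}

bounds_for <- function(bounds, parameter) {
  i <- match(parameter, bounds$parameter)
  if (is.na(i)) {
    stop("unknown parameter \"", parameter, "\"; expected one of: ",
         paste(bounds$parameter, collapse = ", "), call. = FALSE)
  }
  c(lower = bounds$lower[i], upper = bounds$upper[i])
}

as_perspective <- function(perspective) {
  match.arg(perspective, c("hospital", "societal"))
}

regimen_duration <- function(regimen, params) {
  switch(regimen$drug, IS = params$duration_is_h, FCM = params$duration_fcm_h)
}

regimen_drug_price <- function(regimen, params) {
  switch(regimen$drug, IS = params$drug_price_is, FCM = params$drug_price_fcm)
}

per_infusion_components <- function(regimen, params, perspective) {
  dur <- regimen_duration(regimen, params)
  c(drug = regimen_drug_price(regimen, params),
    staff = params$staff_rate * dur,
    indirect = params$indirect_rate * dur,
    devices = params$device_cost,
    nonhospital = if (perspective == "societal") params$nonhospital_cost else 0)
}

#' Cost of a single infusion
#'
#' One infusion costs the vial price plus time costs — (staff + indirect
#' rate) x chair time — plus infusion devices; under the societal
#' perspective the per-session non-hospital direct cost is added. At
#' baseline this gives EUR 60 per IS infusion and EUR 225 per FCM infusion
#' (hospital perspective).
#'
#' @param regimen [regimen()] object or `"IS"`/`"FCM"`.
#' @param params [cost_parameters()].
#' @param perspective `"hospital"` or `"societal"`.
#' @return Total cost of one infusion, EUR.
#' @examples
#' per_infusion_cost("FCM", cost_parameters(), "hospital")  # 225
#' @export
per_infusion_cost <- function(regimen, params = cost_parameters(),
                              perspective = c("hospital", "societal")) {
  regimen <- as_regimen(regimen)
  perspective <- as_perspective(perspective)
  sum(per_infusion_components(regimen, params, perspective))
}

#' Annual infusion cost for one patient
#'
#' Multiplies each per-infusion cost component by the number of infusions
#' the patient's annual dose requires under the regimen.
#'
#' @param patient A one-row cohort slice, or a list/row with field
#'   `annual_dose_mg`.
#' @inheritParams per_infusion_cost
#' @return A `cost_breakdown`: components `drug`, `staff`, `indirect`,
#'   `devices`, `nonhospital`, their `total`, plus `perspective` and
#'   `n_infusions`.
#' @examples
#' patient_cost(list(annual_dose_mg = 800), "IS")$total  # 240
#' @export
patient_cost <- function(patient, regimen, params = cost_parameters(),
                         perspective = c("hospital", "societal")) {
  regimen <- as_regimen(regimen)
  perspective <- as_perspective(perspective)
  dose <- patient$annual_dose_mg
  if (is.null(dose) || length(dose) != 1L) {
    stop("`patient` must carry a single `annual_dose_mg`", call. = FALSE)
  }
  n <- infusions_required(dose, regimen)
  comp <- per_infusion_components(regimen, params, perspective) * n
  structure(c(as.list(comp),
              list(total = sum(comp), perspective = perspective,
                   n_infusions = n)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> %s, %d infusion(s): total EUR %.1f\n",
              x$perspective, x$n_infusions, x$total))
  cat(sprintf("  drug %.1f | staff %.1f | indirect %.1f | devices %.1f | non-hospital %.1f\n",
              x$drug, x$staff, x$indirect, x$devices, x$nonhospital))
  invisible(x)
}

#' Mean annual cost per patient over a cohort
#'
#' The base-case engine: arithmetic mean of per-patient annual totals.
#' Because every component is linear in the infusion count, this equals
#' (total infusions x per-infusion cost) / n patients.
#'
#' @param cohort An `iron_cohort`.
#' @inheritParams per_infusion_cost
#' @return Mean cost per patient, EUR/year.
#' @export
cohort_mean_cost <- function(cohort, regimen, params = cost_parameters(),
                             perspective = c("hospital", "societal")) {
  regimen <- as_regimen(regimen)
  perspective <- as_perspective(perspective)
  validate_cohort(cohort)
  n_inf <- infusions_required(cohort$annual_dose_mg, regimen)
  mean(n_inf) * per_infusion_cost(regimen, params, perspective)
}

#' Incremental cost of iron sucrose over ferric carboxymaltose
#'
#' Mean IS cost minus mean FCM cost per patient and year; positive values
#' favour FCM (the decision criterion of a cost-minimization analysis,
#' both strategies being assumed equally effective and safe).
#'
#' @inheritParams cohort_mean_cost
#' @return Incremental cost, EUR per patient per year.
#' @export
incremental_cost <- function(cohort, params = cost_parameters(),
                             perspective = c("hospital", "societal")) {
  perspective <- as_perspective(perspective)
  cohort_mean_cost(cohort, "IS", params, perspective) -
    cohort_mean_cost(cohort, "FCM", params, perspective)
}

#' Per-patient cost table
#'
#' One row per patient x regimen x perspective, with the full component
#' breakdown — the machine-readable companion of the base-case report.
#'
#' @inheritParams cohort_mean_cost
#' @param path Optional CSV path; written with full precision if given.
#' @return A data frame (invisibly written to `path` when supplied).
#' @export
cohort_cost_table <- function(cohort, params = cost_parameters(), path = NULL) {
  validate_cohort(cohort)
  rows <- expand.grid(i = seq_len(nrow(cohort)), drug = c("IS", "FCM"),
                      perspective = c("hospital", "societal"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(k) {
    i <- rows$i[k]
    bd <- patient_cost(cohort[i, ], rows$drug[k], params, rows$perspective[k])
    data.frame(patient_id = cohort$patient_id[i],
               indication = as.character(cohort$indication[i]),
               annual_dose_mg = cohort$annual_dose_mg[i],
               regimen = rows$drug[k], perspective = rows$perspective[k],
               n_infusions = bd$n_infusions, drug = bd$drug, staff = bd$staff,
               indirect = bd$indirect, devices = bd$devices,
               nonhospital = bd$nonhospital, total = bd$total,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
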