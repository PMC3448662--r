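#' Intravenous iron regimen
#'
#' Defines the two infusion strategies compared by the model: iron sucrose
#' (IS), limited to 200 mg of elemental iron per infusion session, and ferric
#' carboxymaltose (FCM), allowing 1000 mg per infusion. The infusion
#' durations (1 h 15 min for IS, 45 min for FCM) drive the staff and
#' indirect time costs in the cost model.
#'
#' @param drug `"IS"` or `"FCM"`.
#' @return An object of class `iron_regimen`: a list with fields `drug`,
#'   `dose_per_infusion_mg` and `infusion_duration_h`.
#' @examples
#' regimen("FCM")$dose_per_infusion_mg  # 1000
#' @export
regimen <- function(drug = c("IS", "FCM")) {
  drug <- match.arg(drug)
  spec <- switch(drug,
    IS  = list(dose_per_infusion_mg = 200,  infusion_duration_h = 1.25),
    FCM = list(dose_per_infusion_mg = 1000, infusion_duration_h = 0.75)
  )
  structure(c(list(drug = drug), spec), class = "iron_regimen")
}

#' @export
print.iron_regimen <- function(x, ...) {
  cat(sprintf("<iron_regimen> %s: %d mg/infusion, %.2f h/infusion\n",
              x$drug, x$dose_per_infusion_mg, x$infusion_duration_h))
  invisible(x)
}

as_regimen <- function(x) {
  if (inherits(x, "iron_regimen")) return(x)
  if (is.character(x) && length(x) == 1L) return(regimen(x))
  stop("`regimen` must be an iron_regimen object or one of \"IS\", \"FCM\"",
       call. = FALSE)
}

#' Number of infusions required for an annual iron dose
#'
#' The prescribed annual dose is rounded up to the next whole infusion:
#' `ceiling(dose / dose_per_infusion)`. A patient needing 800 mg therefore
#' receives four 200 mg IS infusions, or a single 1000 mg FCM infusion;
#' 1400 mg maps to two FCM infusions.
#'
#' @param annual_dose_mg Positive annual elemental-iron requirement in mg;
#'   vectorised.
#' @param regimen An [regimen()] object or `"IS"`/`"FCM"`.
#' @return Integer vector of infusion counts, each at least 1.
#' @examples
#' infusions_required(800, "IS")   # 4
#' infusions_required(800, "FCM")  # 1
#' @export
infusions_required <- function(annual_dose_mg, regimen) {
  regimen <- as_regimen(regimen)
  if (length(annual_dose_mg) == 0L || !is.numeric(annual_dose_mg) ||
      any(!is.finite(annual_dose_mg)) || any(annual_dose_mg <= 0)) {
    stop("`annual_dose_mg` must be positive and finite", call. = FALSE)
  }
  as.integer(ceiling(annual_dose_mg / regimen$dose_per_infusion_mg))
}

#' Iron actually delivered under a regimen
#'
#' Whole infusions only: delivered iron is the infusion count times the dose
#' per infusion, so it is never less than the prescribed annual dose. For
#' doses that are multiples of 200 mg, IS delivers exactly the prescription;
#' FCM rounds up to the next 1000 mg and may over-deliver by up to 800 mg.
#'
#' @inheritParams infusions_required
#' @return Numeric vector, delivered iron in mg.
#' @examples
#' delivered_iron(800, "FCM")  # 1000
#' delivered_iron(1400, "IS")  # 1400
#' @export
delivered_iron <- function(annual_dose_mg, regimen) {
  regimen <- as_regimen(regimen)
  infusions_required(annual_dose_mg, regimen) * regimen$dose_per_infusion_mg
}
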