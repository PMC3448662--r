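#' @importFrom stats uniroot aggregate
NULL

set_parameter <- function(params, name, value) {
  if (!name %in% VARIED_PARAMETERS) {
    stop("unknown parameter \"", name, "\"; expected one of: ",
         paste(VARIED_PARAMETERS, collapse = ", "), call. = FALSE)
  }
  params[[name]] <- value
  params
}

#' One-way deterministic sensitivity analysis
#'
#' Recomputes the incremental cost (IS minus FCM, per patient per year)
#' over a grid of values of a single unit-cost parameter between its lower
#' and upper bound, all other parameters held at baseline. The incremental
#' cost is linear in every unit cost, so the grid traces a straight line
#' whose slope sign tells whether the parameter pushes towards IS or FCM.
#'
#' @param cohort An `iron_cohort`.
#' @param params Baseline [cost_parameters()].
#' @param bounds [parameter_bounds()].
#' @param parameter One of the six varied parameter names.
#' @param n_points Grid resolution (>= 2).
#' @param perspective Defaults to `"societal"` — the perspective under which
#'   the published robustness claims hold.
#' @return A `one_way_result`: data frame with columns `value` and
#'   `incremental`, plus attributes `parameter` and `perspective`.
#' @export
one_way <- function(cohort, params = cost_parameters(),
                    bounds = parameter_bounds(), parameter, n_points = 11L,
                    perspective = "societal") {
  perspective <- as_perspective(perspective)
  if (n_points < 2L) stop("`n_points` must be at least 2", call. = FALSE)
  b <- bounds_for(bounds, parameter)
  grid <- seq(b[["lower"]], b[["upper"]], length.out = n_points)
  inc <- vapply(grid, function(v) {
    incremental_cost(cohort, set_parameter(params, parameter, v), perspective)
  }, numeric(1))
  structure(data.frame(value = grid, incremental = inc),
            parameter = parameter, perspective = perspective,
            class = c("one_way_result", "data.frame"))
}

#' Two-way sensitivity analysis over both drug prices
#'
#' Evaluates the incremental cost on the full IS-price x FCM-price grid and
#' classifies each cell by the favoured strategy: `"FCM"` when the
#' incremental cost is positive, `"IS"` when negative, `"indifferent"` at
#' exact ties. Default grids cover the published bounds and both break-even
#' thresholds: IS 0-25 EUR step 1, FCM 80-250 EUR step 5.
#'
#' @inheritParams one_way
#' @param is_prices,fcm_prices Non-negative price grids (EUR per vial).
#' @return A `two_way_grid` list: `is_prices`, `fcm_prices`, matrix
#'   `incremental` (rows = IS prices, cols = FCM prices), matrix `favoured`.
#' @export
two_way_drug_prices <- function(cohort, params = cost_parameters(),
                                is_prices = seq(0, 25, by = 1),
                                fcm_prices = seq(80, 250, by = 5),
                                perspective = "societal") {
  perspective <- as_perspective(perspective)
  if (length(is_prices) == 0L || length(fcm_prices) == 0L ||
      any(is_prices < 0) || any(fcm_prices < 0)) {
    stop("price grids must be non-empty and non-negative", call. = FALSE)
  }
  inc <- outer(is_prices, fcm_prices, Vectorize(function(p_is, p_fcm) {
    p <- params; p$drug_price_is <- p_is; p$drug_price_fcm <- p_fcm
    incremental_cost(cohort, p, perspective)
  }))
  dimnames(inc) <- list(is_price = is_prices, fcm_price = fcm_prices)
  fav <- matrix(c("IS", "indifferent", "FCM")[sign(inc) + 2L],
                nrow = nrow(inc), dimnames = dimnames(inc))
  structure(list(is_prices = is_prices, fcm_prices = fcm_prices,
                 incremental = inc, favoured = fav,
                 perspective = perspective),
            class = "two_way_grid")
}

# per-infusion cost net of the drug: time + devices (+ non-hospital)
infusion_overhead <- function(regimen, params, perspective) {
  regimen <- as_regimen(regimen)
  (params$staff_rate + params$indirect_rate) *
    regimen_duration(regimen, params) + params$device_cost +
    if (perspective == "societal") params$nonhospital_cost else 0
}

#' Break-even drug prices
#'
#' Closed-form threshold prices at which the two strategies' mean
#' per-patient costs are equal. With cohort infusion totals `N_IS` and
#' `N_FCM` and per-infusion overheads `o_IS`, `o_FCM` (time + devices +
#' non-hospital if societal), equal cohort costs require
#' `N_IS (p_IS + o_IS) = N_FCM (p_FCM + o_FCM)`; each function solves this
#' identity for one price with the other held at its current value. The
#' result is the exact root of [incremental_cost()] in that price.
#'
#' @inheritParams one_way
#' @return Break-even price in EUR (per 200 mg vial for IS, per 1000 mg
#'   vial for FCM). May be negative when no non-negative price equalises
#'   the strategies.
#' @examples
#' break_even_is_price(load_fixture())  # about 9.96
#' @export
break_even_is_price <- function(cohort, params = cost_parameters(),
                                perspective = "societal") {
  perspective <- as_perspective(perspective)
  validate_cohort(cohort)
  n_is <- sum(infusions_required(cohort$annual_dose_mg, "IS"))
  n_fcm <- sum(infusions_required(cohort$annual_dose_mg, "FCM"))
  n_fcm * (params$drug_price_fcm +
             infusion_overhead("FCM", params, perspective)) / n_is -
    infusion_overhead("IS", params, perspective)
}

#' @rdname break_even_is_price
#' @export
break_even_fcm_price <- function(cohort, params = cost_parameters(),
                                 perspective = "societal") {
  perspective <- as_perspective(perspective)
  validate_cohort(cohort)
  n_is <- sum(infusions_required(cohort$annual_dose_mg, "IS"))
  n_fcm <- sum(infusions_required(cohort$annual_dose_mg, "FCM"))
  n_is * (params$drug_price_is +
            infusion_overhead("IS", params, perspective)) / n_fcm -
    infusion_overhead("FCM", params, perspective)
}
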