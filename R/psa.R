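#' Monte Carlo PSA configuration
#'
#' Settings for the probabilistic sensitivity analysis: number of
#' iterations (10,000 as published), the sampling distribution family for
#' the six varied unit costs, the RNG seed, and the costing perspective
#' (societal by default, i.e. including non-hospital direct costs).
#'
#' @param n_iterations Number of Monte Carlo iterations (>= 1).
#' @param distribution `"uniform"` over the parameter bounds, or
#'   `"truncated_normal"` centred at the baseline with the bounds read as a
#'   95% interval (sd = width / 3.92), rejection-sampled into the bounds.
#' @param seed Integer RNG seed.
#' @param perspective `"societal"` or `"hospital"`.
#' @return A `psa_config` list (also records the varied-parameter set).
#' @export
psa_config <- function(n_iterations = 10000L,
                       distribution = c("uniform", "truncated_normal"),
                       seed = 1L, perspective = "societal") {
  distribution <- match.arg(distribution)
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop("`n_iterations` must be at least 1", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 distribution = distribution, seed = as.integer(seed),
                 perspective = as_perspective(perspective),
                 varied = VARIED_PARAMETERS),
            class = "psa_config")
}

# one matrix of draws, parameters consumed column-by-column in the fixed
# order of VARIED_PARAMETERS so a given seed always maps to the same draws
draw_matrix <- function(params, bounds, distribution, n) {
  draws <- matrix(NA_real_, nrow = n, ncol = length(VARIED_PARAMETERS),
                  dimnames = list(NULL, VARIED_PARAMETERS))
  for (nm in VARIED_PARAMETERS) {
    b <- bounds_for(bounds, nm)
    lo <- b[["lower"]]; hi <- b[["upper"]]
    if (lo > hi) stop("lower bound exceeds upper for ", nm, call. = FALSE)
    if (lo == hi) {
      draws[, nm] <- lo
    } else if (distribution == "uniform") {
      draws[, nm] <- runif(n, lo, hi)
    } else {
      mu <- params[[nm]]
      sd <- (hi - lo) / 3.92
      x <- rnorm(n, mu, sd)
      while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mu, sd)
      draws[, nm] <- x
    }
  }
  draws
}

#' Sample cost parameters from their uncertainty distributions
#'
#' Draws the six varied unit costs either uniformly over their bounds or
#' from a truncated normal centred at the baseline (bounds as a 95%
#' interval). Non-varied fields (infusion durations, currency year) are
#' carried through unchanged. Degenerate bounds (lower = upper) return that
#' value exactly under either distribution. Consumes the current RNG
#' stream; seed externally (e.g. `set.seed`) for reproducibility.
#'
#' @param params Baseline [cost_parameters()].
#' @param bounds [parameter_bounds()].
#' @param distribution `"uniform"` or `"truncated_normal"`.
#' @param n Number of draws.
#' @return For `n = 1` a `cost_parameters` object; for `n > 1` a list of
#'   them.
#' @export
sample_parameters <- function(params = cost_parameters(),
                              bounds = parameter_bounds(),
                              distribution = c("uniform", "truncated_normal"),
                              n = 1L) {
  distribution <- match.arg(distribution)
  draws <- draw_matrix(params, bounds, distribution, n)
  out <- lapply(seq_len(n), function(i) {
    p <- params
    p[VARIED_PARAMETERS] <- as.list(draws[i, ])
    p
  })
  if (n == 1L) out[[1L]] else out
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Propagates unit-cost uncertainty through the cost model: for each
#' iteration the six varied parameters are drawn from their distributions
#' and the incremental cost (IS minus FCM) is evaluated on the fixed
#' cohort. Reports the full vector of draws, the fraction of iterations
#' favouring FCM (incremental strictly greater than 0; exact ties count
#' against FCM), the mean incremental cost, and a histogram.
#'
#' @param cohort An `iron_cohort`.
#' @param params Baseline [cost_parameters()].
#' @param bounds [parameter_bounds()].
#' @param config [psa_config()].
#' @param bin_width Histogram bin width in EUR.
#' @return A `psa_result` list: `incremental` (per-iteration draws),
#'   `fraction_favouring_fcm`, `mean_incremental`, `histogram`, `config`.
#' @examples
#' res <- run_psa(load_fixture(), config = psa_config(n_iterations = 500))
#' res$fraction_favouring_fcm
#' @export
run_psa <- function(cohort, params = cost_parameters(),
                    bounds = parameter_bounds(), config = psa_config(),
                    bin_width = 10) {
  validate_cohort(cohort)
  n_is <- sum(infusions_required(cohort$annual_dose_mg, "IS"))
  n_fcm <- sum(infusions_required(cohort$annual_dose_mg, "FCM"))
  n_pat <- nrow(cohort)
  soc <- config$perspective == "societal"

  draws <- with_seed(config$seed,
    draw_matrix(params, bounds, config$distribution, config$n_iterations))

  # incremental cost is linear in the infusion totals, so the whole run is
  # vectorised instead of looping patient_cost over iterations
  time_is <- (draws[, "staff_rate"] + draws[, "indirect_rate"]) *
    params$duration_is_h
  time_fcm <- (draws[, "staff_rate"] + draws[, "indirect_rate"]) *
    params$duration_fcm_h
  nonhosp <- if (soc) draws[, "nonhospital_cost"] else 0
  per_is <- draws[, "drug_price_is"] + time_is + draws[, "device_cost"] + nonhosp
  per_fcm <- draws[, "drug_price_fcm"] + time_fcm + draws[, "device_cost"] + nonhosp
  incremental <- (n_is * per_is - n_fcm * per_fcm) / n_pat

  structure(list(
    incremental = incremental,
    fraction_favouring_fcm = mean(incremental > 0),
    mean_incremental = mean(incremental),
    histogram = incremental_histogram(incremental, bin_width),
    config = config
  ), class = "psa_result")
}

#' Histogram of incremental-cost draws
#'
#' Counts over half-open bins `[edge, edge + width)` on a grid of
#' bin-width multiples covering all draws; counts sum to the number of
#' draws. Draws below 0 are the simulations favouring iron sucrose.
#'
#' @param incremental_draws Numeric vector of incremental costs, EUR.
#' @param bin_width Positive bin width, EUR.
#' @return Data frame with columns `bin_left`, `bin_right`, `count`.
#' @export
incremental_histogram <- function(incremental_draws, bin_width = 10) {
  if (length(incremental_draws) == 0L) {
    stop("no draws to bin", call. = FALSE)
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  left <- bin_width * floor(incremental_draws / bin_width)
  edges <- seq(min(left), max(left), by = bin_width)
  counts <- tabulate(match(left, edges), nbins = length(edges))
  data.frame(bin_left = edges, bin_right = edges + bin_width, count = counts)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, %s sampling, %s perspective\n",
              x$config$n_iterations, x$config$distribution,
              x$config$perspective))
  cat(sprintf("  favours FCM in %.1f%% of iterations; mean incremental EUR %.1f\n",
              100 * x$fraction_favouring_fcm, x$mean_incremental))
  invisible(x)
}
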