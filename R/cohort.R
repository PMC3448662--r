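#' @importFrom stats rlnorm runif rnorm setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Run `expr` with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Calibration targets for the synthetic cohort
#'
#' The study population the generator emulates: 111 ambulatory patients of a
#' gastrointestinal day-care unit, stratified by indication for intravenous
#' iron, with annual doses delivered as 200 mg iron-sucrose infusions. The
#' defaults are the printed population: stratum sizes 55/22/12/22
#' (chronic liver disease, inflammatory bowel disease, angiodysplasia,
#' other), stratum mean doses 1178/800/833/864 mg, 557 IS infusions in
#' total, and 135,000 mg of iron once each dose is rounded up to the next
#' 1000 mg for ferric carboxymaltose.
#'
#' @param n_patients Total cohort size.
#' @param stratum_sizes Named integer vector of patients per indication.
#' @param stratum_mean_dose_mg Named numeric vector of target mean annual
#'   doses (mg) per indication.
#' @param total_is_infusions Exact cohort total of 200 mg IS infusions.
#' @param total_fcm_iron_mg Exact cohort total of iron delivered under FCM
#'   after rounding each dose up to the next 1000 mg.
#' @param dose_min_mg,dose_max_mg Admissible per-patient dose range (mg).
#' @return A `calibration_targets` list.
#' @export
calibration_targets <- function(
    n_patients = 111L,
    stratum_sizes = c(chronic_liver_disease = 55L,
                      inflammatory_bowel_disease = 22L,
                      angiodysplasia = 12L,
                      other = 22L),
    stratum_mean_dose_mg = c(chronic_liver_disease = 1178,
                             inflammatory_bowel_disease = 800,
                             angiodysplasia = 833,
                             other = 864),
    total_is_infusions = 557L,
    total_fcm_iron_mg = 135000,
    dose_min_mg = 200,
    dose_max_mg = 5200) {
  t <- list(n_patients = as.integer(n_patients),
            stratum_sizes = stratum_sizes,
            stratum_mean_dose_mg = stratum_mean_dose_mg,
            total_is_infusions = as.integer(total_is_infusions),
            total_fcm_iron_mg = total_fcm_iron_mg,
            dose_min_mg = dose_min_mg, dose_max_mg = dose_max_mg)
  validate_targets(t)
  structure(t, class = "calibration_targets")
}

validate_targets <- function(t) {
  if (any(t$stratum_sizes <= 0) || t$n_patients <= 0) {
    stop("all patient counts must be positive", call. = FALSE)
  }
  if (sum(t$stratum_sizes) != t$n_patients) {
    stop("stratum sizes must sum to n_patients", call. = FALSE)
  }
  if (!identical(names(t$stratum_sizes), names(t$stratum_mean_dose_mg))) {
    stop("stratum size and mean-dose names must match", call. = FALSE)
  }
  if (t$dose_min_mg %% 200 != 0 || t$dose_max_mg %% 200 != 0 ||
      t$dose_min_mg < 200 || t$dose_max_mg < t$dose_min_mg) {
    stop("dose range must be positive multiples of 200 mg", call. = FALSE)
  }
  total_mg <- 200 * t$total_is_infusions
  if (total_mg < t$n_patients * t$dose_min_mg ||
      total_mg > t$n_patients * t$dose_max_mg) {
    stop("total IS iron is infeasible for the dose range", call. = FALSE)
  }
  if (t$total_fcm_iron_mg %% 1000 != 0) {
    stop("total_fcm_iron_mg must be a multiple of 1000", call. = FALSE)
  }
  invisible(t)
}

new_cohort <- function(df, provenance = list()) {
  df$patient_id <- as.character(df$patient_id)
  df$indication <- factor(as.character(df$indication),
                          levels = union(INDICATIONS,
                                         unique(as.character(df$indication))))
  df$annual_dose_mg <- as.integer(df$annual_dose_mg)
  validate_cohort(df)
  structure(df, class = c("iron_cohort", "data.frame"),
            provenance = provenance)
}

validate_cohort <- function(df) {
  stopifnot(all(c("patient_id", "indication", "annual_dose_mg") %in% names(df)))
  if (nrow(df) == 0L) stop("cohort is empty", call. = FALSE)
  if (anyDuplicated(df$patient_id)) {
    stop("patient ids must be unique", call. = FALSE)
  }
  d <- df$annual_dose_mg
  if (any(is.na(d)) || any(d %% 200 != 0) || any(d < 200)) {
    stop("annual doses must be positive multiples of 200 mg", call. = FALSE)
  }
  invisible(df)
}

# Split a real-valued stratum total into per-stratum targets that are
# multiples of 200 mg and sum exactly to 200 * total_is_infusions.
stratum_sum_targets <- function(targets) {
  raw <- targets$stratum_sizes * targets$stratum_mean_dose_mg
  t_s <- 200 * round(raw / 200)
  lo <- targets$stratum_sizes * targets$dose_min_mg
  hi <- targets$stratum_sizes * targets$dose_max_mg
  t_s <- pmin(pmax(t_s, lo), hi)
  want <- 200 * targets$total_is_infusions
  # distribute any residual in 200 mg steps, preferring the largest strata
  ord <- order(targets$stratum_sizes, decreasing = TRUE)
  k <- 0L
  while (sum(t_s) != want) {
    i <- ord[k %% length(t_s) + 1L]; k <- k + 1L
    step <- 200 * sign(want - sum(t_s))
    if (t_s[i] + step >= lo[i] && t_s[i] + step <= hi[i]) t_s[i] <- t_s[i] + step
    if (k > 1e6) stop("calibration infeasible: stratum totals", call. = FALSE)
  }
  t_s
}

#' Generate a calibrated synthetic patient cohort
#'
#' Draws per-stratum annual doses (multiples of 200 mg) from a discretised
#' truncated log-normal matched to the stratum mean, then runs an integer
#' repair loop — 200 mg transfers between patients of the same stratum —
#' until the cohort meets the exact calibration totals: stratum sizes, the
#' total number of 200 mg IS infusions, and the total iron delivered after
#' rounding each dose up to the next 1000 mg for FCM. Stratum means are
#' preserved exactly at their 200 mg-rounded targets, always within the
#' stated tolerance of the nominal means.
#'
#' @param targets A [calibration_targets()] object.
#' @param seed Integer seed; the same seed always yields the identical
#'   cohort table.
#' @param mean_tolerance Maximum admissible relative deviation of each
#'   stratum mean dose from its target (default 5%).
#' @param sdlog Log-scale standard deviation of the dose distribution
#'   (right-skewed, as observed in the day-care population).
#' @param max_iter Iteration cap for the repair loop; exceeding it raises a
#'   "calibration infeasible" error.
#' @param pin_range If `TRUE` (default), the observed dose extremes of the
#'   study population are treated as calibration features: one patient of
#'   the highest-mean stratum is pinned at `dose_max_mg` and one patient of
#'   the lowest-mean stratum at `dose_min_mg` (skipped automatically when a
#'   pin would make a stratum total infeasible).
#' @return An `iron_cohort` data frame with columns `patient_id`,
#'   `indication`, `annual_dose_mg`, and a `provenance` attribute recording
#'   seed, generator version and the calibration report.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' summarize_cohort(coh)$total_is_infusions  # 557
#' @export
generate_cohort <- function(targets = calibration_targets(), seed,
                            mean_tolerance = 0.05, sdlog = 0.55,
                            max_iter = 200000L, pin_range = TRUE) {
  validate_targets(targets)
  t_s <- stratum_sum_targets(targets)
  n_s <- targets$stratum_sizes
  lo <- targets$dose_min_mg
  hi <- targets$dose_max_mg

  doses <- with_seed(seed, {
    d <- unlist(lapply(seq_along(n_s), function(i) {
      mu <- t_s[i] / n_s[i]
      x <- rlnorm(n_s[i], meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      pmin(hi, pmax(lo, 200 * round(x / 200)))
    }), use.names = FALSE)
    stratum <- rep(seq_along(n_s), n_s)

    # pin the observed dose extremes, when feasible, and shield them from
    # the repair moves below
    frozen <- integer(0)
    if (pin_range) {
      # a pin is feasible if the stratum's unpinned patients can still reach
      # the stratum total within [lo, hi] each
      rest_ok <- function(i, pinned_sum, n_pinned) {
        rest <- t_s[i] - pinned_sum
        n_free <- n_s[i] - n_pinned
        n_free * lo <= rest && rest <= n_free * hi
      }
      means <- t_s / n_s
      i_max <- which.max(means)
      if (rest_ok(i_max, hi, 1L)) {
        j <- which(stratum == i_max)[1L]
        d[j] <- hi
        frozen <- c(frozen, j)
      }
      i_min <- which.min(means)
      free <- setdiff(which(stratum == i_min), frozen)
      pinned_sum <- lo + if (i_min == i_max && length(frozen)) hi else 0
      if (length(free) > 0 &&
          rest_ok(i_min, pinned_sum, 1L + (i_min == i_max && length(frozen) > 0))) {
        d[free[1L]] <- lo
        frozen <- c(frozen, free[1L])
      }
    }

    # 1. repair each stratum sum to its exact 200 mg-multiple target
    for (i in seq_along(n_s)) {
      idx <- setdiff(which(stratum == i), frozen)
      if (length(idx) == 0L) idx <- which(stratum == i)  # fully pinned stratum
      iter <- 0L
      while (sum(d[which(stratum == i)]) != t_s[i]) {
        step <- 200 * sign(t_s[i] - sum(d[which(stratum == i)]))
        elig <- idx[d[idx] + step >= lo & d[idx] + step <= hi]
        if (length(elig) == 0L || (iter <- iter + 1L) > max_iter) {
          stop("calibration infeasible: stratum sum repair", call. = FALSE)
        }
        j <- elig[sample.int(length(elig), 1L)]
        d[j] <- d[j] + step
      }
    }

    # 2. within-stratum 200 mg transfers (sum-preserving) until the
    #    FCM-rounded total matches. A stochastic hill-climb: a move either
    #    shifts the total by 1000 mg towards the target (accepted) or leaves
    #    it unchanged (accepted half the time, to reshuffle which patients
    #    sit just above a 1000 mg multiple and keep improving moves available).
    target_fcm <- targets$total_fcm_iron_mg
    fcm <- sum(1000 * ceiling(d / 1000))
    iter <- 0L
    while (fcm != target_fcm) {
      if ((iter <- iter + 1L) > max_iter) {
        stop("calibration infeasible: FCM total repair", call. = FALSE)
      }
      a <- sample.int(length(d), 1L)
      if (d[a] - 200 < lo || a %in% frozen) next
      cand <- which(stratum == stratum[a] & d + 200 <= hi)
      cand <- setdiff(cand[cand != a], frozen)
      if (length(cand) == 0L) next
      b <- cand[sample.int(length(cand), 1L)]
      fcm_new <- fcm +
        1000 * (ceiling((d[a] - 200) / 1000) - ceiling(d[a] / 1000)) +
        1000 * (ceiling((d[b] + 200) / 1000) - ceiling(d[b] / 1000))
      if (abs(fcm_new - target_fcm) < abs(fcm - target_fcm) ||
          (fcm_new == fcm && runif(1) < 0.5)) {
        d[a] <- d[a] - 200
        d[b] <- d[b] + 200
        fcm <- fcm_new
      }
    }
    list(d = d, stratum = stratum)
  })

  df <- data.frame(
    patient_id = sprintf("P%03d", seq_len(targets$n_patients)),
    indication = names(n_s)[doses$stratum],
    annual_dose_mg = doses$d,
    stringsAsFactors = FALSE
  )
  means <- tapply(df$annual_dose_mg, df$indication, mean)[names(n_s)]
  rel <- abs(means - targets$stratum_mean_dose_mg) / targets$stratum_mean_dose_mg
  if (any(rel > mean_tolerance)) {
    stop("calibration infeasible: stratum means outside tolerance",
         call. = FALSE)
  }
  new_cohort(df, provenance = list(
    generator = "generate_cohort",
    version = as.character(utils::packageVersion("ironcma")),
    seed = as.integer(seed),
    calibration = list(stratum_sum_targets = unname(t_s),
                       stratum_mean_rel_error = unname(rel))
  ))
}

#' Load the packaged synthetic cohort fixture
#'
#' Returns the version-controlled synthetic stand-in for the study
#' population: a frozen output of [generate_cohort()] (seed 42) satisfying
#' every exact calibration constraint — 111 patients, stratum sizes
#' 55/22/12/22, doses in multiples of 200 mg within 200–5200 mg, 557 IS
#' infusions, 135,000 mg FCM-rounded iron. Byte-identical across runs.
#'
#' @return An `iron_cohort` data frame.
#' @export
load_fixture <- function() {
  path <- system.file("extdata", "synthetic_cohort.csv", package = "ironcma",
                      mustWork = TRUE)
  read_cohort(path)
}

#' Read / write a cohort as CSV
#'
#' Plain CSV with header `patient_id,indication,annual_dose_mg`; lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @param cohort An `iron_cohort`.
#' @return `read_cohort` returns an `iron_cohort`; `write_cohort` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  new_cohort(df, provenance = list(source = path))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- data.frame(patient_id = cohort$patient_id,
                    indication = as.character(cohort$indication),
                    annual_dose_mg = cohort$annual_dose_mg)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise a cohort
#'
#' Cohort-level totals that feed the cost model: per-stratum counts and mean
#' doses, the implied number of 200 mg IS infusions, total iron under IS
#' (delivered exactly) and under FCM (each dose rounded up to the next
#' 1000 mg).
#'
#' @param cohort An `iron_cohort`.
#' @return A `cohort_summary` list with fields `n_patients`, `strata` (data
#'   frame of n and mean dose), `total_is_infusions`, `total_fcm_infusions`,
#'   `total_is_iron_mg`, `total_fcm_iron_mg`.
#' @examples
#' summarize_cohort(load_fixture())$total_fcm_iron_mg  # 135000
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  d <- cohort$annual_dose_mg
  strata <- aggregate(d, list(indication = cohort$indication), FUN = length,
                      drop = FALSE)
  names(strata)[2] <- "n"
  strata$mean_dose_mg <- as.numeric(
    tapply(d, cohort$indication, mean)[as.character(strata$indication)])
  strata <- strata[!is.na(strata$n) & strata$n > 0, , drop = FALSE]
  structure(list(
    n_patients = nrow(cohort),
    strata = strata,
    total_is_infusions = sum(infusions_required(d, "IS")),
    total_fcm_infusions = sum(infusions_required(d, "FCM")),
    total_is_iron_mg = sum(delivered_iron(d, "IS")),
    total_fcm_iron_mg = sum(delivered_iron(d, "FCM"))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n_patients))
  print(x$strata, row.names = FALSE)
  cat(sprintf("IS : %d infusions, %.0f mg (%.0f g) iron\n",
              x$total_is_infusions, x$total_is_iron_mg,
              round(x$total_is_iron_mg / 1000)))
  cat(sprintf("FCM: %d infusions, %.0f mg (%.0f g) iron\n",
              x$total_fcm_infusions, x$total_fcm_iron_mg,
              round(x$total_fcm_iron_mg / 1000)))
  invisible(x)
}
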