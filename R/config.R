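#' @importFrom jsonlite read_json write_json toJSON
NULL

#' Full run configuration
#'
#' Bundles everything a reproducible end-to-end run needs: baseline cost
#' parameters, sensitivity bounds, the cohort source, the costing
#' perspective and PSA settings.
#'
#' @param params [cost_parameters()].
#' @param bounds [parameter_bounds()].
#' @param cohort_source `"fixture"`, `"generate"`, or a path to a cohort
#'   CSV.
#' @param seed Seed used when `cohort_source = "generate"` and as the PSA
#'   default seed.
#' @param perspective Default reporting perspective.
#' @param psa [psa_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(params = cost_parameters(),
                       bounds = parameter_bounds(baseline = params),
                       cohort_source = "fixture", seed = 1L,
                       perspective = "societal",
                       psa = psa_config(seed = seed,
                                        perspective = perspective)) {
  structure(list(params = params, bounds = bounds,
                 cohort_source = cohort_source, seed = as.integer(seed),
                 perspective = as_perspective(perspective), psa = psa),
            class = "run_config")
}

CONFIG_PARAM_FIELDS <- c(VARIED_PARAMETERS, "duration_is_h", "duration_fcm_h",
                         "currency_year")

#' Load / save a run configuration (JSON)
#'
#' The on-disk layout has a `parameters` block (baselines, durations,
#' currency year), a `bounds` block of `lower`/`upper` pairs for the six
#' varied parameters, and run settings. Load and write round-trip exactly.
#' Missing or malformed fields raise an error naming the field; bound
#' ordering and non-negative costs are validated on load.
#'
#' @param path JSON file path.
#' @param config A `run_config`.
#' @return `load_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (block in c("parameters", "bounds")) {
    if (is.null(raw[[block]])) {
      stop("config is missing the \"", block, "\" block", call. = FALSE)
    }
  }
  missing_p <- setdiff(CONFIG_PARAM_FIELDS, names(raw$parameters))
  if (length(missing_p)) {
    stop("config parameters block is missing: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  params <- do.call(cost_parameters, raw$parameters[CONFIG_PARAM_FIELDS])
  missing_b <- setdiff(VARIED_PARAMETERS, names(raw$bounds))
  if (length(missing_b)) {
    stop("config bounds block is missing: ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  }
  bound_args <- lapply(raw$bounds[VARIED_PARAMETERS], function(b) {
    if (is.null(b$lower) || is.null(b$upper)) {
      stop("each bound needs `lower` and `upper`", call. = FALSE)
    }
    c(b$lower, b$upper)
  })
  bounds <- do.call(parameter_bounds, c(bound_args, list(baseline = params)))
  psa_raw <- raw$psa
  psa <- psa_config(
    n_iterations = psa_raw$n_iterations %||% 10000L,
    distribution = psa_raw$distribution %||% "uniform",
    seed = psa_raw$seed %||% raw$seed %||% 1L,
    perspective = psa_raw$perspective %||% raw$perspective %||% "societal")
  run_config(params = params, bounds = bounds,
             cohort_source = raw$cohort_source %||% "fixture",
             seed = raw$seed %||% 1L,
             perspective = raw$perspective %||% "societal", psa = psa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  bounds <- lapply(seq_len(nrow(config$bounds)), function(i) {
    list(lower = config$bounds$lower[i], upper = config$bounds$upper[i])
  })
  names(bounds) <- config$bounds$parameter
  out <- list(
    parameters = unclass(config$params)[CONFIG_PARAM_FIELDS],
    bounds = bounds,
    cohort_source = config$cohort_source,
    seed = config$seed,
    perspective = config$perspective,
    psa = unclass(config$psa)[c("n_iterations", "distribution", "seed",
                                "perspective")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default packaged configuration
#'
#' The published baselines and bounds, shipped as
#' `inst/extdata/default_config.json`.
#'
#' @return Path to the packaged JSON config.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.json", package = "ironcma",
              mustWork = TRUE)
}

resolve_cohort <- function(config) {
  src <- config$cohort_source
  if (identical(src, "fixture")) return(load_fixture())
  if (identical(src, "generate")) return(generate_cohort(seed = config$seed))
  if (is.character(src) && file.exists(src)) return(read_cohort(src))
  stop("cohort source must be \"fixture\", \"generate\" or an existing CSV path",
       call. = FALSE)
}

#' Base-case report
#'
#' Runs the deterministic base case end to end: mean cost per patient and
#' year for each regimen under both perspectives, the incremental costs,
#' and the total iron delivered per strategy. Human-readable printing
#' rounds to 0.1 EUR; the stored values keep full precision.
#'
#' @param config A `run_config` (or the packaged default).
#' @return A `base_case_report` list with elements `mean_costs` (data
#'   frame: regimen, perspective, mean_cost), `incremental` (named by
#'   perspective), `delivered_iron_mg` (named by regimen), `summary`
#'   (cohort summary), and `config_hash`/`seed`/`version` provenance.
#' @export
run_base_case <- function(config = run_config()) {
  cohort <- resolve_cohort(config)
  grid <- expand.grid(regimen = c("IS", "FCM"),
                      perspective = c("hospital", "societal"),
                      stringsAsFactors = FALSE)
  grid$mean_cost <- mapply(function(r, p) {
    cohort_mean_cost(cohort, r, config$params, p)
  }, grid$regimen, grid$perspective)
  inc <- c(hospital = incremental_cost(cohort, config$params, "hospital"),
           societal = incremental_cost(cohort, config$params, "societal"))
  s <- summarize_cohort(cohort)
  structure(list(
    mean_costs = grid,
    incremental = inc,
    delivered_iron_mg = c(IS = s$total_is_iron_mg, FCM = s$total_fcm_iron_mg),
    summary = s,
    config_hash = config_hash(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("ironcma"))
  ), class = "base_case_report")
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(list(
    params = unclass(config$params), bounds = unclass(config$bounds),
    cohort_source = config$cohort_source, seed = config$seed,
    perspective = config$perspective), auto_unbox = TRUE, digits = NA)
  # small rolling hash; avoids a digest dependency for a provenance tag
  h <- Reduce(function(h, ch) (h * 31 + ch) %% 2147483647,
              as.numeric(utf8ToInt(as.character(json))), init = 17)
  sprintf("%08x", as.integer(h))
}

#' @export
print.base_case_report <- function(x, ...) {
  cat("Base-case cost-minimization report (EUR, per patient per year)\n")
  for (p in c("hospital", "societal")) {
    rows <- x$mean_costs[x$mean_costs$perspective == p, ]
    cat(sprintf("  %-8s  IS %6.1f   FCM %6.1f   incremental %6.1f\n", p,
                rows$mean_cost[rows$regimen == "IS"],
                rows$mean_cost[rows$regimen == "FCM"],
                x$incremental[[p]]))
  }
  cat(sprintf("  delivered iron: IS %.0f g, FCM %.0f g\n",
              round(x$delivered_iron_mg[["IS"]] / 1000),
              round(x$delivered_iron_mg[["FCM"]] / 1000)))
  cat(sprintf("  [config %s | seed %d | ironcma %s]\n",
              x$config_hash, x$seed, x$version))
  invisible(x)
}

#' Write report outputs
#'
#' Writes the machine-readable outputs of a base-case run to a directory:
#' `mean_costs.csv` (full precision), `summary.json` (rounded to 0.1 EUR
#' for human consumption plus provenance).
#'
#' @param report A `base_case_report`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "mean_costs.csv")
  write.csv(report$mean_costs, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    mean_costs_eur = as.list(round(setNames(report$mean_costs$mean_cost,
                                            paste(report$mean_costs$regimen,
                                                  report$mean_costs$perspective,
                                                  sep = "_")), 1)),
    incremental_eur = as.list(round(report$incremental, 1)),
    delivered_iron_g = as.list(round(report$delivered_iron_mg / 1000)),
    n_patients = report$summary$n_patients,
    total_is_infusions = report$summary$total_is_infusions,
    config_hash = report$config_hash, seed = report$seed,
    version = report$version
  ), js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}
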