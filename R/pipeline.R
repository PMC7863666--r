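#' Simulate a landscape and visit set to CSV files
#'
#' One-command synthetic demo: generates a lake landscape and a visit table
#' and writes them in the package CSV schemas, byte-identical across runs
#' with the same configuration and seed.
#'
#' @param landscape A [landscape_config()].
#' @param pref A [preference_model()].
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, a list with `lakes_csv`, `visits_csv`, `lakes`,
#'   `visits`.
#' @export
pipeline_simulate <- function(landscape = landscape_config(),
                              pref = preference_model(),
                              out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lakes <- generate_landscape(landscape)
  visits <- simulate_visits(lakes, pref)
  lakes_csv <- file.path(out_dir, "lakes.csv")
  visits_csv <- file.path(out_dir, "visits.csv")
  write_lake_table(lakes, lakes_csv)
  write_visit_table(visits, visits_csv)
  invisible(list(lakes_csv = lakes_csv, visits_csv = visits_csv,
                 lakes = lakes, visits = visits))
}

#' Run the full natal-habitat-preference analysis
#'
#' Sequences the analysis stages: (1) semivariogram screening of every trait
#' with an exponential model fit; (2) unconstrained randomization tests for
#' all traits at the Bonferroni-adjusted alpha; (3) for traits with detected
#' spatial structure where the majority of visits fall within the fitted
#' practical range (the autocorrelation threshold), a second, spatially
#' constrained randomization test with the null pool restricted to that
#' threshold; (4) trophic-class goodness-of-fit tests, overall and per natal
#' class; (5) Welch trait comparisons and the travel summary.
#'
#' @param lakes A `lake_table` (or path to a lake CSV).
#' @param visits A `visit_table` (or path to a visit CSV).
#' @param traits Traits to test.
#' @param n_iterations Monte Carlo iterations per test.
#' @param alpha_family Family-wise error rate.
#' @param autocorr_threshold_km Fixed constraint radius; `NULL` (default)
#'   uses each flagged trait's fitted practical range.
#' @param gof_radius_km Availability window radius for the trophic tests.
#' @param seed Master seed for all randomness.
#' @return An `nhpi_analysis` list bundling every stage's results.
#' @export
pipeline_analyze <- function(lakes, visits, traits = basic_traits(),
                             n_iterations = 10000, alpha_family = 0.05,
                             autocorr_threshold_km = NULL,
                             gof_radius_km = 40, seed = NULL) {
  if (is.character(lakes)) lakes <- read_lake_table(lakes)
  if (is.character(visits)) visits <- read_visit_table(visits, lakes)

  variograms <- list()
  fits <- list()
  for (tr in traits) {
    v <- empirical_semivariogram(lakes, tr)
    variograms[[tr]] <- v
    fits[[tr]] <- tryCatch(fit_variogram_model(v, "exponential"),
                           error = function(e) NULL)
  }

  travel <- travel_summary(visits, lakes)

  unconstrained <- run_all_traits(visits, lakes, traits = traits,
                                  alpha_family = alpha_family,
                                  n_iterations = n_iterations, seed = seed)

  constrained <- list()
  flagged <- character()
  for (tr in traits) {
    f <- fits[[tr]]
    if (is.null(f) || f$no_structure) next
    # a practical range beyond the lag support is not resolvable from the
    # data and indicates an unstructured or trend-dominated trait
    if (f$practical_range_km > attr(variograms[[tr]], "max_lag_km")) next
    thr <- if (is.null(autocorr_threshold_km)) f$practical_range_km else
      autocorr_threshold_km
    within <- mean(travel$per_visit$distance_km <= thr)
    if (within > 0.5) {
      flagged <- c(flagged, tr)
      sub_seed <- if (is.null(seed)) NULL else
        (seed + 1000 + match(tr, traits)) %% .Machine$integer.max
      constrained[[tr]] <- tryCatch(
        randomization_test(visits, lakes, tr, n_iterations = n_iterations,
                           pool_radius_km = thr, seed = sub_seed),
        error = function(e) NULL)
    }
  }

  trophic <- NULL
  if (any(!is.na(lakes$trophic_code))) {
    natal <- lakes[lakes$lake_id %in% unique(visits$natal_lake_id), ,
                   drop = FALSE]
    trophic <- tryCatch({
      expected <- expected_class_distribution(natal, lakes,
                                              radius_km = gof_radius_km)
      code <- stats::setNames(lakes$trophic_code, lakes$lake_id)
      obs <- table(code[visits$destination_lake_id])
      overall <- gof_test(stats::setNames(as.numeric(obs), names(obs)),
                          expected, grouping = "all")
      list(expected = expected, overall = overall,
           per_natal_class = per_natal_class_tests(visits, lakes, expected))
    }, error = function(e) list(error = conditionMessage(e)))
  }

  baseline <- lake_trait_comparison(visits, lakes, traits = traits,
                                    alpha_family = alpha_family)

  structure(list(n_lakes = nrow(lakes), n_visits = nrow(visits),
                 variogram_fits = fits, variograms = variograms,
                 flagged_traits = flagged,
                 unconstrained = unconstrained, constrained = constrained,
                 trophic = trophic, baseline = baseline, travel = travel,
                 seed = seed),
            class = "nhpi_analysis")
}

#' @export
print.nhpi_analysis <- function(x, ...) {
  cat("NHPI analysis:", x$n_visits, "visits over", x$n_lakes, "lakes\n")
  cat("Spatially structured traits (majority of visits in range):",
      if (length(x$flagged_traits)) paste(x$flagged_traits, collapse = ", ")
      else "none", "\n\n")
  print(x$unconstrained)
  if (length(x$constrained)) {
    cat("\nSpatially constrained re-tests:\n")
    for (r in x$constrained) if (!is.null(r)) print(r)
  }
  if (!is.null(x$trophic) && is.null(x$trophic$error)) {
    cat("\n")
    print(x$trophic$overall)
  }
  invisible(x)
}

#' Write an analysis bundle to JSON
#'
#' Serializes every stage of an [pipeline_analyze()] result (dropping the
#' bulky per-iteration null distributions and bin tables) for downstream
#' reporting.
#'
#' @param analysis An `nhpi_analysis`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
analysis_to_json <- function(analysis, path) {
  slim_result <- function(r) {
    if (is.null(r)) return(NULL)
    r <- unclass(r)
    r$null_means <- NULL
    r
  }
  obj <- list(
    n_lakes = analysis$n_lakes, n_visits = analysis$n_visits,
    seed = analysis$seed,
    variogram_fits = lapply(analysis$variogram_fits,
                            function(f) if (is.null(f)) NULL else unclass(f)),
    flagged_traits = analysis$flagged_traits,
    unconstrained = list(
      alpha_per_test = analysis$unconstrained$alpha_per_test,
      significant = as.list(analysis$unconstrained$significant),
      results = lapply(analysis$unconstrained$results, slim_result)),
    constrained = lapply(analysis$constrained, slim_result),
    trophic = if (!is.null(analysis$trophic) &&
                  is.null(analysis$trophic$error)) {
      list(expected = as.list(analysis$trophic$expected),
           overall = unclass(analysis$trophic$overall),
           per_natal_class = lapply(analysis$trophic$per_natal_class,
                                    unclass))
    } else analysis$trophic,
    baseline = analysis$baseline,
    travel = list(mean_km = analysis$travel$mean_km,
                  max_km = analysis$travel$max_km,
                  bearing_histogram = analysis$travel$bearing_histogram))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  writeLines(js, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level keys `landscape`, `preference`, `analysis` (each
#' optional), whose fields are passed to [landscape_config()],
#' [preference_model()] and [pipeline_analyze()] respectively. A top-level
#' `seed` seeds every stage.
#'
#' @param path YAML file path.
#' @return A list with elements `landscape`, `preference`, `analysis`,
#'   `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seed <- cfg$seed
  ls_args <- cfg$landscape %||% list()
  pf_args <- cfg$preference %||% list()
  if (!is.null(seed)) {
    ls_args$seed <- ls_args$seed %||% seed
    pf_args$seed <- pf_args$seed %||% (seed + 1)
  }
  list(landscape = do.call(landscape_config, ls_args),
       preference = do.call(preference_model, pf_args),
       analysis = cfg$analysis %||% list(),
       seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
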