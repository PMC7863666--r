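#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value, as used to compare natal against destination lake
#' traits at a Bonferroni-adjusted alpha.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 values.
#' @param alpha Per-test significance level recorded on the result.
#' @return A `welch_result` list: `mean_a`, `mean_b`, `t_statistic`, `df`,
#'   `p_value`, `significant`, `alpha`.
#' @export
welch_t_test <- function(sample_a, sample_b, alpha = 0.05) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("zero variance in both samples", call. = FALSE)
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  structure(list(mean_a = mean(sample_a), mean_b = mean(sample_b),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 significant = tt$p.value <= alpha,
                 alpha = alpha),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf(
    "Welch t test: mean_a %.4f vs mean_b %.4f; t = %.4f, df = %.2f, p = %.4g%s\n",
    x$mean_a, x$mean_b, x$t_statistic, x$df, x$p_value,
    if (x$significant) sprintf(" (significant at alpha %.3g)", x$alpha)
    else ""))
  invisible(x)
}

#' Bonferroni-adjusted per-test alpha
#'
#' @param family_alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests in the family.
#' @return `family_alpha / m`; e.g. 0.05 over 5 trait tests gives 0.01.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  stopifnot(family_alpha > 0, family_alpha < 1, m >= 1)
  family_alpha / m
}

#' Natal versus destination lake-trait comparison table
#'
#' Lake-level Welch comparisons: the set of distinct natal lakes against the
#' set of distinct destination lakes (each lake counted once per role), one
#' test per trait at the Bonferroni-adjusted alpha.
#'
#' @param visits A `visit_table`.
#' @param lakes A `lake_table`.
#' @param traits Trait columns to compare; default the five basic traits.
#' @param alpha_family Family-wise error rate. Default 0.05.
#' @return Data frame with one row per trait: `trait`, `natal_mean`,
#'   `destination_mean`, `df`, `t`, `p_value`, `significant`; attribute
#'   `"alpha_per_test"`.
#' @export
lake_trait_comparison <- function(visits, lakes, traits = basic_traits(),
                                  alpha_family = 0.05) {
  natal_ids <- unique(visits$natal_lake_id)
  dest_ids <- unique(visits$destination_lake_id)
  alpha <- bonferroni_alpha(alpha_family, length(traits))
  rows <- lapply(traits, function(tr) {
    z <- trait_by_id(lakes, tr)
    w <- welch_t_test(z[natal_ids], z[dest_ids], alpha = alpha)
    data.frame(trait = tr, natal_mean = w$mean_a,
               destination_mean = w$mean_b, df = w$df, t = w$t_statistic,
               p_value = w$p_value, significant = w$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_per_test") <- alpha
  out
}

#' Travel distance and bearing summary of juvenile visits
#'
#' Great-circle distance and initial bearing from natal to destination lake
#' for every visit, with the mean and maximum distance and a bearing
#' histogram for polar plotting.
#'
#' @param visits A `visit_table`.
#' @param lakes A `lake_table`.
#' @param bearing_bin_deg Width of the bearing histogram bins, degrees.
#' @return A `travel_summary` list: `per_visit` (data frame with
#'   `distance_km`, `bearing_deg`), `mean_km`, `max_km`, `bearing_histogram`
#'   (data frame `bin_start`, `bin_end`, `count`).
#' @export
travel_summary <- function(visits, lakes, bearing_bin_deg = 30) {
  if (nrow(visits) == 0) stop("empty visit set", call. = FALSE)
  lat <- stats::setNames(lakes$lat, lakes$lake_id)
  lon <- stats::setNames(lakes$lon, lakes$lake_id)
  d <- haversine_km(lat[visits$natal_lake_id], lon[visits$natal_lake_id],
                    lat[visits$destination_lake_id],
                    lon[visits$destination_lake_id])
  b <- bearing_deg(lat[visits$natal_lake_id], lon[visits$natal_lake_id],
                   lat[visits$destination_lake_id],
                   lon[visits$destination_lake_id])
  breaks <- seq(0, 360, by = bearing_bin_deg)
  counts <- tabulate(findInterval(b, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1)
  structure(list(per_visit = data.frame(distance_km = unname(d),
                                        bearing_deg = unname(b)),
                 mean_km = mean(d), max_km = max(d),
                 bearing_histogram = data.frame(
                   bin_start = breaks[-length(breaks)],
                   bin_end = breaks[-1], count = counts)),
            class = "travel_summary")
}

#' @export
print.travel_summary <- function(x, ...) {
  cat(sprintf(
    "Travel summary over %d visits: mean %.2f km, max %.2f km\n",
    nrow(x$per_visit), x$mean_km, x$max_km))
  invisible(x)
}
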