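#' Expected trophic-class distribution of available lakes
#'
#' The availability benchmark for the goodness-of-fit tests: the proportion
#' of each trophic class among the loon-suitable candidate lakes lying within
#' `radius_km` of at least one natal lake (the union of the natal windows;
#' an intersection reading is available via `window = "all"` but is usually
#' empty at study scale). Candidates are filtered for minimum area and
#' excluded classes before counting.
#'
#' @param natal_lakes A `lake_table` of natal lakes (or a subset of rows).
#' @param all_lakes The full `lake_table` of candidate lakes.
#' @param radius_km Window radius around natal lakes, km. Default 40.
#' @param min_area_ha Minimum candidate area, ha. Default 10.
#' @param excluded_classes Classes never inhabited (e.g. trout ponds).
#' @param window `"any"` (within radius of at least one natal lake, default)
#'   or `"all"` (within radius of every natal lake).
#' @return Named numeric vector of expected proportions over the classes
#'   present among candidates (sums to 1), with attribute `"n_candidates"`.
#' @export
expected_class_distribution <- function(natal_lakes, all_lakes,
                                        radius_km = 40, min_area_ha = 10,
                                        excluded_classes = character(),
                                        window = c("any", "all")) {
  window <- match.arg(window)
  if (nrow(natal_lakes) == 0) stop("no natal lakes given", call. = FALSE)
  cand <- filter_loon_suitable(all_lakes, min_area_ha = min_area_ha,
                               excluded_classes = excluded_classes)
  cand <- cand[!is.na(cand$trophic_code), , drop = FALSE]
  if (nrow(cand) == 0) stop("no candidate lakes with a trophic class",
                            call. = FALSE)
  within <- matrix(FALSE, nrow(cand), nrow(natal_lakes))
  for (j in seq_len(nrow(natal_lakes))) {
    d <- haversine_km(natal_lakes$lat[j], natal_lakes$lon[j],
                      cand$lat, cand$lon)
    within[, j] <- d <= radius_km
  }
  keep <- if (window == "any") rowSums(within) > 0 else
    rowSums(within) == ncol(within)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no candidate lakes within ", radius_km, " km window",
         call. = FALSE)
  }
  tab <- table(cand$trophic_code)
  props <- as.numeric(tab) / sum(tab)
  names(props) <- names(tab)
  attr(props, "n_candidates") <- nrow(cand)
  props
}

#' Chi-square goodness-of-fit test against expected class proportions
#'
#' Computes `X^2 = sum (O_k - n p_k)^2 / (n p_k)` over the classes with
#' positive expected proportion, with `df = (#classes with p_k > 0) - 1` and
#' an upper-tail p-value from the chi-square distribution. An observation in
#' a class with zero expected proportion is an error (the availability model
#' cannot explain it). Classes are never pooled; when any expected count
#' falls below 5 the result carries `low_expected_warning = TRUE` instead.
#'
#' @param observed_counts Named integer vector of visit counts per class.
#' @param expected_proportions Named numeric vector summing to 1. Classes in
#'   `observed_counts` absent here are treated as proportion 0 (an error if
#'   observed); classes here absent from the observations count as 0 visits.
#' @param grouping Label stored on the result (e.g. `"all"` or a natal class
#'   code).
#' @return A `class_gof` list: `grouping`, `observed_counts`,
#'   `expected_proportions`, `expected_counts`, `chi_square`, `df`,
#'   `p_value`, `low_expected_warning`.
#' @export
gof_test <- function(observed_counts, expected_proportions,
                     grouping = "all") {
  n <- sum(observed_counts)
  if (n <= 0) stop("total observed count must be positive", call. = FALSE)
  if (abs(sum(expected_proportions) - 1) > 1e-9) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  classes <- union(names(expected_proportions), names(observed_counts))
  p <- stats::setNames(rep(0, length(classes)), classes)
  p[names(expected_proportions)] <- expected_proportions
  o <- stats::setNames(rep(0, length(classes)), classes)
  o[names(observed_counts)] <- observed_counts
  impossible <- names(which(o > 0 & p == 0))
  if (length(impossible)) {
    stop("observed visits in class(es) with zero expected proportion: ",
         paste(impossible, collapse = ", "), call. = FALSE)
  }
  use <- p > 0
  expected <- n * p[use]
  chi_square <- sum((o[use] - expected)^2 / expected)
  df <- sum(use) - 1
  structure(list(grouping = grouping,
                 observed_counts = o[use],
                 expected_proportions = p[use],
                 expected_counts = expected,
                 chi_square = chi_square, df = df,
                 p_value = stats::pchisq(chi_square, df, lower.tail = FALSE),
                 low_expected_warning = any(expected < 5)),
            class = "class_gof")
}

#' @export
print.class_gof <- function(x, ...) {
  cat("Trophic-class goodness of fit (", x$grouping, ")\n", sep = "")
  tab <- rbind(observed = x$observed_counts,
               expected = round(x$expected_counts, 2))
  print(tab)
  cat(sprintf("  X^2 = %.4f, df = %d, p = %.4g%s\n", x$chi_square, x$df,
              x$p_value,
              if (x$low_expected_warning) "  [expected count < 5]" else ""))
  invisible(x)
}

#' Per-natal-class goodness-of-fit tests
#'
#' Groups visits by the trophic class of the natal lake and tests each
#' group's destination-class counts against the expected availability
#' distribution. Each result also reports the group's "own-class" observed
#' versus expected proportion — the descriptive directional reading of
#' natal-class fidelity. Natal classes with no visits are omitted and listed
#' in attribute `"omitted"`.
#'
#' @param visits A `visit_table`.
#' @param lakes A `lake_table` resolving visit lake ids to trophic classes.
#' @param expected_proportions Expected class proportions (see
#'   [expected_class_distribution()]).
#' @return Named list of `class_gof` results (one per natal class present),
#'   each with an `own_class` element
#'   (`list(class, observed_prop, expected_prop)`).
#' @export
per_natal_class_tests <- function(visits, lakes, expected_proportions) {
  code <- stats::setNames(lakes$trophic_code, lakes$lake_id)
  natal_class <- code[visits$natal_lake_id]
  dest_class <- code[visits$destination_lake_id]
  if (anyNA(natal_class) || anyNA(dest_class)) {
    stop("visits reference lakes without a trophic class", call. = FALSE)
  }
  groups <- sort(unique(natal_class))
  out <- list()
  for (g in groups) {
    dc <- dest_class[natal_class == g]
    obs <- table(dc)
    res <- gof_test(stats::setNames(as.numeric(obs), names(obs)),
                    expected_proportions, grouping = g)
    own_obs <- if (g %in% names(res$observed_counts))
      res$observed_counts[[g]] / sum(res$observed_counts) else 0
    own_exp <- if (g %in% names(expected_proportions))
      unname(expected_proportions[[g]]) else 0
    res$own_class <- list(class = g, observed_prop = own_obs,
                          expected_prop = own_exp)
    out[[g]] <- res
  }
  attr(out, "omitted") <- setdiff(names(expected_proportions), groups)
  out
}

#' Export observed/expected class tables as a plotting-ready data frame
#'
#' @param gof A `class_gof` result.
#' @return Data frame with `class`, `observed`, `expected`, `observed_prop`,
#'   `expected_prop`.
#' @export
gof_table <- function(gof) {
  data.frame(class = names(gof$observed_counts),
             observed = as.numeric(gof$observed_counts),
             expected = as.numeric(gof$expected_counts),
             observed_prop = as.numeric(gof$observed_counts) /
               sum(gof$observed_counts),
             expected_prop = as.numeric(gof$expected_proportions),
             row.names = NULL)
}
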