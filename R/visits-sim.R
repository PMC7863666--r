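#' Destination-choice preference model for simulated juveniles
#'
#' A softmax discrete-choice model over the suitable non-natal lakes within
#' flight range of a juvenile's natal lake. Choice probability is
#' proportional to `exp(-w_ph * |pH_natal - pH_dest| + w_size * log(area) +
#' w_complex * 1[Complex class])`; all-zero weights give a uniform chooser.
#' The weights are pure simulation knobs for exercising the inference, not
#' biological estimates.
#'
#' @param w_ph pH-similarity weight, per pH unit; larger favours pH-similar
#'   destinations.
#' @param w_size Attraction to log surface area.
#' @param w_complex Additive attraction to trophically Complex destinations.
#' @param max_travel_km Choice radius around the natal lake, km. Default 33,
#'   the scale of the longest observed juvenile flights.
#' @param n_juveniles Number of simulated juveniles.
#' @param visits_per_juvenile Visits drawn per juvenile.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return A `preference_model` list.
#' @export
preference_model <- function(w_ph = 0, w_size = 0, w_complex = 0,
                             max_travel_km = 33, n_juveniles = 30,
                             visits_per_juvenile = 2, seed = NULL) {
  stopifnot(max_travel_km > 0, is.finite(w_ph), is.finite(w_size),
            is.finite(w_complex), n_juveniles >= 1, visits_per_juvenile >= 1)
  structure(list(w_ph = w_ph, w_size = w_size, w_complex = w_complex,
                 max_travel_km = max_travel_km, n_juveniles = n_juveniles,
                 visits_per_juvenile = visits_per_juvenile, seed = seed),
            class = "preference_model")
}

#' Simulate juvenile lake visits
#'
#' Each juvenile's natal lake is drawn uniformly from the suitable lakes;
#' each of its visits then picks a destination from the suitable non-natal
#' lakes within `max_travel_km` with softmax probabilities given by the
#' preference model. Juveniles whose natal lake has no in-range neighbour are
#' skipped with a warning. Visit dates are uniform over September-October of
#' the 2012-2015 seasons.
#'
#' @param lakes A `lake_table`.
#' @param pref A [preference_model()].
#' @return A `visit_table`, reproducible from `pref$seed`.
#' @export
simulate_visits <- function(lakes, pref = preference_model()) {
  if (!is.null(pref$seed)) set.seed(pref$seed)
  suit <- which(!is.na(lakes$suitable) & lakes$suitable)
  if (length(suit) < 2) stop("need at least 2 suitable lakes", call. = FALSE)
  dmat <- lake_distance_matrix(lakes)
  logarea <- log(lakes$area_ha)
  is_complex <- !is.na(lakes$trophic_code) &
    startsWith(lakes$trophic_code, "C") & lakes$trophic_code != "TS"

  natal_idx <- sample(suit, pref$n_juveniles, replace = TRUE)
  rows <- vector("list", pref$n_juveniles)
  n_skipped <- 0
  for (j in seq_len(pref$n_juveniles)) {
    natal <- natal_idx[j]
    pool <- setdiff(suit, natal)
    pool <- pool[dmat[natal, pool] <= pref$max_travel_km]
    if (length(pool) == 0) {
      n_skipped <- n_skipped + 1
      next
    }
    util <- -pref$w_ph * abs(lakes$ph[natal] - lakes$ph[pool]) +
      pref$w_size * logarea[pool] +
      pref$w_complex * as.numeric(is_complex[pool])
    prob <- exp(util - max(util))
    dest <- pool[sample.int(length(pool), pref$visits_per_juvenile,
                            replace = TRUE, prob = prob)]
    year <- sample(2012:2015, 1)
    dates <- as.Date(sprintf("%d-09-01", year)) +
      sample.int(61, pref$visits_per_juvenile, replace = TRUE) - 1
    rows[[j]] <- data.frame(
      juvenile_id = sprintf("J%03d", j),
      natal_lake_id = lakes$lake_id[natal],
      destination_lake_id = lakes$lake_id[dest],
      date = format(dates, "%Y-%m-%d"),
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0) {
    warning(n_skipped, " juvenile(s) skipped: no suitable lake within ",
            pref$max_travel_km, " km of the natal lake", call. = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0) {
    stop("no visits could be simulated; all natal lakes isolated",
         call. = FALSE)
  }
  as_visit_table(df, lakes)
}
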