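# Shared fixtures and independent oracles.

# Small lake table at planar km offsets about the default origin, with every
# basic trait filled (overridable per trait).
make_lakes <- function(x_km, y_km, ph = 7, area_ha = 100, max_depth = 10,
                       secchi = 3, shape_index = 1, trophic_code = "CCC",
                       suitable = TRUE, ids = NULL) {
  n <- length(x_km)
  ll <- loonhab:::km_to_latlon(x_km, y_km)
  as_lake_table(data.frame(
    lake_id = ids %||% sprintf("L%d", seq_len(n)),
    name = sprintf("lake %d", seq_len(n)),
    lat = ll$lat, lon = ll$lon,
    area_ha = rep_len(area_ha, n),
    perimeter_km = rep_len(shape_index, n) * sqrt(rep_len(area_ha, n)),
    shape_index = rep_len(shape_index, n),
    max_depth = rep_len(max_depth, n),
    secchi = rep_len(secchi, n),
    ph = rep_len(ph, n),
    trophic_code = rep_len(trophic_code, n),
    suitable = rep_len(suitable, n),
    stringsAsFactors = FALSE))
}

make_visits <- function(lakes, natal_ids, dest_ids,
                        juvenile_ids = sprintf("J%d", seq_along(natal_ids))) {
  as_visit_table(data.frame(
    juvenile_id = juvenile_ids, natal_lake_id = natal_ids,
    destination_lake_id = dest_ids, date = "2013-09-15",
    stringsAsFactors = FALSE), lakes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact randomization p-value by brute-force enumeration over all
# destination assignments (one draw per visit from its pool). The add-one
# form treats the enumeration as a complete set of resamples (the worked
# small-pool convention); the plain form is the probability the Monte Carlo
# estimator converges to.
enum_randomization_p <- function(visits, lakes, trait,
                                 pool_radius_km = NULL, add_one = TRUE) {
  z <- stats::setNames(lakes[[trait]], lakes$lake_id)
  obs <- observed_mean_difference(visits, lakes, trait)
  pools <- lapply(visits$natal_lake_id, function(nid) {
    abs(z[nid] - z[build_resampling_pool(nid, lakes, pool_radius_km)])
  })
  grid <- do.call(expand.grid, pools)
  stats <- rowMeans(as.matrix(grid))
  tol <- 1e-9 * (abs(obs) + 1)
  if (add_one) (sum(stats <= obs + tol) + 1) / (length(stats) + 1)
  else mean(stats <= obs + tol)
}

# Welch t from the defining formulas.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Chi-square GOF statistic by an explicit element-wise loop.
gof_oracle_stat <- function(observed, proportions) {
  n <- sum(observed)
  stat <- 0
  for (k in seq_along(observed)) {
    if (proportions[k] > 0) {
      e <- n * proportions[k]
      stat <- stat + unname((observed[k] - e)^2 / e)
    }
  }
  stat
}

# Exact semivariogram bins of an exponential model, as if estimated without
# noise, for fit self-consistency checks.
exact_variogram <- function(lags, model, nugget, psill, range_param,
                            n_pairs = 50) {
  g <- loonhab:::variogram_model_gamma(lags, model, nugget, psill,
                                       range_param)
  structure(data.frame(lag = lags, gamma = g,
                       n_pairs = rep_len(n_pairs, length(lags))),
            trait = "synthetic", bin_width_km = diff(lags[1:2]),
            max_lag_km = max(lags),
            class = c("lake_variogram", "data.frame"))
}
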