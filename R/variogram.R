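#' Empirical (semi)variogram of a lake trait
#'
#' Bins half the mean squared trait difference between lake pairs by
#' great-circle separation distance: gamma(h) = (1 / 2 N_h) * sum (z_i - z_j)^2
#' over the N_h pairs whose distance falls in the bin. With `direction_deg`
#' set, only pairs whose inter-lake bearing (folded modulo 180, since the
#' statistic is orientation-symmetric) lies within `tolerance_deg` of the
#' requested bearing contribute; the default half-width of 22.5 degrees makes
#' the four canonical bearings 0/45/90/135 partition the pair set. Empty bins
#' are kept with count 0 and `NA` semivariance.
#'
#' @param lakes A `lake_table`.
#' @param trait Name of a numeric lake-table column, e.g. `"ph"`.
#' @param bin_width_km Lag bin width, km. Default 2.
#' @param max_lag_km Largest lag considered; default half the maximum
#'   pairwise distance.
#' @param direction_deg Optional bearing (degrees) of a directional filter.
#' @param tolerance_deg Half-width of the directional window, degrees.
#' @return A `lake_variogram`: data frame with columns `lag`, `gamma`,
#'   `n_pairs`, plus attributes recording the trait and directional window.
#' @export
empirical_semivariogram <- function(lakes, trait, bin_width_km = 2,
                                    max_lag_km = NULL, direction_deg = NULL,
                                    tolerance_deg = 22.5) {
  z <- lakes[[trait]]
  if (is.null(z)) stop("unknown trait: ", trait, call. = FALSE)
  ok <- !is.na(z)
  if (sum(ok) < 2) {
    stop("need at least 2 lakes with trait '", trait, "' present",
         call. = FALSE)
  }
  lk <- lakes[ok, , drop = FALSE]
  z <- z[ok]
  n <- nrow(lk)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- haversine_km(lk$lat[i], lk$lon[i], lk$lat[j], lk$lon[j])
  if (is.null(max_lag_km)) max_lag_km <- max(d) / 2
  sqdiff <- (z[i] - z[j])^2
  keep <- d <= max_lag_km & d > 0
  if (!is.null(direction_deg)) {
    b <- bearing_deg(lk$lat[i], lk$lon[i], lk$lat[j], lk$lon[j]) %% 180
    target <- direction_deg %% 180
    # circular distance on the 180-degree axis of orientations
    delta <- abs(b - target)
    delta <- pmin(delta, 180 - delta)
    keep <- keep & delta < tolerance_deg
  }
  d <- d[keep]; sqdiff <- sqdiff[keep]
  breaks <- seq(0, max_lag_km + bin_width_km, by = bin_width_km)
  bin <- findInterval(d, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1
  counts <- tabulate(bin, nbins = nb)
  sums <- vapply(seq_len(nb), function(k) sum(sqdiff[bin == k]), numeric(1))
  gamma <- ifelse(counts > 0, sums / (2 * counts), NA_real_)
  out <- data.frame(lag = breaks[-length(breaks)] + bin_width_km / 2,
                    gamma = gamma, n_pairs = counts)
  # trailing all-empty bins beyond the data carry no information
  last <- max(c(0, which(counts > 0)))
  out <- out[seq_len(max(last, 1)), , drop = FALSE]
  structure(out, trait = trait, direction_deg = direction_deg,
            tolerance_deg = tolerance_deg, bin_width_km = bin_width_km,
            max_lag_km = max_lag_km,
            class = c("lake_variogram", "data.frame"))
}

#' @export
print.lake_variogram <- function(x, ...) {
  dir <- attr(x, "direction_deg")
  cat("Empirical semivariogram of '", attr(x, "trait"), "'",
      if (!is.null(dir)) paste0(" (directional, ", dir, " deg +/- ",
                                attr(x, "tolerance_deg"), ")"),
      ": ", nrow(x), " bins, ", sum(x$n_pairs), " pairs\n", sep = "")
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

# Theoretical semivariance of the supported models at lag h.
variogram_model_gamma <- function(h, model, nugget, psill, range_param) {
  structural <- switch(model,
    exponential = 1 - exp(-h / range_param),
    spherical = ifelse(h >= range_param, 1,
                       1.5 * h / range_param - 0.5 * (h / range_param)^3),
    stop("unknown model: ", model, call. = FALSE))
  out <- nugget + psill * structural
  out[h == 0] <- 0
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Fits nugget, sill and range of an exponential or spherical semivariogram
#' model to the non-empty bins of an empirical variogram, minimising the
#' pair-count-weighted squared error. The range parameter is profiled out on
#' a log grid and refined, with nugget and partial sill solved by constrained
#' linear WLS at each candidate range — robust and deterministic. The
#' practical range (distance at ~95% of the sill) is `3 * range_param` for
#' the exponential model and `range_param` for the spherical. A variogram
#' flat at (numerically) zero structural variance is flagged
#' `no_structure = TRUE` with `sill = nugget`.
#'
#' @param v A `lake_variogram`.
#' @param model `"exponential"` (default) or `"spherical"`.
#' @return A `variogram_fit` list: `model`, `nugget`, `sill` (total),
#'   `range_param`, `practical_range_km`, `fit_loss`, `no_structure`.
#' @export
fit_variogram_model <- function(v, model = c("exponential", "spherical")) {
  model <- match.arg(model)
  use <- !is.na(v$gamma) & v$n_pairs > 0
  h <- v$lag[use]; g <- v$gamma[use]; w <- v$n_pairs[use]
  if (length(h) < 4) {
    stop("need at least 4 non-empty variogram bins to fit", call. = FALSE)
  }
  if (all(g < 1e-12)) {
    return(new_variogram_fit(model, nugget = 0, psill = 0,
                             range_param = max(h), fit_loss = 0,
                             no_structure = TRUE, trait = attr(v, "trait")))
  }

  wls_at_range <- function(a) {
    f <- variogram_model_gamma(h, model, 0, 1, a)
    # gamma ~ nugget + psill * f, weighted, with both coefficients >= 0
    fit <- stats::lm.wfit(cbind(nugget = 1, psill = f), g, w)
    co <- fit$coefficients
    cands <- list(co)
    # NA coefficients arise when f is constant over the lags (collinear
    # design, e.g. a spherical range below the smallest lag)
    if (anyNA(co) || any(co < 0)) {
      # boundary-constrained alternatives
      c1 <- c(0, max(0, sum(w * g * f) / sum(w * f^2)))      # nugget = 0
      c2 <- c(max(0, stats::weighted.mean(g, w)), 0)          # psill = 0
      cands <- list(c1, c2)
    }
    best <- NULL
    for (co2 in cands) {
      if (any(co2 < 0)) next
      loss <- sum(w * (g - co2[1] - co2[2] * f)^2)
      if (is.null(best) || loss < best$loss) {
        best <- list(nugget = unname(co2[1]), psill = unname(co2[2]),
                     loss = loss)
      }
    }
    best
  }

  a_grid <- exp(seq(log(max(min(h), 1e-3) / 3), log(max(h) * 10),
                    length.out = 250))
  losses <- vapply(a_grid, function(a) wls_at_range(a)$loss, numeric(1))
  k <- which.min(losses)
  lo <- a_grid[max(1, k - 1)]; hi <- a_grid[min(length(a_grid), k + 1)]
  opt <- stats::optimize(function(la) wls_at_range(exp(la))$loss,
                         lower = log(lo), upper = log(hi), tol = 1e-12)
  a_hat <- exp(opt$minimum)
  sol <- wls_at_range(a_hat)
  no_structure <- sol$psill < 1e-10 * max(sol$nugget, 1e-12) ||
    sol$psill < 1e-12
  if (no_structure) a_hat <- max(h)
  new_variogram_fit(model, nugget = sol$nugget, psill = sol$psill,
                    range_param = a_hat, fit_loss = sol$loss,
                    no_structure = no_structure, trait = attr(v, "trait"))
}

new_variogram_fit <- function(model, nugget, psill, range_param, fit_loss,
                              no_structure, trait = NULL) {
  structure(list(model = model, trait = trait, nugget = nugget,
                 partial_sill = psill, sill = nugget + psill,
                 range_param = range_param,
                 practical_range_km = if (model == "exponential")
                   3 * range_param else range_param,
                 fit_loss = fit_loss, no_structure = no_structure),
            class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat("Variogram model fit (", x$model, ")",
      if (!is.null(x$trait)) paste0(" for '", x$trait, "'"), "\n", sep = "")
  cat(sprintf("  nugget %.4g, sill %.4g, range parameter %.3f km\n",
              x$nugget, x$sill, x$range_param))
  cat(sprintf("  practical range %.2f km (95%% of sill)\n",
              x$practical_range_km))
  if (x$no_structure) cat("  NOTE: no spatial structure detected\n")
  invisible(x)
}

#' Directional variogram scan for anisotropy
#'
#' Computes one directional semivariogram per requested bearing (default the
#' four canonical orientations, whose 22.5-degree windows partition the pair
#' set) and fits each, flagging the direction of maximal fitted sill —
#' a simple screen for anisotropic spatial structure such as a SW-NE trait
#' gradient (the 45-degree window).
#'
#' @inheritParams empirical_semivariogram
#' @param directions Bearings (degrees) to scan.
#' @param model Variogram model passed to [fit_variogram_model()].
#' @return An `anisotropy_scan` list: `variograms` (named by direction),
#'   `fits`, `sills`, and `max_sill_direction`.
#' @export
anisotropy_scan <- function(lakes, trait, directions = c(0, 45, 90, 135),
                            bin_width_km = 2, max_lag_km = NULL,
                            tolerance_deg = 22.5,
                            model = c("exponential", "spherical")) {
  model <- match.arg(model)
  vs <- lapply(directions, function(dir) {
    empirical_semivariogram(lakes, trait, bin_width_km = bin_width_km,
                            max_lag_km = max_lag_km, direction_deg = dir,
                            tolerance_deg = tolerance_deg)
  })
  names(vs) <- as.character(directions)
  fits <- lapply(vs, function(v) {
    tryCatch(fit_variogram_model(v, model), error = function(e) NULL)
  })
  sills <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$sill,
                  numeric(1))
  structure(list(variograms = vs, fits = fits, sills = sills,
                 max_sill_direction =
                   directions[which.max(replace(sills, is.na(sills), -Inf))]),
            class = "anisotropy_scan")
}

#' @export
print.anisotropy_scan <- function(x, ...) {
  cat("Anisotropy scan over bearings:",
      paste(names(x$variograms), collapse = ", "), "deg\n")
  cat("  fitted sills:", paste(sprintf("%.3g", x$sills), collapse = ", "),
      "\n")
  cat("  maximal sill at", x$max_sill_direction, "deg\n")
  invisible(x)
}

#' Serialize a variogram and/or its fit to JSON
#'
#' @param v A `lake_variogram`.
#' @param fit Optional `variogram_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
variogram_to_json <- function(v, fit = NULL, path = NULL) {
  obj <- list(trait = attr(v, "trait"),
              direction_deg = attr(v, "direction_deg"),
              tolerance_deg = attr(v, "tolerance_deg"),
              bins = as.data.frame(v))
  if (!is.null(fit)) obj$fit <- unclass(fit)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
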