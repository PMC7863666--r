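test_that("haversine distance matches the closed form and its invariants", {
  expect_equal(haversine_km(45, -89, 45, -89), 0)
  # one degree of latitude on a 6371 km sphere
  expect_equal(haversine_km(45, -89, 46, -89), pi * 6371 / 180,
               tolerance = 1e-6)
  expect_equal(haversine_km(45, -89, 46, -89), 111.19, tolerance = 1e-4)
  set.seed(1)
  for (i in 1:10) {
    a <- c(stats::runif(1, -80, 80), stats::runif(1, -170, 170))
    b <- c(stats::runif(1, -80, 80), stats::runif(1, -170, 170))
    expect_equal(haversine_km(a[1], a[2], b[1], b[2]),
                 haversine_km(b[1], b[2], a[1], a[2]))
  }
  expect_error(haversine_km(95, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 200, 0, 0), "longitude")
})

test_that("bearings are degrees clockwise from north in [0, 360)", {
  expect_equal(bearing_deg(45, -89, 46, -89), 0)
  expect_equal(bearing_deg(0, 0, 0, 1), 90)
  expect_equal(bearing_deg(45, -89, 44, -89), 180)
  b <- bearing_deg(45, -89, 45, -90)
  expect_true(b >= 0 && b < 360 && abs(b - 270) < 1)
  expect_error(bearing_deg(45, -89, 45, -89), "coincident")
})

test_that("empirical semivariogram reproduces hand-computed bins", {
  # constant trait: zero semivariance everywhere
  lakes <- make_lakes(c(0, 3, 7, 12), c(0, 0, 0, 0), ph = 5.5)
  v <- empirical_semivariogram(lakes, "ph", bin_width_km = 2,
                               max_lag_km = 15)
  expect_true(all(v$gamma[v$n_pairs > 0] == 0))

  # two lakes, values 0 and 2, one bin: gamma = (1/2) * (2-0)^2 = 2
  lakes2 <- make_lakes(c(0, 1), c(0, 0), max_depth = c(0, 2))
  v2 <- empirical_semivariogram(lakes2, "max_depth", bin_width_km = 2,
                                max_lag_km = 2)
  expect_equal(v2$gamma[v2$n_pairs > 0], 2.0)
  expect_equal(sum(v2$n_pairs), 1)

  # iid noise: flat at the process variance across lags
  set.seed(21)
  n <- 150
  lakes3 <- make_lakes(stats::runif(n, 0, 60), stats::runif(n, 0, 60),
                       ph = 7)
  lakes3$secchi <- stats::rnorm(n, 3, 1)
  v3 <- empirical_semivariogram(lakes3, "secchi")
  busy <- v3$n_pairs > 50
  expect_true(all(abs(v3$gamma[busy] - 1) < 0.4))

  expect_error(empirical_semivariogram(lakes, "nonesuch"), "unknown trait")
  lakes$ph <- NA_real_
  expect_error(empirical_semivariogram(lakes, "ph"), "at least 2")
})

test_that("variogram model fitting recovers noiseless parameters", {
  lags <- seq(1, 40, by = 2)
  v <- exact_variogram(lags, "exponential", nugget = 0, psill = 1,
                       range_param = 5)
  fit <- fit_variogram_model(v, "exponential")
  expect_equal(fit$nugget, 0, tolerance = 1e-6)
  expect_equal(fit$sill, 1, tolerance = 1e-6)
  expect_equal(fit$range_param, 5, tolerance = 1e-6)
  expect_equal(fit$practical_range_km, 3 * fit$range_param)
  expect_equal(fit$practical_range_km, 15, tolerance = 1e-5)
  expect_false(fit$no_structure)

  # nonzero nugget, spherical model: practical range equals the range param
  v2 <- exact_variogram(lags, "spherical", nugget = 0.3, psill = 2,
                        range_param = 18)
  fit2 <- fit_variogram_model(v2, "spherical")
  expect_equal(fit2$nugget, 0.3, tolerance = 1e-5)
  expect_equal(fit2$sill, 2.3, tolerance = 1e-5)
  expect_equal(fit2$practical_range_km, fit2$range_param)
  expect_equal(fit2$range_param, 18, tolerance = 1e-4)

  # flat-at-zero variogram is flagged as structureless
  v3 <- exact_variogram(lags, "exponential", 0, 0, 5)
  fit3 <- fit_variogram_model(v3)
  expect_true(fit3$no_structure)
  expect_equal(fit3$sill, fit3$nugget)

  expect_error(fit_variogram_model(v[1:3, ]), "at least 4")
})

test_that("directional windows at the four canonical bearings partition the pairs", {
  set.seed(22)
  lakes <- make_lakes(stats::runif(80, 0, 50), stats::runif(80, 0, 50))
  lakes$ph <- stats::rnorm(80, 7, 0.5)
  omni <- empirical_semivariogram(lakes, "ph", max_lag_km = 30)
  per_dir <- lapply(c(0, 45, 90, 135), function(d) {
    empirical_semivariogram(lakes, "ph", max_lag_km = 30, direction_deg = d)
  })
  expect_equal(sum(vapply(per_dir, function(v) sum(v$n_pairs), numeric(1))),
               sum(omni$n_pairs))
})

test_that("anisotropy scan finds a constructed 45-degree gradient", {
  set.seed(23)
  x <- stats::runif(120, 0, 50); y <- stats::runif(120, 0, 50)
  lakes <- make_lakes(x, y)
  # linear trend along the SW-NE (45 deg) axis plus weak noise
  lakes$ph <- 5 + 3 * (x + y) / (2 * 50) + stats::rnorm(120, 0, 0.1)
  scan <- anisotropy_scan(lakes, "ph")
  expect_equal(scan$max_sill_direction, 45)
  expect_length(scan$variograms, 4)
  # semivariance growth is steepest in the 45-degree window
  g45 <- scan$variograms[["45"]]
  g135 <- scan$variograms[["135"]]
  top <- function(v) mean(utils::tail(v$gamma[v$n_pairs > 0], 3))
  expect_gt(top(g45), top(g135))

  one <- anisotropy_scan(lakes, "ph", directions = 90)
  expect_length(one$variograms, 1)
})

test_that("variogram JSON serialization carries bins and fit", {
  lakes <- make_lakes(c(0, 3, 8, 14, 21, 29), c(0, 1, 2, 1, 0, 2),
                      ph = c(7, 7.5, 6.5, 8, 6, 7.2))
  v <- empirical_semivariogram(lakes, "ph", bin_width_km = 4,
                               max_lag_km = 30)
  js <- jsonlite::fromJSON(variogram_to_json(v))
  expect_equal(js$trait, "ph")
  expect_equal(nrow(js$bins), nrow(v))
})
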