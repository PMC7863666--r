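test_that("observed mean difference averages over visit records", {
  lakes <- make_lakes(c(0, 5, 10), c(0, 0, 0), ph = c(7, 8, 10))
  v1 <- make_visits(lakes, "L1", "L2")
  expect_equal(observed_mean_difference(v1, lakes, "ph"), 1.0)
  v2 <- make_visits(lakes, c("L1", "L1"), c("L2", "L3"))
  expect_equal(observed_mean_difference(v2, lakes, "ph"), 2.0)
  # a duplicated record counts twice; here it leaves the mean unchanged
  v3 <- make_visits(lakes, c("L1", "L1", "L1"), c("L2", "L3", "L3"),
                    juvenile_ids = c("J1", "J2", "J2"))
  expect_equal(observed_mean_difference(v3, lakes, "ph"),
               mean(c(1, 3, 3)))
  expect_error(observed_mean_difference(v1[0, ], lakes, "ph"), "empty")
})

test_that("resampling pools exclude the natal lake and honour the radius", {
  # L1 at origin; L2..L4 at 5, 15, 30 km; L5 unsuitable at 2 km
  lakes <- make_lakes(c(0, 5, 15, 30, 2), c(0, 0, 0, 0, 0),
                      suitable = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_setequal(build_resampling_pool("L1", lakes), c("L2", "L3", "L4"))
  expect_setequal(build_resampling_pool("L1", lakes, radius_km = 20),
                  c("L2", "L3"))
  for (id in lakes$lake_id[lakes$suitable]) {
    expect_false(id %in% build_resampling_pool(id, lakes))
  }
  expect_error(build_resampling_pool("L1", lakes, radius_km = 1),
               "L1")
})

test_that("Monte Carlo p-values match exhaustive enumeration on small instances", {
  set.seed(51)
  for (rep in 1:4) {
    n_pool <- sample(4:6, 1)
    lakes <- make_lakes(stats::runif(n_pool + 1, 0, 10),
                        stats::runif(n_pool + 1, 0, 10),
                        ph = round(stats::runif(n_pool + 1, 5, 9), 2))
    visits <- make_visits(lakes, rep("L1", 3),
                          sample(lakes$lake_id[-1], 3, replace = TRUE))
    exact <- enum_randomization_p(visits, lakes, "ph", add_one = FALSE)
    mc <- randomization_test(visits, lakes, "ph", n_iterations = 20000,
                             seed = 52 + rep)$p_value
    expect_lt(abs(mc - exact), 0.02)
  }
})

test_that("the worked three-lake enumeration gives p exactly one half", {
  lakes <- make_lakes(c(0, 2, 4, 6), c(0, 0, 0, 0), ph = c(7, 6, 7, 8),
                      ids = c("N", "A", "B", "C"))
  visits <- make_visits(lakes, "N", "B")  # natal pH 7, destination pH 7
  expect_equal(observed_mean_difference(visits, lakes, "ph"), 0)
  # null statistics over the pool {6, 7, 8} are {1, 0, 1}
  expect_equal(enum_randomization_p(visits, lakes, "ph"), 0.5)
})

test_that("p-value boundaries and determinism behave as specified", {
  # destination trait farther from natal than any pool lake: p = 1 exactly
  lakes <- make_lakes(c(0, 2, 4, 6), c(0, 0, 0, 0),
                      max_depth = c(10, 11, 12, 50))
  visits <- make_visits(lakes, "L1", "L4")
  r <- randomization_test(visits, lakes, "max_depth", n_iterations = 200,
                          seed = 53)
  expect_equal(r$p_value, 1.0)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_gte(r$observed_mean_abs_diff, 0)

  # identical seeds give identical results; the add-one form floors p
  lakes2 <- generate_landscape(landscape_config(n_lakes = 30, seed = 54))
  visits2 <- suppressWarnings(simulate_visits(
    lakes2, preference_model(w_ph = 10, n_juveniles = 15, seed = 55)))
  a <- randomization_test(visits2, lakes2, "ph", n_iterations = 500,
                          seed = 56)
  b <- randomization_test(visits2, lakes2, "ph", n_iterations = 500,
                          seed = 56)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 501)
  expect_equal(length(a$null_means), 500)
  expect_true(a$null_q025 <= a$null_q975)
})

test_that("subsetting by travel distance drops only the distant visits", {
  lakes <- make_lakes(c(0, 5, 25), c(0, 0, 0), ph = c(7, 7.5, 8.5))
  visits <- make_visits(lakes, c("L1", "L1"), c("L2", "L3"))
  r <- randomization_test(visits, lakes, "ph", n_iterations = 100,
                          subset_radius_km = 10, seed = 57)
  expect_equal(r$n_obs, 1)
  expect_error(randomization_test(visits, lakes, "ph",
                                  subset_radius_km = 0.1, seed = 57),
               "no visits")
})

test_that("the family runner applies Bonferroni-adjusted decisions", {
  lakes <- generate_landscape(landscape_config(n_lakes = 30, seed = 58))
  visits <- suppressWarnings(simulate_visits(
    lakes, preference_model(n_juveniles = 15, seed = 59)))
  fam <- run_all_traits(visits, lakes, n_iterations = 200, seed = 60)
  expect_length(fam$results, 5)
  expect_equal(fam$alpha_per_test, 0.01)
  fam1 <- run_all_traits(visits, lakes, traits = "ph", n_iterations = 200,
                         seed = 60)
  expect_equal(fam1$alpha_per_test, 0.05)
  # reproducible end to end
  fam2 <- run_all_traits(visits, lakes, n_iterations = 200, seed = 60)
  expect_identical(vapply(fam$results, `[[`, numeric(1), "p_value"),
                   vapply(fam2$results, `[[`, numeric(1), "p_value"))
})

test_that("per-juvenile collapse removes repeat juvenile-lake records", {
  lakes <- make_lakes(c(0, 5, 10), c(0, 0, 0))
  visits <- make_visits(lakes, c("L1", "L1", "L2"), c("L2", "L2", "L3"),
                        juvenile_ids = c("J1", "J1", "J2"))
  fam <- run_all_traits(visits, lakes, traits = "ph", n_iterations = 50,
                        seed = 61, collapse_per_juvenile = TRUE)
  expect_equal(fam$results$ph$n_obs, 2)
})
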