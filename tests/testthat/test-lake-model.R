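test_that("lake tables load with completeness reporting and strict ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "lake_id,name,lat,lon,area_ha,perimeter_km,shape_index,max_depth,secchi,ph,trophic_code,suitable",
    "L1,Alpha,45.7,-89.5,100,3.5,0.35,12,3.1,7.2,CCC,TRUE",
    "L2,Beta,45.8,-89.4,50,4.0,0.57,8,2.0,6.8,SWD,TRUE"), path)
  lakes <- read_lake_table(path)
  expect_s3_class(lakes, "lake_table")
  expect_equal(nrow(lakes), 2)
  expect_equal(attr(lakes, "report")$n_complete, 2)

  # missing pH: loaded with NA, counted incomplete, never dropped
  writeLines(c(
    "lake_id,name,lat,lon,area_ha,perimeter_km,shape_index,max_depth,secchi,ph,trophic_code,suitable",
    "L1,Alpha,45.7,-89.5,100,3.5,0.35,12,3.1,,CCC,TRUE",
    "L2,Beta,45.8,-89.4,50,4.0,0.57,8,2.0,6.8,SWD,TRUE"), path)
  lakes <- read_lake_table(path)
  expect_equal(nrow(lakes), 2)
  expect_true(is.na(lakes$ph[1]))
  expect_equal(attr(lakes, "report")$n_incomplete, 1)

  # duplicate id errors and names the offender
  writeLines(c(
    "lake_id,name,lat,lon,area_ha,perimeter_km,shape_index,max_depth,secchi,ph,trophic_code,suitable",
    "L7,Alpha,45.7,-89.5,100,3.5,0.35,12,3.1,7.0,CCC,TRUE",
    "L7,Beta,45.8,-89.4,50,4.0,0.57,8,2.0,6.8,SWD,TRUE"), path)
  expect_error(read_lake_table(path), "L7")

  # unparseable coordinate errors and names the row
  writeLines(c(
    "lake_id,name,lat,lon,area_ha,perimeter_km,shape_index,max_depth,secchi,ph,trophic_code,suitable",
    "L1,Alpha,45.7,-89.5,100,3.5,0.35,12,3.1,7.0,CCC,TRUE",
    "L2,Beta,oops,-89.4,50,4.0,0.57,8,2.0,6.8,SWD,TRUE"), path)
  expect_error(read_lake_table(path), "row 2")
})

test_that("visit tables resolve lakes and apply the completeness filter", {
  lakes <- make_lakes(c(0, 5, 10), c(0, 0, 0))
  v <- make_visits(lakes, c("L1", "L1", "L2"), c("L2", "L3", "L3"))
  expect_equal(attr(v, "report")$n_read, 3)
  expect_equal(attr(v, "report")$n_after_filter, 3)

  # destination L3 missing secchi: completeness filter 3 -> 2
  lakes2 <- lakes
  lakes2$secchi[3] <- NA
  df <- data.frame(juvenile_id = c("J1", "J2", "J3"),
                   natal_lake_id = c("L1", "L1", "L2"),
                   destination_lake_id = c("L2", "L3", "L3"),
                   date = "2013-09-15")
  v2 <- as_visit_table(df, lakes2, require_complete_traits = TRUE)
  expect_equal(attr(v2, "report")$n_read, 3)
  expect_equal(nrow(v2), 1)  # J2 and J3 both visit the incomplete L3
  v3 <- as_visit_table(df, lakes2, require_complete_traits = FALSE)
  expect_equal(nrow(v3), 3)

  # unknown lake is a named error; self-visits are dropped with a reason
  df$destination_lake_id[2] <- "L99"
  expect_error(as_visit_table(df, lakes), "L99")
  df$destination_lake_id[2] <- "L1"
  expect_warning(v4 <- as_visit_table(df, lakes), "natal equals destination")
  expect_equal(nrow(v4), 2)
  expect_equal(attr(v4, "report")$rejected$row, 2)
})

test_that("lake and visit tables round-trip through CSV exactly", {
  lakes <- generate_landscape(landscape_config(n_lakes = 15, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lake_table(lakes, path)
  back <- read_lake_table(path)
  for (col in c("lat", "lon", basic_traits(), "perimeter_km")) {
    expect_identical(back[[col]], lakes[[col]], label = col)
  }
  expect_identical(back$trophic_code, lakes$trophic_code)

  visits <- suppressWarnings(
    simulate_visits(lakes, preference_model(n_juveniles = 8, seed = 12)))
  vpath <- withr::local_tempfile(fileext = ".csv")
  write_visit_table(visits, vpath)
  vback <- read_visit_table(vpath, lakes)
  expect_identical(as.data.frame(vback), as.data.frame(visits))
})

test_that("shape index follows the km-over-sqrt-hectare convention", {
  # a 100-ha circle attains the analytic minimum, 0.35 at 2 d.p.
  circle <- compute_shape_index(2 * sqrt(pi), 100)
  expect_equal(circle, 2 * sqrt(pi) / 10, tolerance = 1e-12)
  expect_equal(round(circle, 2), 0.35)
  # 1 km x 1 km square
  expect_equal(compute_shape_index(4, 100), 0.40)
  # invariant under uniform linear rescaling of the outline
  expect_equal(compute_shape_index(2 * 3.6, 4 * 80),
               compute_shape_index(3.6, 80))
  # strictly monotone in each argument
  p <- seq(1, 10, length.out = 25)
  expect_true(all(diff(compute_shape_index(p, 50)) > 0))
  a <- seq(20, 500, length.out = 25)
  expect_true(all(diff(compute_shape_index(5, a)) < 0))
  expect_error(compute_shape_index(0, 10), "positive")
  expect_error(compute_shape_index(3, -1), "positive")
})

test_that("trophic classification is total and closed over its code set", {
  expect_equal(classify_trophic(6, "Cool", "Clear", FALSE), "CCC")
  expect_equal(classify_trophic(2, "Warm", "Dark", FALSE), "SWD")
  expect_equal(classify_trophic(5, "Cool", "Clear", TRUE), "TS")
  # threshold count is Complex; the threshold is a parameter
  expect_equal(classify_trophic(4, "Warm", "Clear", FALSE), "CWC")
  expect_equal(classify_trophic(4, "Warm", "Clear", FALSE,
                                complex_threshold = 5), "SWC")
  grid <- expand.grid(count = 0:8, temp = c("Warm", "Cool"),
                      clar = c("Clear", "Dark"), ts = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  codes <- classify_trophic(grid$count, grid$temp, grid$clar, grid$ts)
  expect_true(all(codes %in% trophic_codes()))
  expect_setequal(unique(codes), trophic_codes())
  expect_error(classify_trophic(3, "Tepid", "Clear", FALSE), "Tepid")
})

test_that("suitability filtering removes small lakes and excluded classes", {
  lakes <- make_lakes(c(0, 1, 2), c(0, 0, 0), area_ha = c(8, 12, 200),
                      trophic_code = c("CCC", "CCC", "trout pond"))
  kept <- filter_loon_suitable(lakes)
  expect_setequal(kept$lake_id, c("L2", "L3"))
  expect_equal(attr(kept, "removals")$below_min_area, 1)

  kept2 <- filter_loon_suitable(lakes, excluded_classes = "trout pond")
  expect_setequal(kept2$lake_id, "L2")
  expect_equal(attr(kept2, "removals")$excluded_class, 1)

  # no thresholds: identity
  expect_equal(nrow(filter_loon_suitable(lakes, min_area_ha = 0,
                                         use_flag = FALSE)), 3)
})
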