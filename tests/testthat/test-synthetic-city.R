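test_that("city generation is reproducible and labels are well-formed", {
  c1 <- generate_city(30, 10, 4, seed = 5)
  c2 <- generate_city(30, 10, 4, seed = 5)
  expect_identical(c1, c2)
  c3 <- generate_city(30, 10, 4, seed = 6)
  expect_false(identical(c1$lsoas, c3$lsoas))

  expect_true(all(c1$lsoas$planted %in% 1:4))
  expect_true(all(c1$gps$planted %in% 1:4))
  expect_true(all(c1$lsoas$population > 0))
  expect_true(all(is.finite(c(c1$lsoas$x, c1$lsoas$y, c1$gps$x, c1$gps$y))))

  # single community forces uniform labels
  c4 <- generate_city(4, 4, 1, seed = 1)
  expect_true(all(c4$lsoas$planted == 1))
  expect_true(all(c4$gps$planted == 1))

  # round-robin allocation: every community gets at least one of each
  c5 <- generate_city(300, 60, 6, seed = 9)
  expect_setequal(unique(c5$lsoas$planted), 1:6)
  expect_setequal(unique(c5$gps$planted), 1:6)

  expect_error(generate_city(10, 3, 5, seed = 1), "invalid configuration")
  expect_error(generate_city(2, 10, 5, seed = 1), "invalid configuration")
})

test_that("registration sampling is deterministic and respects the leakage model", {
  city <- generate_city(20, 8, 2, epsilon = 0, seed = 3)
  r1 <- sample_registrations(city, patients_per_lsoa = 15, dup_rate = 0.3, seed = 4)
  r2 <- sample_registrations(city, patients_per_lsoa = 15, dup_rate = 0.3, seed = 4)
  expect_identical(r1, r2)

  # zero leakage: every registration stays in the planted community
  gcomm <- city$gps$planted[match(r1$truth$gp_id, city$gps$gp_id)]
  lcomm <- city$lsoas$planted[match(r1$truth$lsoa_id, city$lsoas$lsoa_id)]
  expect_identical(gcomm, lcomm)

  # dup_rate = 0: record count equals patient count
  r0 <- sample_registrations(city, patients_per_lsoa = 10, dup_rate = 0, seed = 4)
  expect_equal(nrow(r0$records), nrow(r0$truth))

  # dates inside the configured window
  expect_true(all(r1$records$record_date >= as.Date("2017-04-01")))
  expect_true(all(r1$records$record_date <= as.Date("2018-03-31")))
})

test_that("deduplication recovers the planted truth exactly", {
  city <- generate_city(25, 10, 2, seed = 11)
  reg <- sample_registrations(city, patients_per_lsoa = 20, dup_rate = 0.4,
                              seed = 12)
  expect_gt(nrow(reg$records), nrow(reg$truth))  # duplicates present
  dd <- deduplicate_patients(reg)
  got <- dd[order(dd$patient_id), c("patient_id", "lsoa_id", "gp_id")]
  want <- reg$truth[order(reg$truth$patient_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("zero-leakage EMS never exceeds the community practice count", {
  city <- generate_city(40, 12, 2, epsilon = 0, seed = 21)
  reg <- sample_registrations(city, patients_per_lsoa = 25, dup_rate = 0, seed = 22)
  rm <- build_registration_matrix(deduplicate_patients(reg), min_patients = 1)
  mk <- lsoa_market_concentration(rm)
  comm_size <- table(city$gps$planted)
  lcomm <- city$lsoas$planted[match(mk$lsoa_id, city$lsoas$lsoa_id)]
  expect_true(all(mk$ems <= as.numeric(comm_size[lcomm]) + 1e-9))
})

test_that("city and registration writers emit the documented CSV schemas", {
  city <- generate_city(6, 4, 2, seed = 31)
  reg <- sample_registrations(city, patients_per_lsoa = 5, dup_rate = 0.2, seed = 32)
  dir <- withr::local_tempdir()
  paths <- write_city(city, reg, dir)
  lsoas <- read.csv(paths[["lsoas"]])
  expect_named(lsoas, c("lsoa_id", "x", "y", "population", "planted"))
  gps <- read.csv(paths[["gps"]])
  expect_named(gps, c("gp_id", "x", "y", "ccg_id", "planted"))
  rec <- read.csv(paths[["registrations"]])
  expect_named(rec, c("patient_id", "lsoa_id", "gp_id", "record_date"))
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", rec$record_date)))

  gj_path <- file.path(dir, "tiles.geojson")
  lsoa_tiles_geojson(city, gj_path)
  gj <- jsonlite::read_json(gj_path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 6)
  expect_equal(gj$features[[1]]$geometry$type, "Polygon")
})
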