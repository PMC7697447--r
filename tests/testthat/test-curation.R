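test_that("inclusion rules code every failure and accept the worked examples", {
  db <- generate_fixture_database(2, seed = 1)
  rec <- apply_inclusion_rules(db)
  expect_true(all(rec$included))
  expect_equal(rec$exclusion_reasons, c("", ""))

  small <- db[1, ]
  small$n <- 5
  expect_equal(apply_inclusion_rules(small)$exclusion_reasons, "insufficient_n")
  six <- db[1, ]
  six$n <- 6
  expect_true(apply_inclusion_rules(six)$included)

  noproc <- db[1, ]
  noproc$proc <- NA
  expect_equal(apply_inclusion_rules(noproc)$exclusion_reasons, "no_proc_assignable")

  noctx <- db[1, ]
  noctx$conc_band <- NA
  expect_equal(apply_inclusion_rules(noctx)$exclusion_reasons, "insufficient_context")
  nogv <- db[1, ]
  nogv$general_ventilation <- NA  # indoor record: ventilation status required
  expect_false(apply_inclusion_rules(nogv)$included)

  multi <- db[1, ]
  multi$n <- 3
  multi$proc <- NA
  multi$setting <- NA
  reasons <- strsplit(apply_inclusion_rules(multi)$exclusion_reasons, ",")[[1]]
  expect_setequal(reasons, c("insufficient_n", "no_proc_assignable",
                             "insufficient_context"))
})

test_that("control adjustment removes unearned LEV and RPE credit, idempotently", {
  db <- generate_fixture_database(2, seed = 1)

  lev_bad <- db[2, ]
  lev_bad$lev_reported_effective <- FALSE
  adj <- adjust_controls(lev_bad)
  expect_false(adj$lev_present_cmp)
  expect_true(adj$lev_present)  # original untouched
  expect_match(adj$notes, "LEV credit removed")

  rpe_rec <- db[1, ]
  rpe_rec$rpe <- "90"
  rpe_rec$rpe_worn <- TRUE
  adj2 <- adjust_controls(rpe_rec)
  expect_equal(adj2$rpe_cmp, "none")
  expect_equal(adj2$rpe, "90")
  expect_match(adj2$notes, "RPE credit removed")

  inside <- rpe_rec
  inside$measurement_inside_rpe <- TRUE
  expect_warning(adj3 <- adjust_controls(inside), "inside respirators")
  expect_equal(adj3$rpe_cmp, "90")

  clean <- adjust_controls(db)
  expect_equal(clean$lev_present_cmp, clean$lev_present)
  expect_equal(clean$rpe_cmp, c("none", "none"))
  again <- adjust_controls(clean)
  expect_equal(again$notes, clean$notes)
  expect_equal(again$lev_present_cmp, clean$lev_present_cmp)
})

test_that("control-credit removal can only raise the comparison estimate", {
  db <- build_records(generate_fixture_database(20, seed = 17))
  db <- db[db$included, ]
  with_credit <- db
  with_credit$lev_reported_effective <- NA
  without_credit <- db
  without_credit$lev_reported_effective <- FALSE
  est_with <- compare_records(with_credit)$tra_estimate
  est_without <- compare_records(without_credit)$tra_estimate
  expect_true(all(est_without >= est_with))
})

test_that("build_records validates schema, derives bands, and assigns deterministic ids", {
  path <- system.file("extdata", "example_studies.csv", package = "traworker")
  rec <- build_records(path)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$included))
  expect_equal(rec$proc, c(10, 2))

  no_units <- tibble::tibble(source_ref = "s", substance = "x", n = 10,
                             units = NA_character_)
  expect_error(build_records(no_units), "units")
  expect_error(build_records(tibble::tibble(source_ref = "s", n = 10)),
               "missing column")

  dup <- rec[c(1, 1), ]
  expect_error(build_records(dup), "duplicate record_id")

  anon <- tibble::tibble(
    source_ref = "Survey A", substance = "toluene", n = 8, units = "ppm",
    gm = 3, gsd = 1.7, proc = 5, setting = "industrial",
    physical_state = "liquid", vapour_pressure_kpa = 3,
    duration_min = 300, conc_band = ">25%", location = "indoor",
    general_ventilation = "basic", lev_present = FALSE)
  b1 <- build_records(anon)
  b2 <- build_records(anon)
  expect_identical(b1$record_id, b2$record_id)
  expect_equal(b1$dur_band, ">4 h")  # derived from 300 min
  expect_true(b1$included)
})

test_that("curated databases round-trip through CSV", {
  db <- build_records(generate_fixture_database(10, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curated_db(db, path)
  back <- read_curated_db(path)
  expect_equal(back$record_id, db$record_id)
  expect_equal(back$gm, db$gm, tolerance = 1e-9)
  expect_equal(back$included, db$included)
})
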