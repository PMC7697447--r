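test_that("both worked examples come out conservative with the published ratios", {
  res <- compare_records(generate_fixture_database(2, seed = 1))
  expect_equal(res$tra_estimate, c(35, 0.84))
  # quotients of the published pairs: 35 / 30.9 and 0.84 / 0.33
  expect_equal(res$ratio[1], 35 / 30.9, tolerance = 0.005)
  expect_equal(res$ratio[2], 0.84 / 0.33, tolerance = 1e-6)
  expect_equal(res$verdict, c("conservative", "conservative"))
  expect_equal(res$percentile_used, c(0.75, 0.75))
})

test_that("verdict classification follows the asymmetric CI rule", {
  db <- generate_fixture_database(2, seed = 1)[1, ]
  # estimate exactly equal to the measured point -> conservative (boundary)
  point <- lognormal_percentile(gm = db$gm, gsd = db$gsd, p = 0.75)
  tab <- tra_default_table()
  eq_tab <- unclass(tab)
  eq_tab$base_estimates$value[
    eq_tab$base_estimates$proc == 10 &
      eq_tab$base_estimates$setting == "industrial" &
      eq_tab$base_estimates$phase == "vapour" &
      eq_tab$base_estimates$band == "medium"] <- point / 0.7
  res_eq <- compare_records(db, do.call(tra_table, eq_tab))
  expect_equal(res_eq$ratio, 1)
  expect_equal(res_eq$verdict, "conservative")

  # estimate just under the point but inside the CI -> borderline, and an
  # estimate below the lower CI bound -> underestimate
  ci <- percentile_ci(new_lognormal_fit(db$gm, db$gsd, db$n), p = 0.75)
  for (target in list(c(0.99 * point, "borderline"),
                      c(0.5 * ci$ci_low, "underestimate"))) {
    eq_tab$base_estimates$value[
      eq_tab$base_estimates$proc == 10 &
        eq_tab$base_estimates$setting == "industrial" &
        eq_tab$base_estimates$phase == "vapour" &
        eq_tab$base_estimates$band == "medium"] <- as.numeric(target[1]) / 0.7
    res <- compare_records(db, do.call(tra_table, eq_tab))
    expect_equal(res$verdict, target[2], ignore_attr = TRUE)
  }
})

test_that("interpreting the output as a higher percentile can only lower the ratio", {
  db <- build_records(generate_fixture_database(15, seed = 11))
  db <- db[db$included & db$gsd > 1, ]
  r75 <- compare_records(db, p = 0.75)$ratio
  r90 <- compare_records(db, p = 0.90)$ratio
  expect_true(all(r90 <= r75))
})

test_that("verdicts and ratios are invariant under unit conversion of the measurements", {
  db <- generate_fixture_database(2, seed = 1)
  res_ppm <- compare_records(db)
  db_mg <- db
  db_mg$gm <- ppm_to_mgm3(db$gm, db$molecular_weight)
  db_mg$units <- "mg/m3"
  res_mg <- compare_records(db_mg)
  expect_equal(res_mg$ratio, res_ppm$ratio, tolerance = 1e-12)
  expect_equal(res_mg$verdict, res_ppm$verdict)

  db_nomw <- db_mg
  db_nomw$molecular_weight <- NA
  expect_error(compare_records(db_nomw), "no molecular weight")
})

test_that("excluded records are skipped, and an all-excluded set is an error", {
  db <- build_records(generate_fixture_database(2, seed = 1))
  bad <- db
  bad$n <- c(5, 4)
  expect_error(compare_records(apply_inclusion_rules(bad)), "inclusion criteria")
  mixed <- db
  mixed$n[1] <- 5
  mixed <- apply_inclusion_rules(mixed)
  expect_message(res <- compare_records(mixed), "excluded")
  expect_equal(nrow(res), 1)
})

test_that("database summaries aggregate verdicts and ratios, order-invariantly", {
  res <- compare_records(generate_fixture_database(2, seed = 1))
  s <- summarize_comparisons(res)
  expect_equal(s$n_records, 2)
  expect_equal(s$fraction_conservative, 1)
  expect_equal(s$ratio_distribution$geometric_mean,
               exp(mean(log(res$ratio))))
  expect_equal(sum(s$breakdown$n_records), s$n_records)

  one <- summarize_comparisons(res[1, ])
  expect_equal(one$n_records, 1)
  expect_equal(one$ratio_distribution$median, res$ratio[1])

  # a constructed mix with known verdicts
  fake <- res[c(1, 1, 1, 2), ]
  fake$verdict <- c("conservative", "borderline", "underestimate", "conservative")
  fake$record_id <- paste0("r", 1:4)
  s_mix <- summarize_comparisons(fake)
  expect_equal(s_mix$fraction_conservative, 0.5)
  expect_equal(sum(s_mix$verdicts$n_records), 4)
  shuffled <- summarize_comparisons(fake[c(3, 1, 4, 2), ])
  expect_equal(shuffled$fraction_conservative, s_mix$fraction_conservative)
  expect_equal(shuffled$ratio_distribution, s_mix$ratio_distribution)

  expect_error(summarize_comparisons(res[0, ]), "non-empty")
})

test_that("comparison results round-trip through the deterministic writer", {
  res <- compare_records(generate_fixture_database(2, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".json")
  write_comparison_results(res, path, summary_path = spath)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$ratio, signif(res$ratio, 6))
  expect_equal(back$verdict, res$verdict)
  js <- jsonlite::read_json(spath, simplifyVector = TRUE)
  expect_equal(js$n_records, 2)
  expect_equal(js$fraction_conservative, 1)
  b1 <- readBin(path, "raw", file.size(path))
  write_comparison_results(res, path)
  expect_identical(readBin(path, "raw", file.size(path)), b1)
  expect_warning(write_comparison_results(res[0, ], path), "empty")
})
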