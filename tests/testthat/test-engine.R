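test_that("the engine reproduces both published worked-example estimates", {
  e1 <- tra_estimate(printing_scenario())
  expect_equal(e1$estimate, 35)
  expect_equal(e1$units, "ppm")
  expect_equal(e1$fugacity_band, "medium")
  expect_equal(e1$conc_band, ">25%")
  expect_equal(e1$dur_band, ">4 h")

  e2 <- tra_estimate(theatre_scenario())
  expect_equal(e2$estimate, 0.84)
  expect_equal(e2$fugacity_band, "high")
  expect_equal(e2$base_estimate, 50)
})

test_that("every estimate decomposes exactly as base times the five factors", {
  est <- tra_estimate(scenario_grid())
  expect_equal(est$estimate,
               est$base_estimate * est$f_conc * est$f_dur * est$f_gv *
                 est$f_lev * est$f_rpe,
               tolerance = 0)
  expect_true(all(est$percentile_semantics == 0.75))
  # identity case: no controls, widest bands, basic ventilation
  base_only <- est[est$conc_band == ">25%" & est$dur_band == ">4 h" &
                     est$general_ventilation == "basic" &
                     !est$lev_present & est$rpe == "none", ]
  expect_equal(base_only$estimate, base_only$base_estimate)
  expect_equal(base_only$f_conc * base_only$f_dur * base_only$f_gv *
                 base_only$f_lev * base_only$f_rpe,
               rep(1, nrow(base_only)))
})

test_that("weakening any single control or widening a band never decreases the estimate", {
  sc <- scenario_grid()
  est <- tra_estimate(sc)
  weaken <- list(
    function(s) { s$lev_present <- FALSE; s },
    function(s) { s$general_ventilation <- "basic"; s },
    function(s) { s$rpe <- "none"; s },
    function(s) { s$conc_band <- ">25%"; s },
    function(s) { s$dur_band <- ">4 h"; s })
  for (w in weaken) {
    expect_true(all(tra_estimate(w(sc))$estimate >= est$estimate))
  }
})

test_that("solids are estimated in mg/m3 from their dustiness band", {
  solid <- tibble::tibble(
    substance = "lactose", physical_state = "solid", dustiness = "medium",
    proc = 5, setting = "industrial", conc_band = ">25%", dur_band = ">4 h",
    location = "indoor", general_ventilation = "basic", lev_present = FALSE)
  e <- tra_estimate(solid)
  expect_equal(e$units, "mg/m3")
  expect_equal(e$estimate, lookup_base_estimate(tra_default_table(), 5,
                                                "industrial", "medium", "dust")$value)
})

test_that("engine rejects invalid scenario input with clear messages", {
  sc <- printing_scenario()
  sc$proc <- 30
  expect_error(tra_estimate(sc), "PROC")
  sc <- printing_scenario()
  sc$setting <- "domestic"
  expect_error(tra_estimate(sc), "setting")
  sc <- printing_scenario()[, setdiff(names(printing_scenario()), c("concentration_pct"))]
  expect_error(tra_estimate(sc), "conc_band or concentration_pct")
  expect_error(tra_estimate(printing_scenario()[0, ]), "at least one row")
})

test_that("outdoor scenarios use the outdoor ventilation factor and ignore the indoor class", {
  sc <- printing_scenario()
  sc$location <- "outdoor"
  sc$general_ventilation <- "basic"
  out_basic <- tra_estimate(sc)
  sc$general_ventilation <- "enhanced"
  out_enh <- tra_estimate(sc)
  expect_equal(out_basic$f_gv, 0.7)
  expect_equal(out_basic$estimate, out_enh$estimate)
})
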