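# Shared fixtures: the two published worked-example scenarios.

printing_scenario <- function() {
  tibble::tibble(
    substance = "isopropanol", physical_state = "liquid",
    vapour_pressure_kpa = 4.1, molecular_weight = 60.10,
    proc = 10, setting = "industrial",
    concentration_pct = 100, duration_min = 480,
    location = "indoor", general_ventilation = "good",
    lev_present = FALSE, rpe = "none")
}

theatre_scenario <- function() {
  tibble::tibble(
    substance = "sevoflurane", physical_state = "liquid",
    vapour_pressure_kpa = 26, molecular_weight = 200.05,
    proc = 2, setting = "professional",
    conc_band = "1-5%", dur_band = "1-4 h",
    location = "indoor", general_ventilation = "good",
    lev_present = TRUE, rpe = "none")
}

# a deterministic grid of valid scenarios for property-style loops
scenario_grid <- function() {
  grid <- expand.grid(
    setting = c("industrial", "professional"),
    band = c("low", "medium", "high"),
    conc_band = c("<1%", ">25%"),
    dur_band = c("15-60 min", ">4 h"),
    general_ventilation = c("basic", "good"),
    lev_present = c(FALSE, TRUE),
    rpe = c("none", "90"),
    stringsAsFactors = FALSE)
  vp <- c(low = 0.1, medium = 4, high = 20)
  tibble::tibble(
    substance = "grid", physical_state = "liquid",
    vapour_pressure_kpa = unname(vp[grid$band]),
    proc = 5, setting = grid$setting,
    conc_band = grid$conc_band, dur_band = grid$dur_band,
    location = "indoor", general_ventilation = grid$general_ventilation,
    lev_present = grid$lev_present, rpe = grid$rpe)
}
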