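#' Generate a synthetic workplace measurement set
#'
#' Draws `n` exposure measurements from a lognormal distribution with the
#' stated geometric mean and geometric standard deviation. Two sampling
#' strategies are available:
#' \describe{
#'   \item{random}{independent draws — a representative measurement survey.}
#'   \item{compliance_biased}{emulates compliance-oriented measurement
#'     campaigns that deliberately target operations and workers expected to
#'     have elevated exposure: with probability `bias_prob` a draw is taken
#'     from the distribution truncated below its `bias_quantile` quantile,
#'     otherwise from the full distribution. Observed percentiles therefore
#'     stochastically exceed those of the true distribution, the hazard such
#'     datasets pose when used to judge an exposure model.}
#' }
#' Identical `spec + seed` always yields identical output.
#'
#' @param gm True geometric mean (> 0).
#' @param gsd True geometric standard deviation (>= 1). `gsd = 1` yields `n`
#'   copies of `gm` exactly.
#' @param n Number of measurements (>= 1).
#' @param seed Integer seed; required, no hidden RNG state.
#' @param units `"ppm"` or `"mg/m3"`.
#' @param strategy `"random"` or `"compliance_biased"`.
#' @param bias_quantile Truncation quantile for the biased strategy,
#'   default 0.5 (draws forced above the true median).
#' @param bias_prob Fraction of draws subject to the truncation,
#'   default 0.8.
#' @param sample_durations Optional durations (minutes) attached to the set.
#' @return A [measurement_set()] carrying the generated raw values; the true
#'   parameters are attached as attribute `ground_truth`.
#' @examples
#' ms <- generate_measurements(gm = 24.1, gsd = 1.44, n = 13, seed = 7)
#' fit_lognormal(ms)
#' @export
generate_measurements <- function(gm, gsd, n, seed, units = "ppm",
                                  strategy = c("random", "compliance_biased"),
                                  bias_quantile = 0.5, bias_prob = 0.8,
                                  sample_durations = NULL) {
  strategy <- match.arg(strategy)
  if (!is.numeric(gm) || gm <= 0) abort("gm must be > 0")
  if (!is.numeric(gsd) || gsd < 1) abort("gsd must be >= 1")
  if (!is.numeric(n) || n < 1 || n != round(n)) abort("n must be a positive integer")
  if (missing(seed) || is.null(seed)) abort("seed is required for reproducibility")
  if (bias_quantile <= 0 || bias_quantile >= 1) abort("bias_quantile must be in (0, 1)")
  if (bias_prob < 0 || bias_prob > 1) abort("bias_prob must be in [0, 1]")

  mu <- log(gm)
  sigma <- log(gsd)
  values <- withr::with_seed(as.integer(seed), {
    if (strategy == "random") {
      rlnorm(n, mu, sigma)
    } else {
      # inverse-CDF draw: biased draws use u ~ U(bias_quantile, 1)
      biased <- stats::runif(n) < bias_prob
      u <- stats::runif(n)
      u[biased] <- bias_quantile + u[biased] * (1 - bias_quantile)
      stats::qlnorm(u, mu, sigma)
    }
  })
  ms <- measurement_set(values = values, units = units,
                        sample_durations = sample_durations,
                        context = list(strategy = strategy, seed = seed))
  attr(ms, "ground_truth") <- list(gm = gm, gsd = gsd, n = n,
                                   strategy = strategy,
                                   bias_quantile = bias_quantile,
                                   bias_prob = bias_prob)
  ms
}

# The two published worked-example records every fixture database carries.
# Record wex-2's measured GSD is synthetic (2.0, a typical workplace spread)
# with the GM back-solved so that the lognormal P75 equals the published
# 0.33 ppm; the study's 42 raw values were never published.
worked_example_records <- function() {
  tibble::tibble(
    record_id = c("wex-1-isopropanol-printing", "wex-2-sevoflurane-theatre"),
    source_ref = c("industrial printing survey (isopropanol)",
                   "operating-theatre anaesthetic survey (sevoflurane)"),
    substance = c("isopropanol", "sevoflurane"),
    cas = c("67-63-0", "28523-86-6"),
    molecular_weight = c(60.10, 200.05),
    physical_state = "liquid",
    vapour_pressure_kpa = c(4.1, 26),
    dustiness = NA_character_,
    proc = c(10, 2),
    setting = c("industrial", "professional"),
    conc_band = c(">25%", "1-5%"),
    dur_band = c(">4 h", "1-4 h"),
    duration_min = c(480, 120),
    sampling_duration_min = c(480, 360),
    location = "indoor",
    general_ventilation = "good",
    lev_present = c(FALSE, TRUE),
    lev_reported_effective = NA,
    rpe = "none",
    rpe_worn = FALSE,
    measurement_inside_rpe = NA,
    n = c(13, 42),
    gm = c(24.1, 0.33 / 2^qnorm(0.75)),
    gsd = c(1.44, 2.0),
    units = "ppm",
    true_gm = NA_real_,
    true_gsd = NA_real_,
    notes = c("13 samples, 320-572 min; GM 59.3 mg/m3 (24.1 ppm), GSD 1.44",
              "42 samples; published measured P75 0.33 ppm; GSD synthetic (2.0), GM back-solved to match")
  )
}

#' Generate a synthetic curated-database fixture
#'
#' Builds a curated-record table with known ground truth so curation,
#' comparison and summary logic are testable without any external data. The
#' first two records are always the two published worked examples
#' (isopropanol printing / PROC 10 and sevoflurane operating theatre /
#' PROC 2); further records are drawn over PROCs, settings and bands
#' supported by `table`, with measured distributions generated around the
#' scenario's own TRA estimate and the generating parameters stored in
#' `true_gm` / `true_gsd` columns for assertions.
#'
#' A fraction of the synthetic records is deliberately defective to exercise
#' the inclusion rules: `p_small_n` get fewer than six measurements and
#' `p_missing_proc` lose their PROC assignment.
#'
#' @param n_records Total records (>= 2; the first two are the worked
#'   examples).
#' @param seed Integer seed.
#' @param table Parameter table used to pick supported scenarios.
#' @param p_small_n,p_missing_proc Fractions of synthetic records made to
#'   fail the n >= 6 and PROC-assignable inclusion criteria.
#' @return A tibble in the curated-database schema (see [build_records()]).
#' @export
generate_fixture_database <- function(n_records, seed,
                                      table = tra_default_table(),
                                      p_small_n = 0.15,
                                      p_missing_proc = 0.1) {
  if (n_records < 2) abort("n_records must be >= 2 (the two worked examples are always included)")
  wex <- worked_example_records()
  if (n_records == 2) return(wex)
  n_syn <- n_records - 2

  be <- table$base_estimates
  be <- be[be$phase == "vapour", ]
  syn <- withr::with_seed(as.integer(seed), {
    pick <- be[sample.int(nrow(be), n_syn, replace = TRUE), ]
    vp <- c(low = 0.1, medium = 4, high = 20)[pick$band]
    conc_band <- sample(CONC_BANDS, n_syn, replace = TRUE)
    dur_band <- sample(DURATION_BANDS, n_syn, replace = TRUE)
    gv <- sample(c("basic", "good", "enhanced"), n_syn, replace = TRUE)
    lev <- sample(c(TRUE, FALSE), n_syn, replace = TRUE)
    sc <- tibble::tibble(
      substance = sprintf("synthetic-substance-%02d", seq_len(n_syn)),
      physical_state = "liquid", vapour_pressure_kpa = unname(vp),
      proc = pick$proc, setting = pick$setting,
      conc_band = conc_band, dur_band = dur_band,
      location = "indoor", general_ventilation = gv,
      lev_present = lev, rpe = "none")
    est <- tra_estimate(sc, table)$estimate
    # measured GM set near the estimate so verdicts span both directions
    true_gsd <- exp(stats::runif(n_syn, log(1.3), log(3)))
    true_gm <- est * exp(stats::rnorm(n_syn, -0.5, 0.6)) / true_gsd^qnorm(0.75)
    n_i <- sample(8:30, n_syn, replace = TRUE)
    small <- stats::runif(n_syn) < p_small_n
    n_i[small] <- sample(2:5, sum(small), replace = TRUE)
    noproc <- stats::runif(n_syn) < p_missing_proc
    fits <- purrr::map(seq_len(n_syn), function(i) {
      fit_lognormal(rlnorm(n_i[i], log(true_gm[i]), log(true_gsd[i])))
    })
    tibble::tibble(
      record_id = sprintf("syn-%03d", seq_len(n_syn)),
      source_ref = sprintf("synthetic study %d (seed %d)", seq_len(n_syn), as.integer(seed)),
      substance = sc$substance, cas = NA_character_,
      molecular_weight = 100, physical_state = "liquid",
      vapour_pressure_kpa = sc$vapour_pressure_kpa, dustiness = NA_character_,
      proc = ifelse(noproc, NA_real_, sc$proc), setting = sc$setting,
      conc_band = sc$conc_band, dur_band = sc$dur_band,
      duration_min = NA_real_, sampling_duration_min = NA_real_,
      location = sc$location, general_ventilation = sc$general_ventilation,
      lev_present = sc$lev_present, lev_reported_effective = NA,
      rpe = "none", rpe_worn = FALSE, measurement_inside_rpe = NA,
      n = n_i,
      gm = purrr::map_dbl(fits, "gm"), gsd = purrr::map_dbl(fits, "gsd"),
      units = "ppm",
      true_gm = true_gm, true_gsd = true_gsd,
      notes = "synthetic record with embedded ground truth")
  })
  dplyr::bind_rows(wex, syn)
}
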