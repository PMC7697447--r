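#' Compare TRA estimates against measured percentiles
#'
#' For every included curated record: build the control-adjusted comparison
#' scenario (via [adjust_controls()]), compute the model estimate, compute
#' the measured percentile at `p` with its confidence interval, reconcile
#' units (measurements in mg/m3 are converted to ppm through the molecular
#' weight when the estimate is in ppm, and vice versa), and classify:
#' \describe{
#'   \item{conservative}{estimate >= measured percentile point (the model
#'     over- or exactly predicts — its intended screening behaviour).}
#'   \item{underestimate}{estimate below the *lower confidence bound* of the
#'     measured percentile — the asymmetric rule: a validity conclusion must
#'     not be drawn when uncertainty could hide underestimation, so a point
#'     estimate below the percentile but inside its CI is only borderline.}
#'   \item{borderline}{between the two.}
#' }
#'
#' @param records Curated-record tibble ([build_records()] output or the
#'   same schema). Excluded records are dropped with a message; comparing a
#'   single excluded record is an error.
#' @param table A `tra_table`.
#' @param p Percentile the model output is interpreted as; default 0.75
#'   (the tool's nominal semantics). Setting `p = 0.90` reproduces the
#'   alternative 90th-percentile reading side by side.
#' @param ci_level Confidence level for the measured percentile, default 0.95.
#' @return Tibble of class `tra_comparisons`: `record_id`, `tra_estimate`,
#'   `units`, `measured_point`, `measured_ci_low`, `measured_ci_high`,
#'   `ratio` (= estimate / measured point, > 1 means conservative),
#'   `verdict`, `percentile_used`, plus scenario keys for stratification.
#' @export
compare_records <- function(records, table = tra_default_table(),
                            p = 0.75, ci_level = 0.95) {
  rec <- tibble::as_tibble(records)
  if (!nrow(rec)) abort("no records to compare")
  if (!"included" %in% names(rec)) rec <- apply_inclusion_rules(rec)
  if (all(!rec$included)) {
    abort("no included records: all rows fail the inclusion criteria")
  }
  if (any(!rec$included)) {
    message(sum(!rec$included), " excluded record(s) skipped")
    rec <- rec[rec$included, ]
  }
  if (!"lev_present_cmp" %in% names(rec)) rec <- adjust_controls(rec)

  scenario <- tibble::tibble(
    substance = rec$substance,
    physical_state = rec$physical_state,
    vapour_pressure_kpa = rec$vapour_pressure_kpa,
    dustiness = rec$dustiness,
    proc = rec$proc, setting = rec$setting,
    conc_band = rec$conc_band, dur_band = rec$dur_band,
    location = rec$location, general_ventilation = rec$general_ventilation,
    lev_present = rec$lev_present_cmp, rpe = rec$rpe_cmp)
  est <- tra_estimate(scenario, table)

  measured <- purrr::map(seq_len(nrow(rec)), function(i) {
    fit <- new_lognormal_fit(rec$gm[i], rec$gsd[i], rec$n[i], rec$units[i])
    ci <- percentile_ci(fit, p = p, level = ci_level, method = "parametric")
    target <- est$units[i]
    if (normalize_units(rec$units[i]) != normalize_units(target)) {
      if (is.na(rec$molecular_weight[i])) {
        abort(paste0("record ", rec$record_id[i], ": measurements in ",
                     rec$units[i], " but estimate in ", target,
                     " and no molecular weight available for conversion"))
      }
      ci[c("point", "ci_low", "ci_high")] <-
        lapply(ci[c("point", "ci_low", "ci_high")], convert_units,
               from = rec$units[i], to = target,
               molecular_weight = rec$molecular_weight[i])
    }
    ci
  })

  point <- purrr::map_dbl(measured, "point")
  out <- tibble::tibble(
    record_id = rec$record_id,
    proc = rec$proc, setting = rec$setting,
    fugacity_band = est$fugacity_band,
    tra_estimate = est$estimate, units = est$units,
    measured_point = point,
    measured_ci_low = purrr::map_dbl(measured, "ci_low"),
    measured_ci_high = purrr::map_dbl(measured, "ci_high"),
    n = rec$n,
    ratio = est$estimate / point,
    percentile_used = p)
  out$verdict <- dplyr::case_when(
    out$tra_estimate >= out$measured_point ~ "conservative",
    out$tra_estimate < out$measured_ci_low ~ "underestimate",
    TRUE ~ "borderline")
  class(out) <- c("tra_comparisons", class(out))
  out
}

#' Summarize model performance over a comparison database
#'
#' Aggregates [compare_records()] output: record count, the fraction of
#' records where the model was conservative, the distribution of
#' model/measured ratios (geometric mean and quartiles), and verdict counts
#' stratified by PROC, setting and fugacity band — the combinations that
#' were actually studied, which is what a partial validation can and cannot
#' claim.
#'
#' @param results A `tra_comparisons` tibble (non-empty).
#' @return List of class `tra_db_summary`: `n_records`,
#'   `fraction_conservative`, `ratio_distribution` (one-row tibble),
#'   `verdicts` (counts), `breakdown` (per PROC x setting x band tibble).
#'   [glance()] returns the scalars as one row.
#' @export
summarize_comparisons <- function(results) {
  if (!is.data.frame(results) || !nrow(results)) {
    abort("results must be a non-empty comparison table")
  }
  res <- dplyr::arrange(tibble::as_tibble(results), .data$record_id)
  ratio_q <- quantile(res$ratio, c(0.25, 0.5, 0.75), type = 7)
  breakdown <- res |>
    dplyr::count(.data$proc, .data$setting, .data$fugacity_band,
                 .data$verdict, name = "n_records") |>
    dplyr::arrange(.data$proc, .data$setting, .data$fugacity_band, .data$verdict)
  structure(list(
    n_records = nrow(res),
    fraction_conservative = mean(res$verdict == "conservative"),
    ratio_distribution = tibble::tibble(
      geometric_mean = exp(mean(log(res$ratio))),
      q25 = unname(ratio_q[1]), median = unname(ratio_q[2]),
      q75 = unname(ratio_q[3]),
      min = min(res$ratio), max = max(res$ratio)),
    verdicts = res |> dplyr::count(.data$verdict, name = "n_records") |>
      dplyr::arrange(.data$verdict),
    breakdown = breakdown),
    class = "tra_db_summary")
}

#' @export
print.tra_db_summary <- function(x, ...) {
  cat("<tra_db_summary>", x$n_records, "records |",
      sprintf("%.0f%% conservative", 100 * x$fraction_conservative), "\n")
  cat("  ratio (model/measured): GM",
      signif(x$ratio_distribution$geometric_mean, 3),
      " IQR [", signif(x$ratio_distribution$q25, 3), ",",
      signif(x$ratio_distribution$q75, 3), "]\n")
  print(x$verdicts)
  invisible(x)
}

#' Glance at a database summary
#'
#' @param x A `tra_db_summary`.
#' @param ... Unused.
#' @return One-row tibble: `n_records`, `fraction_conservative`,
#'   `ratio_gm`, `ratio_median`.
#' @method glance tra_db_summary
#' @export
glance.tra_db_summary <- function(x, ...) {
  tibble::tibble(n_records = x$n_records,
                 fraction_conservative = x$fraction_conservative,
                 ratio_gm = x$ratio_distribution$geometric_mean,
                 ratio_median = x$ratio_distribution$median)
}

#' Write comparison results
#'
#' Deterministic CSV writer (fixed column order, numbers at 6 significant
#' digits) plus a JSON summary alongside when `summary_path` is given.
#' Writing an empty result set produces a header-only file with a warning.
#'
#' @param results `tra_comparisons` tibble.
#' @param path Output CSV path.
#' @param summary_path Optional JSON path for [summarize_comparisons()]
#'   output.
#' @return `path`, invisibly.
#' @export
write_comparison_results <- function(results, path, summary_path = NULL) {
  res <- tibble::as_tibble(results)
  if (!nrow(res)) warn("writing an empty results table (header only)")
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(x) signif(x, 6))
  readr::write_csv(res, path, na = "")
  if (!is.null(summary_path) && nrow(res)) {
    s <- summarize_comparisons(results)
    jsonlite::write_json(
      list(n_records = s$n_records,
           fraction_conservative = s$fraction_conservative,
           ratio_distribution = as.list(s$ratio_distribution),
           verdicts = s$verdicts, breakdown = s$breakdown),
      summary_path, auto_unbox = TRUE, digits = 6)
  }
  invisible(path)
}
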