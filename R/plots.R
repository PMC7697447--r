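#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted exposure distribution
#'
#' Histogram of the measurements (when raw values are available) with the
#' fitted lognormal density and the fitted P75 marked — the quantity a
#' Tier-1 screening estimate is compared against.
#'
#' @param object A `lognormal_fit` or [measurement_set()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lognormal_fit
#' @export
autoplot.lognormal_fit <- function(object, bins = 15, ...) {
  fit <- object
  grid <- exp(seq(log(fit$gm) - 3.5 * log(max(fit$gsd, 1.01)),
                  log(fit$gm) + 3.5 * log(max(fit$gsd, 1.01)), length.out = 200))
  dens <- tibble::tibble(
    x = grid,
    density = stats::dlnorm(grid, log(fit$gm), log(fit$gsd)))
  p75 <- lognormal_percentile(fit, 0.75)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = p75, linetype = "dashed") +
    ggplot2::annotate("text", x = p75, y = max(dens$density), hjust = -0.1,
                      vjust = 1, label = paste0("P75 = ", signif(p75, 3))) +
    ggplot2::labs(x = paste0("concentration",
                             if (!is.null(fit$units)) paste0(" (", fit$units, ")")),
                  y = "density",
                  title = sprintf("Fitted lognormal: GM %.3g, GSD %.3g, n = %d",
                                  fit$gm, fit$gsd, fit$n)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lognormal_fit
#' @method autoplot measurement_set
#' @export
autoplot.measurement_set <- function(object, bins = 15, ...) {
  fit <- fit_lognormal(object)
  p <- autoplot(fit, bins = bins)
  if (!is.null(object$values)) {
    p <- p + ggplot2::geom_rug(
      data = tibble::tibble(x = object$values),
      ggplot2::aes(x = .data$x), inherit.aes = FALSE, alpha = 0.6)
  }
  p
}

#' Plot model-versus-measurement comparisons
#'
#' Scatter of TRA estimate against measured percentile (with its CI) on
#' log-log axes; the identity line separates conservative (above) from
#' under-predicting (below) records, colour-coded by verdict.
#'
#' @param object A `tra_comparisons` tibble from [compare_records()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tra_comparisons
#' @export
autoplot.tra_comparisons <- function(object, ...) {
  res <- tibble::as_tibble(object)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$measured_point,
                                    y = .data$tra_estimate,
                                    colour = .data$verdict)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$measured_ci_low,
                                         xmax = .data$measured_ci_high),
                            height = 0, alpha = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("measured P%d (with %d%% CI)",
                              round(100 * res$percentile_used[1]),
                              95),
                  y = "TRA estimate",
                  colour = "verdict",
                  title = "Model estimate vs measured percentile") +
    ggplot2::theme_minimal()
}

#' Factor-breakdown bar chart for estimates
#'
#' Shows, per scenario, the base estimate and the multiplicative reduction
#' each modifier contributes — the audit trail behind every number the
#' engine produces.
#'
#' @param estimates Output of [tra_estimate()].
#' @return A ggplot object.
#' @export
plot_factor_breakdown <- function(estimates) {
  est <- tibble::as_tibble(estimates)
  est$scenario <- if ("substance" %in% names(est)) {
    paste0(est$substance, " (PROC ", est$proc, ")")
  } else paste0("PROC ", est$proc, " / ", est$setting)
  long <- tidyr::pivot_longer(
    est[c("scenario", "f_conc", "f_dur", "f_gv", "f_lev", "f_rpe")],
    -"scenario", names_to = "modifier", values_to = "factor")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$modifier, y = .data$factor)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(y = "multiplicative factor", x = NULL,
                  title = "Modifier breakdown (1 = no reduction)") +
    ggplot2::theme_minimal()
}
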