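#' Measurement sets
#'
#' A `measurement_set` bundles workplace exposure measurements — either raw
#' positive values or a GM/GSD/n summary — with their units and context.
#' Raw values must all be positive (non-detects and censored values are out
#' of scope; inputs must be detected values).
#'
#' @param values Numeric vector of positive concentrations, or `NULL` when a
#'   summary is supplied.
#' @param gm,gsd,n Summary statistics: geometric mean (> 0), geometric
#'   standard deviation (>= 1), number of measurements (>= 1). Ignored when
#'   `values` is given.
#' @param units `"ppm"` or `"mg/m3"`.
#' @param sample_durations Optional vector of sampling durations, minutes.
#' @param context Optional free-text or list context metadata.
#' @return An object of class `measurement_set`.
#' @examples
#' measurement_set(gm = 24.1, gsd = 1.44, n = 13, units = "ppm")
#' @export
measurement_set <- function(values = NULL, gm = NULL, gsd = NULL, n = NULL,
                            units, sample_durations = NULL, context = NULL) {
  units <- normalize_units(units)
  if (!is.null(values)) {
    if (!is.numeric(values) || !length(values)) abort("values must be a non-empty numeric vector")
    if (any(!is.finite(values) | values <= 0)) abort("all measurement values must be > 0")
    n <- length(values)
    gm <- NULL
    gsd <- NULL
  } else {
    if (is.null(gm) || is.null(gsd) || is.null(n)) {
      abort("supply raw values or a full (gm, gsd, n) summary")
    }
    if (gm <= 0) abort("gm must be > 0")
    if (gsd < 1) abort("gsd must be >= 1")
    if (n < 1 || n != round(n)) abort("n must be a positive integer")
  }
  structure(list(values = values, gm = gm, gsd = gsd, n = n, units = units,
                 sample_durations = sample_durations, context = context),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set> n =", x$n, "|", x$units,
      if (is.null(x$values)) "(summary only)" else "(raw values)", "\n")
  if (!is.null(x$gm)) cat("  gm =", x$gm, " gsd =", x$gsd, "\n")
  invisible(x)
}

#' Fit a lognormal summary to exposure measurements
#'
#' Computes the geometric mean `exp(mean(log x))` and geometric standard
#' deviation `exp(sd(log x))` (sample sd, n-1 denominator) of positive
#' measurements. A summary-only [measurement_set()] passes through
#' unchanged. Workplace exposure concentrations are conventionally treated
#' as lognormal, so (GM, GSD) fully parameterize the fitted distribution.
#'
#' @param x Numeric vector of positive values (n >= 2), a
#'   [measurement_set()], or a data frame with a `value` column.
#' @param units Units label attached to the fit when `x` is a bare vector.
#' @return Object of class `lognormal_fit` with fields `gm`, `gsd`, `n`,
#'   `units`. [tidy()] and [glance()] methods are available.
#' @examples
#' fit_lognormal(c(1, exp(2)))  # gm = e, gsd = e^sqrt(2)
#' @export
fit_lognormal <- function(x, units = NULL) {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) abort("data frame input needs a 'value' column")
    units <- units %||% if ("units" %in% names(x)) unique(x$units) else NULL
    x <- x$value
  }
  if (inherits(x, "measurement_set")) {
    units <- x$units
    if (is.null(x$values)) {
      return(new_lognormal_fit(x$gm, x$gsd, x$n, units))
    }
    x <- x$values
  }
  if (!is.numeric(x)) abort("x must be numeric")
  if (any(!is.finite(x) | x <= 0)) abort("all measurement values must be > 0")
  if (length(x) < 2) abort("at least 2 raw values are required to fit gm and gsd")
  lx <- log(x)
  new_lognormal_fit(exp(mean(lx)), exp(sd(lx)), length(x), units)
}

new_lognormal_fit <- function(gm, gsd, n, units = NULL) {
  structure(list(gm = gm, gsd = gsd, n = n, units = units),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("<lognormal_fit> gm =", signif(x$gm, 4), " gsd =", signif(x$gsd, 4),
      " n =", x$n, if (!is.null(x$units)) paste0(" [", x$units, "]"), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a lognormal fit
#'
#' @param x A `lognormal_fit`.
#' @param ... Unused.
#' @return One row per parameter (`gm`, `gsd`) with its estimate.
#' @method tidy lognormal_fit
#' @export
tidy.lognormal_fit <- function(x, ...) {
  tibble::tibble(term = c("gm", "gsd"), estimate = c(x$gm, x$gsd))
}

#' @rdname tidy.lognormal_fit
#' @return `glance()`: a one-row tibble with `gm`, `gsd`, `n`, `p50`, `p75`.
#' @method glance lognormal_fit
#' @export
glance.lognormal_fit <- function(x, ...) {
  tibble::tibble(gm = x$gm, gsd = x$gsd, n = x$n,
                 p50 = x$gm, p75 = lognormal_percentile(x, 0.75))
}

#' Lognormal percentile
#'
#' The p-th quantile of a lognormal distribution with geometric mean `gm`
#' and geometric standard deviation `gsd`: `gm * gsd^qnorm(p)`. The Tier-1
#' tool output is compared against the 75th percentile
#' (`z_0.75 = 0.6745`), so `p = 0.75` is the default.
#'
#' @param fit A `lognormal_fit`, or anything with `gm`/`gsd` fields (a list
#'   or one-row data frame); alternatively supply `gm` and `gsd` directly.
#' @param p Probability in (0, 1); vectorized.
#' @param gm,gsd Direct parameter interface (used when `fit` is missing).
#' @return Concentration(s) at the requested percentile(s).
#' @examples
#' lognormal_percentile(gm = 24.1, gsd = 1.44, p = 0.75)  # ~30.8 ppm
#' @export
lognormal_percentile <- function(fit = NULL, p = 0.75, gm = NULL, gsd = NULL) {
  if (!is.null(fit)) {
    gm <- fit$gm
    gsd <- fit$gsd
  }
  if (is.null(gm) || is.null(gsd)) abort("supply a fit or gm and gsd")
  if (any(p <= 0 | p >= 1)) abort("p must lie strictly between 0 and 1")
  if (any(gm <= 0)) abort("gm must be > 0")
  if (any(gsd < 1)) abort("gsd must be >= 1")
  gm * gsd^qnorm(p)
}

#' Empirical (order-statistic) percentile
#'
#' Nonparametric percentile using linear interpolation between order
#' statistics (the rule where the p-th percentile of n sorted values sits at
#' rank `1 + p(n-1)`, interpolating linearly — `stats::quantile` type 7).
#' Provided as the distribution-free alternative to
#' [lognormal_percentile()] for model-measurement comparisons.
#'
#' @param values Non-empty numeric vector.
#' @param p Probability in \[0, 1\]; vectorized.
#' @return Interpolated percentile(s).
#' @examples
#' empirical_percentile(1:100, 0.75)  # 75.25
#' @export
empirical_percentile <- function(values, p = 0.75) {
  if (!is.numeric(values) || !length(values)) abort("values must be a non-empty numeric vector")
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  unname(quantile(values, probs = p, type = 7))
}

#' Percentile with confidence interval
#'
#' Computes a percentile of the exposure distribution with a confidence
#' interval, for comparison against a Tier-1 estimate that nominally
#' represents the 75th percentile. At least six measurements are required —
#' the minimum the curation rules accept as able to support a 75th
#' percentile with a meaningful confidence interval.
#'
#' Methods:
#' \describe{
#'   \item{parametric}{exact bounds for a lognormal quantile via the
#'     noncentral-t construction used for normal tolerance limits (EN 689
#'     lineage): on the log scale the `1-alpha` CI for `mu + z_p sigma` is
#'     `xbar + t(alpha/2 | 1-alpha/2; n-1, ncp = z_p sqrt(n)) * s / sqrt(n)`.
#'     Works from raw values or a GM/GSD/n summary.}
#'   \item{bootstrap}{percentile bootstrap of the empirical percentile;
#'     requires raw values and a `seed` (no hidden RNG state), with at
#'     least 2000 resamples.}
#' }
#'
#' @param x A [measurement_set()], `lognormal_fit`, or numeric vector of raw
#'   values.
#' @param p Percentile probability in (0, 1), default 0.75.
#' @param level Two-sided confidence level, default 0.95.
#' @param method `"parametric"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (>= 2000).
#' @param seed Integer seed, required for `method = "bootstrap"`.
#' @return A one-row tibble of class `percentile_estimate`: `p`, `point`,
#'   `ci_low`, `ci_high`, `ci_level`, `method`, `n`.
#' @examples
#' set.seed(1)
#' percentile_ci(rlnorm(13, log(24.1), log(1.44)), p = 0.75)
#' @export
percentile_ci <- function(x, p = 0.75, level = 0.95,
                          method = c("parametric", "bootstrap"),
                          n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  if (p <= 0 || p >= 1) abort("p must lie strictly between 0 and 1")
  if (level <= 0 || level >= 1) abort("level must lie strictly between 0 and 1")

  values <- NULL
  if (inherits(x, "measurement_set")) {
    values <- x$values
    fit <- fit_lognormal(x)
  } else if (inherits(x, "lognormal_fit")) {
    fit <- x
  } else if (is.numeric(x)) {
    values <- x
    fit <- fit_lognormal(x)
  } else {
    abort("x must be a measurement_set, lognormal_fit or numeric vector")
  }
  if (fit$n < 6) {
    abort(paste0("n = ", fit$n, " measurements: the inclusion criteria require ",
                 "a minimum of six to compute a percentile with its confidence interval"))
  }

  if (method == "parametric") {
    n <- fit$n
    mu <- log(fit$gm)
    s <- log(fit$gsd)
    zp <- qnorm(p)
    alpha <- 1 - level
    ncp <- zp * sqrt(n)
    point <- exp(mu + zp * s)
    lo <- exp(mu + qt(alpha / 2, n - 1, ncp) * s / sqrt(n))
    hi <- exp(mu + qt(1 - alpha / 2, n - 1, ncp) * s / sqrt(n))
  } else {
    if (is.null(values)) abort("bootstrap requires raw measurement values")
    if (is.null(seed)) abort("bootstrap requires an explicit integer seed")
    if (n_boot < 2000) abort("use at least 2000 bootstrap resamples")
    n <- length(values)
    point <- empirical_percentile(values, p)
    boot <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(i) {
        empirical_percentile(sample(values, n, replace = TRUE), p)
      }, numeric(1))
    })
    alpha <- 1 - level
    lo <- unname(quantile(boot, alpha / 2, type = 7))
    hi <- unname(quantile(boot, 1 - alpha / 2, type = 7))
  }
  out <- tibble::tibble(p = p, point = point, ci_low = lo, ci_high = hi,
                        ci_level = level, method = method, n = n)
  class(out) <- c("percentile_estimate", class(out))
  out
}
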