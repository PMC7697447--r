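test_that("fit_lognormal matches closed forms and passes summaries through", {
  # two-point closed form: values (1, e^2) -> gm = e, gsd = e^sqrt(2)
  fit <- fit_lognormal(c(1, exp(2)))
  expect_equal(fit$gm, exp(1))
  expect_equal(fit$gsd, exp(sqrt(2)))
  expect_equal(fit$n, 2)

  const <- fit_lognormal(rep(3.2, 5))
  expect_equal(const$gm, 3.2)
  expect_equal(const$gsd, 1)

  ms <- measurement_set(gm = 24.1, gsd = 1.44, n = 13, units = "ppm")
  pass <- fit_lognormal(ms)
  expect_equal(list(pass$gm, pass$gsd, pass$n), list(24.1, 1.44, 13))

  expect_error(fit_lognormal(c(1, -2, 3)), "> 0")
  expect_error(fit_lognormal(5), "at least 2")
})

test_that("fit_lognormal agrees with an independent maximum-likelihood fit", {
  skip_if_not_installed("fitdistrplus")
  set.seed(11)
  x <- rlnorm(40, log(10), log(2))
  fit <- fit_lognormal(x)
  ml <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(log(fit$gm), unname(ml$estimate["meanlog"]), tolerance = 1e-6)
  # MLE uses n denominator; rescale to the sample (n-1) estimator
  expect_equal(log(fit$gsd),
               unname(ml$estimate["sdlog"]) * sqrt(40 / 39), tolerance = 1e-6)
})

test_that("lognormal percentiles reproduce the published P75 and obey closed forms", {
  # printed GM 24.1 / GSD 1.44 give 30.8; the published 30.9 came from
  # unrounded inputs -> accept 0.5%
  expect_equal(lognormal_percentile(gm = 24.1, gsd = 1.44, p = 0.75),
               30.9, tolerance = 0.005)
  expect_equal(lognormal_percentile(gm = 10, gsd = 2, p = 0.5), 10)
  expect_equal(lognormal_percentile(gm = 7, gsd = 1, p = 0.99), 7)
  fit <- fit_lognormal(c(1, exp(2)))
  expect_equal(lognormal_percentile(fit, 0.75),
               exp(1) * exp(sqrt(2))^qnorm(0.75))
  expect_error(lognormal_percentile(gm = 1, gsd = 2, p = 1), "between 0 and 1")
})

test_that("lognormal_percentile is increasing in p, gm, and (above the median) gsd", {
  p <- seq(0.05, 0.95, by = 0.05)
  q <- lognormal_percentile(gm = 5, gsd = 1.8, p = p)
  expect_true(all(diff(q) > 0))
  gms <- seq(0.5, 50, length.out = 20)
  expect_true(all(diff(lognormal_percentile(gm = gms, gsd = 1.8, p = 0.75)) > 0))
  gsds <- seq(1, 4, length.out = 20)
  expect_true(all(diff(lognormal_percentile(gm = 5, gsd = gsds, p = 0.75)) > 0))
  expect_true(all(diff(lognormal_percentile(gm = 5, gsd = gsds, p = 0.25)) < 0))
})

test_that("empirical percentile uses linear interpolation between order statistics", {
  expect_equal(empirical_percentile(1:100, 0.75), 75.25)
  expect_equal(empirical_percentile(42, 0.3), 42)
  expect_equal(empirical_percentile(rep(7, 9), 0.9), 7)
  # brute-force check of the rank 1 + p(n-1) definition on a random set
  set.seed(3)
  x <- sort(rlnorm(17))
  h <- 1 + 0.75 * 16
  expect_equal(empirical_percentile(x, 0.75),
               x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)]))
  expect_error(empirical_percentile(numeric(0), 0.5), "non-empty")
})

test_that("empirical percentile converges to the lognormal percentile of the generator", {
  for (n in c(200, 2000, 20000)) {
    x <- generate_measurements(gm = 10, gsd = 2, n = n, seed = 5)$values
    rel_err <- abs(empirical_percentile(x, 0.75) /
                     lognormal_percentile(gm = 10, gsd = 2, p = 0.75) - 1)
    expect_lt(rel_err, 5 / sqrt(n))
  }
})

test_that("percentile CIs enforce the six-measurement minimum and bracket the point", {
  expect_error(percentile_ci(rlnorm(5, 0, 0.3)), "minimum of six")
  x <- generate_measurements(gm = 24.1, gsd = 1.44, n = 13, seed = 9)$values
  ci <- percentile_ci(x, p = 0.75, level = 0.95)
  expect_true(ci$ci_low <= ci$point && ci$point <= ci$ci_high)
  expect_gt(ci$point, 0)
  expect_equal(ci$n, 13)
  # degenerate spread: all values equal -> interval collapses onto the gm
  fit <- fit_lognormal(rep(4.4, 8))
  d <- percentile_ci(fit, p = 0.75)
  expect_equal(c(d$ci_low, d$point, d$ci_high), rep(4.4, 3))
})

test_that("bootstrap CIs require raw values and an explicit seed, and are reproducible", {
  x <- generate_measurements(gm = 10, gsd = 1.8, n = 20, seed = 21)$values
  expect_error(percentile_ci(x, method = "bootstrap"), "seed")
  expect_error(percentile_ci(fit_lognormal(x), method = "bootstrap"),
               "raw measurement values")
  b1 <- percentile_ci(x, method = "bootstrap", seed = 99)
  b2 <- percentile_ci(x, method = "bootstrap", seed = 99)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$point && b1$point <= b1$ci_high)
  expect_error(percentile_ci(x, method = "bootstrap", seed = 1, n_boot = 100),
               "2000")
})

test_that("fit + percentile recovers the generator's P75 (parameter recovery)", {
  # at n = 13 a single survey's gm has ~10% sampling error, so the recovery
  # bands (gm within 15%, gsd within 0.15, P75 within 20%) are asserted on
  # the median over 25 fixed-seed replicates, where sampling noise is small
  true_p75 <- lognormal_percentile(gm = 24.1, gsd = 1.44, p = 0.75)
  fits <- purrr::map(1:25, ~ fit_lognormal(generate_measurements(24.1, 1.44, 13, seed = .x)))
  expect_equal(median(purrr::map_dbl(fits, "gm")), 24.1, tolerance = 0.15)
  expect_lt(abs(median(purrr::map_dbl(fits, "gsd")) - 1.44), 0.15)
  expect_equal(median(purrr::map_dbl(fits, lognormal_percentile, p = 0.75)),
               true_p75, tolerance = 0.2)
  # one survey of n = 1000 pins the parameters down directly
  fit1k <- fit_lognormal(generate_measurements(24.1, 1.44, 1000, seed = 7))
  expect_equal(lognormal_percentile(fit1k, 0.75), true_p75, tolerance = 0.03)
})

test_that("parametric CI width shrinks with n", {
  widths <- vapply(c(8, 16, 32, 64, 128), function(n) {
    fit <- new_lognormal_fit(10, 2, n)
    ci <- percentile_ci(fit, p = 0.75)
    log(ci$ci_high / ci$ci_low)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
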