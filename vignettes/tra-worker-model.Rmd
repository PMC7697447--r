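---
title: "A table-driven Tier-1 worker inhalation model and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A table-driven Tier-1 worker inhalation model and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traworker)
```

## The model

Regulatory screening assessment of worker exposure to chemicals (Tier-1
assessment under REACH) needs an estimate of airborne concentration from a
handful of coarse inputs, because detailed workplace information is rarely
available across a supply chain. The ECETOC TRA worker inhalation model
answers this with a multiplicative band model. A worker activity is coded as
a PROC process category (1–28, e.g. PROC 10 = low-energy spreading, PROC 2 =
closed process with occasional controlled exposure); the substance's
tendency to become airborne (fugacity) is banded low/medium/high from vapour
pressure for liquids or from a dustiness class for solids; and the workplace
is either *industrial* (established hygiene systems) or *professional* (less
controlled, typically higher exposures). Each (PROC, setting, phase, band)
key selects a tabulated **base estimate** \(B\), representing default
operational conditions, which is then scaled down by five multiplicative
modifying factors:

\[
E \;=\; B \times f_{\mathrm{conc}} \times f_{\mathrm{dur}} \times
        f_{\mathrm{gv}} \times f_{\mathrm{lev}} \times f_{\mathrm{rpe}},
\qquad f_\bullet \in (0, 1],
\]

for the concentration of the substance in the product, the exposure
duration, general (room) ventilation, local exhaust ventilation (LEV) and
respiratory protective equipment (RPE). The output is a single value that
nominally represents the **75th percentile** of the underlying exposure
distribution — the semantics every comparison in this package is built
around. Units are ppm for volatile liquids and mg/m³ for solids; the two are
linked by the ideal-gas relation ppm = (mg/m³) × 24.45 / MW.

`tra_estimate()` implements exactly this and nothing else: every number it
returns decomposes exactly into the base estimate and the five factors it
reports, so an assessment is auditable line by line.

## The parameter table and its provenance

The engine is strictly table-driven (`tra_table`); the bundled default
(`tra_default_table()`) is a CSV with a mandatory provenance column and can
be swapped wholesale with `read_tra_table()`. Three kinds of entries:

* **Anchored rows.** Two published end-to-end results over-determine their
  rows: 35 ppm for PROC 10 / industrial / medium volatility with only a
  good-ventilation credit implies a 50 ppm base and \(f_{\mathrm{gv}} =
  0.7\); 0.84 ppm for PROC 2 / professional / high volatility under the
  1–5% band, 1–4 h band, good ventilation and LEV implies
  \(50 \times 0.2 \times 0.6 \times 0.7 \times 0.2\). These two base
  estimates are flagged `worked-example back-solve`.
* **Documented band factors.** The four concentration factors
  (0.1/0.2/0.6/1), four duration factors (0.1/0.2/0.6/1), indoor general
  ventilation (1/0.7/0.3 for basic/good/enhanced, either setting), the
  outdoor factor (0.7), and RPE classes (90% → 0.1, 95% → 0.05) are the
  standard TRA v3 banding.
* **Representative defaults.** All other base estimates (and the uniform
  LEV efficacies of 0.1 industrial / 0.2 professional) are representative
  values chosen to be monotone in fugacity and activity energy. Their
  provenance column says so explicitly: users doing real assessments should
  substitute the official ECETOC workbook tables, which are not reproduced
  here.

Some (PROC, setting) combinations deliberately have no row — PROC 7
(industrial spraying) has no professional variant, PROC 11 (non-industrial
spraying) no industrial one — and a lookup there is an explicit
"scenario not supported" error, never a silent default.

### Band boundaries and other numerical choices

* Volatility: low < 0.5 kPa ≤ medium ≤ 10 kPa < high, bounds inclusive in
  the medium band, matching the published "0.5–10 kPa" range notation.
  Concentration boundaries 1/5/25% and duration boundaries 15/60/240 min
  fall in the lower band. Factors are monotone across bands, so the rule
  only needs to be documented, not conservative.
* Molar volume 24.45 L/mol (25 °C, 101.325 kPa). This is the value that
  reproduces all three published conversion pairs (59.3 mg/m³ ↔ 24.1 ppm at
  MW 60.10; 7 ↔ 0.86 and 7.96 ↔ 0.97 at MW 200.05) within 1%; the 20 °C
  value (24.06) does not.
* Dustiness is a user-supplied class. No threshold on a measured dustiness
  index is defined here.
* RPE is a factor on the *estimate* only. Measurement processing never sees
  it (see curation below).

## Exposure statistics

Workplace concentrations are treated as lognormal throughout, summarized by
the geometric mean and geometric standard deviation. `fit_lognormal()` uses
the closed-form estimators GM = exp(mean(ln x)), GSD = exp(sd(ln x)) with
the sample (n−1) denominator — stated explicitly because the MLE uses n. The
p-th percentile is \( \mathrm{GM} \times \mathrm{GSD}^{z_p} \)
(`lognormal_percentile()`; \(z_{0.75} = 0.6745\)). Note one deliberate
tolerance: from the printed rounded summary GM 24.1 / GSD 1.44 the P75 is
30.8 ppm, while the published figure of 30.9 ppm came from unrounded inputs;
the package accepts both within 0.5%.

`percentile_ci()` attaches a confidence interval, defaulting to the exact
parametric construction for a normal quantile on the log scale (the
noncentral-t form used for tolerance limits, the EN 689 lineage of
occupational hygiene practice):

\[
\exp\!\Big(\bar y + t_{\alpha/2;\,n-1;\,z_p\sqrt n}\, s/\sqrt n\Big)
\;\le\; \mathrm{P}_p \;\le\;
\exp\!\Big(\bar y + t_{1-\alpha/2;\,n-1;\,z_p\sqrt n}\, s/\sqrt n\Big),
\]

with \(\bar y, s\) the mean and sd of log values. It is exact for lognormal
data and works from a GM/GSD/n summary — essential, since published studies
often report only summaries. A percentile bootstrap (≥ 2000 resamples,
mandatory explicit seed — no hidden RNG state) is available for raw values
when the lognormal assumption is in doubt. Both methods refuse fewer than
six measurements, mirroring the curation rule. `empirical_percentile()` is
the order-statistic alternative, using linear interpolation at rank
1 + p(n−1) (documented so results are reproducible to the digit). Non-detects
and censored values are out of scope; all inputs must be positive detected
values.

## Curation and control-credit adjustment

Validating a screening model against existing measurement studies requires
rules, applied identically to every dataset. `apply_inclusion_rules()`
encodes three: at least **six measurements** (enough to support a 75th
percentile with a meaningful confidence interval), an **assignable PROC**,
and **sufficient context** — operationalized strictly as: every band-level
engine input resolvable without guessing; any unknown field fails the
criterion, because ambiguities in activity, ventilation status or product
composition can flip a validation conclusion. Failures are coded
(`insufficient_n`, `no_proc_assignable`, `insufficient_context`) so the rule
set is extensible and every exclusion auditable. One record is one workplace
scenario dataset; per-measurement modelling of merged datasets is
deliberately not reproduced.

`adjust_controls()` prepares the *comparison* scenario without touching the
original: LEV credit is dropped when investigators reported the LEV as not
delivering its protective potential, and RPE credit is always dropped unless
measurements were explicitly taken inside the respirator — which standard
practice forbids (and which triggers a warning, since it would break the
face seal). Because all factors lie in (0, 1], removing credit can only
raise the comparison estimate; this monotonicity is a tested invariant.
Where a study reports both a sampling duration and a shorter actual exposure
duration, the exposure duration drives the band and both are stored.

## Comparison verdicts

`compare_records()` computes the control-adjusted estimate, the measured
percentile with its CI (converting units through the molecular weight when
needed), and the ratio estimate/measured. The verdict rule is asymmetric on
purpose: **conservative** when the estimate is at or above the measured
percentile point (the intended screening behaviour; a ratio of exactly 1
counts as conservative); **underestimate** only when the estimate falls
below the *lower confidence bound* of the measured percentile; and
**borderline** in between — a point estimate below the percentile but inside
its CI must not be read as demonstrated underestimation. The percentile the
tool output is compared against is a parameter (default 0.75) because the
literature contains both 75th- and 90th-percentile readings of the same
output; both are computable side by side, and for GSD > 1 the ratio at
p = 0.9 can only be smaller. `summarize_comparisons()` stratifies verdicts
by PROC × setting × fugacity band, because a partial validation can only
speak for the combinations actually studied.

## The synthetic-data generator

`generate_measurements()` draws i.i.d. lognormal values (the `random`
strategy) — the standard model of within-scenario exposure variability. The
`compliance_biased` strategy emulates compliance-oriented measurement
campaigns that target operations and workers expected to be highly exposed:
each draw is, with probability `bias_prob` (default 0.8), taken from the
distribution truncated below its `bias_quantile` quantile (default 0.5, the
median), via inverse-CDF sampling. The observed distribution then
stochastically dominates the true one, so empirical percentiles are inflated
— the hazard such datasets pose for model validation. The defaults were set
by a power calculation *before* any test was run: with this mixture the
biased P75 targets the true ~86th percentile, and at n = 100 per sample the
probability that a biased sample's empirical P75 exceeds a paired random
sample's is ≈ 0.98, so the ≥ 95%-of-pairs property holds with margin. No
formula for the bias was ever published; this is a minimal truncation model
with its two parameters exposed, not hard-coded.

What the generator does *not* emulate: between-worker and day-to-day
variance components, autocorrelated task-based time series, censoring at
detection limits, and reporting error. Tests passing on generated data
therefore demonstrate the statistical machinery and the engine's contracts,
not fidelity to any specific workplace.

`generate_fixture_database()` produces curated-database fixtures whose first
two records are always the two published worked examples. For the
operating-theatre record the 42 raw measurements were never published; the
fixture stores a **synthetic** GSD of 2.0 (a typical workplace spread) with
the GM back-solved to 0.2068 ppm so that the lognormal P75 equals the
published 0.33 ppm. Synthetic records embed their generating parameters in
`true_gm`/`true_gsd` columns so tests can assert against ground truth, and
defective records (small n, missing PROC) are injected at stated rates to
exercise the inclusion rules.

## Problem sizes and runtime

The test suite runs everything at desk scale: scenario grids of ~100
combinations for the engine's structural properties, n = 13 surveys
(25 fixed-seed replicates for parameter recovery) and one n = 1000 survey,
1000 Monte-Carlo replicates for the CI coverage check (exact method, so
coverage is nominal up to binomial noise of ±0.7%), and 500 paired
replicates at n = 100 for the sampling-bias property. The full suite
completes in well under a minute on one CPU.

## Worked example

```{r example}
scenarios <- dplyr::bind_rows(
  tibble::tibble(substance = "isopropanol", physical_state = "liquid",
                 vapour_pressure_kpa = 4.1, proc = 10, setting = "industrial",
                 conc_band = ">25%", dur_band = ">4 h", location = "indoor",
                 general_ventilation = "good", lev_present = FALSE),
  tibble::tibble(substance = "sevoflurane", physical_state = "liquid",
                 vapour_pressure_kpa = 26, proc = 2, setting = "professional",
                 conc_band = "1-5%", dur_band = "1-4 h", location = "indoor",
                 general_ventilation = "good", lev_present = TRUE))
tra_estimate(scenarios)[, c("substance", "base_estimate", "f_conc", "f_dur",
                            "f_gv", "f_lev", "estimate", "units")]

db  <- generate_fixture_database(2, seed = 1)
res <- compare_records(db)
res[, c("record_id", "tra_estimate", "measured_point", "ratio", "verdict")]
summarize_comparisons(res)
```

## Known limitations

* The bundled non-anchored base estimates are representative, not official;
  conclusions about any specific PROC other than the two anchored rows
  depend on the table supplied.
* Only inhalation is covered; dermal exposure, consumer and environmental
  modules are out of scope, as are CHESAR exchange formats.
* The parametric CI is exact only under lognormality; use the bootstrap for
  raw data with visible departures.
* No handling of non-detects, mixed-substance exposures, or time-weighted
  averaging across tasks.
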