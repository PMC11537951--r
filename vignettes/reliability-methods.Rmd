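---
title: "Measurement reliability in anthropometric standardisation exercises"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement reliability in anthropometric standardisation exercises}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temkit)
```

## The problem

Anthropometric survey data are only as good as the people holding the tape
and the scale. Before fieldwork, a *standardisation exercise* has every
trainee measure the same volunteers repeatedly: each volunteer is seen by
several raters (here 2–11, median 4), each rater measures twice, and the
replicates are summarised into reliability statistics per parameter
(weight, length/height, MUAC, waist and calf circumference), per rater
group (site leads vs fieldworkers) and, where the panel spans ages, per age
stratum. `temkit` implements that analysis end to end, plus a generator for
synthetic exercises with known error structure.

## Statistical model and estimators

The implicit model behind all the statistics is additive and homoscedastic
within a stratum:

$$x_{v,r,j} = \mu_v + b_r + \varepsilon_{v,r,j}, \qquad
\mu_v \sim N(\mu, \sigma_b^2),\;
b_r \sim N(0, \sigma_r^2),\;
\varepsilon \sim N(0, \sigma_e^2),$$

with $v$ a volunteer, $r$ a rater and $j$ a round.

**Pooled TEM.** With replicate groups $i$ of sizes $k_i$,
$\mathrm{TEM} = \sqrt{\sum_i \sum_j (x_{ij}-\bar x_i)^2 / \sum_i (k_i-1)}$
— the square root of the one-way within-group mean square. The classical
anthropometric formulas are special cases: duplicate pairs give
$\sqrt{\sum d^2/2N}$, balanced $k$ gives the multi-rater form. We use the
pooled form because inter-rater groups here are genuinely unbalanced; it
needs no balancing assumption and ties the TEM to the ANOVA decomposition
used for the ICC ($MS_W = \mathrm{TEM}^2$, an identity the tests assert
exactly).

**Replicate views.** Intra-rater statistics use both rounds of each
(volunteer, rater) pair, one group per pair ($k_i = 2$). Inter-rater
statistics use each rater's *first* measurement, one group per volunteer;
volunteers measured by fewer than two raters carry no between-rater
information and are excluded (and reported). Under the model the intra TEM
estimates $\sigma_e$ and the inter TEM estimates
$\sqrt{\sigma_e^2+\sigma_r^2}$, which is why a positive rater bias SD
produces the familiar inter > intra ordering.

**%TEM and R.** $\%\mathrm{TEM} = 100\,\mathrm{TEM}/\bar x$, where
$\bar x$ is the mean of exactly the observations entering that TEM (the
convention is not universal; using the analysed data keeps numerator and
denominator consistent). $R = 1 - \mathrm{TEM}^2/\mathrm{SD}^2$ with SD the
standard deviation of all observations in the stratum, the common survey
usage. Both identities hold exactly in every emitted report row. "Total
TEM" in $R$ is the TEM of the same column (inter or intra): combining the
two modes would make the two reported $R$ columns identical, which
stratified reports plainly are not. Negative $R$ (error exceeding spread)
is reported as computed, with a warning, never truncated — truncation hides
pathological strata.

**One-way ICC.** The design has no fixed rater panel per volunteer, so the
one-way random-effects, single-rater ICC is the right form:
$(MS_B - MS_W)/(MS_B + (k_0-1)MS_W)$ with Searle's
$k_0 = (M - \sum k_i^2/M)/(N-1)$. Rather than imputing a subjects × raters
matrix with missing cells, we operate on the grouped representation
directly: the one-way model never uses rater identity, so missingness *is*
just unbalanced group sizes — mathematically identical and exactly
testable. Negative ICCs (lower bound $-1/(k_0-1)$) are reported as
computed.

**TEM comparison.** $F = \mathrm{TEM}_a^2/\mathrm{TEM}_b^2$ on
$(n_a-1, n_b-1)$ degrees of freedom with a two-sided
$p = \min(1, 2\min(P(F\le f), P(F\ge f)))$, symmetric in group order. The
"$n-1$" convention follows reporting practice in this field, but the exact
chi-square df of a pooled TEM is $\sum_i (k_i - 1)$; `compare_tem()`
therefore accepts explicit df overrides, and the calibration test uses
single-group arms where the two conventions coincide, so uniformity of the
null p-values is checked where the reference distribution is exact.

**Bland–Altman.** Intra: $y = $ round 2 − round 1 (the sign convention is
arbitrary; a flag flips it, the limit width is invariant), $x$ = pair mean.
Inter: $y_{ij} = x_{ij} - \bar x_i$ against $\bar x_i$, the volunteer's
mean over included first-round measurements — a construction whose overall
bias is structurally zero (deviations from an own mean sum to zero), which
the tests use as a regression guard; the informative outputs are the spread
and limits. The reference mean can optionally include second rounds. Limits
of agreement are bias ± 2·SD — exactly 2, the convention of the exercise
this package supports, configurable to 1.96 — and the bias CI is t-based on
$n-1$ df, the conventional small-sample choice. Degenerate inputs (all
differences equal) give point limits and a warning, never `NaN`.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| Age-group breaks | [0,2), [2,12], (12,∞) years | the verbal bands "0 ≤ 2", "2–12", "> 12" overlap at 2 and are ambiguous at 12; this makes "> 12" literal and sends exact boundaries to the older group. Configurable. |
| LoA multiplier | 2 SD | exercise convention; 1.96 available |
| Intra difference sign | round 2 − round 1 | arbitrary; flag to flip |
| Instrument grid | 0.01 kg (weight), 0.1 cm (rest) | scale and tape resolution; off-grid values are validation warnings, not errors, since unit conversion can produce them legitimately |
| Duplicates | fatal (keep-first by flag) | silent averaging or keeping would bias TEM downward |
| Age split | weight, length/height, MUAC | waist and calf are measured in one age band, so a split is vacuous; config-driven, not hard-coded |

Threshold sets (`built_in_thresholds()`): %TEM < 2.0 for weight and
length/height; a stricter pair for experienced anthropometrists
(inter < 1.5, intra < 1.0) next to the beginner pair (2.0 / 1.5); ICC and
R > 0.90 as "excellent". Custom sets load from YAML/JSON.

## The synthetic generator

`generate_dataset()` draws from the model above, then applies instrument
rounding. The study-like preset emulates a two-tier national exercise: 15
volunteers (5 per age stratum) for a pool of 12 site-lead teams and 75
volunteers (27/26/22) for 46 fieldworker teams, raters-per-volunteer drawn
from a distribution on 2–11 with median 4, two rounds, waist/calf
restricted to the over-12 stratum. The anthropometric means and SDs (infant
weight ≈ 9 kg, adult height ≈ 165 cm, …) are plausible package constants,
documented here precisely because they are *not* estimates from any real
exercise. Two defaults encode qualitative field knowledge: under-2
length/height gets twice the error SD (infant length is genuinely harder),
and rater systematic bias defaults to zero SD — enable $\sigma_r > 0$ to
reproduce the inter > intra TEM ordering of real data.

What the generator deliberately does **not** model: digit preference and
heaping, transcription errors, heteroscedastic error within a stratum,
rater drift over time, and site effects. Passing parameter-recovery tests
therefore shows the estimators are correct under the assumed model, not
that real exercises satisfy the model.

## Numerical and degenerate-input choices

* Empty strata and single-rater volunteers give `NA` markers plus warnings,
  never errors: a partial exercise still yields a full report skeleton.
* All-identical data: TEM = 0 is legitimate; ICC and R are undefined
  (`NA`, warned) because there is no variance to apportion.
* Zero SD of Bland–Altman differences: point limits with a warning.
* Report CSVs carry full double precision (readable back bit-faithfully);
  the markdown rendering rounds to 3 decimals and prints `NA` as `NA`.
* Reports are deterministic: same input and configuration, byte-identical
  files.

## Validation strategy and problem sizes

The test suite checks every estimator two ways: frozen hand-computed
examples, and independent oracles (`stats::anova` mean squares, the
textbook balanced ICC(1,1) closed form, the classical pairs TEM,
hand-coded Searle $k_0$) on hundreds of random instances at relative error
≤ 1e-12. Parameter recovery uses 500 volunteers × 2 raters for the TEM
($\sigma_e = 0.3$, estimate within ±0.02·σ-equivalent bounds [0.28,
0.32]) and 1000 volunteers × 4 raters for the ICC (population value
25/25.25 ≈ 0.990, within ±0.01); the F-test null calibration uses 2000
simulated exercises, and limits-of-agreement coverage 10,000 pairs — sizes
chosen so Monte-Carlo error is well inside the asserted bounds while the
whole suite runs in about a minute.

## Known limitations

* Measurement *accuracy* (bias against a gold standard) is out of scope —
  reliability statistics cannot detect a consistently wrong technique
  shared by all raters.
* The one-way ICC is the only ICC form offered; two-way models
  (consistency/agreement with fixed raters) are not applicable to this
  rotating-rater design and are not implemented.
* The F comparison inherits the $n-1$ df reporting convention by default;
  users wanting exact calibration on multi-group TEMs should pass
  $\sum (k_i - 1)$ as df.
* %TEM denominators use the analysed observations of each column; exercises
  computed with other conventions (e.g. first-round means in intra columns)
  will differ in the third decimal.
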