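---
title: "The interval Kano (Candy) model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The interval Kano (Candy) model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(candykano)
```

## The problem

Kano-style questionnaires ask each respondent a *pair* of questions per
service item — how they would feel if the service were provided (forward)
and if it were absent (reverse) — on the five options "I don't like it",
"Can bear", "It doesn't matter", "Ought to be", "Be fond of". The goal is
to sort items into requirement categories: Must-be (M, absence hurts),
One-dimensional (O, works both ways), Attractive (A, presence delights),
Indifferent (I), plus the per-response outcomes Reverse (R) and
Questionable (Q).

Two well-known failure modes motivate the interval model. In
home-contexts where family members feel responsible for care, many
respondents answer neutrally everywhere, inflating I under the traditional
frequency method; others answer only at the extremes, inflating O. Both
push the data into a homogeneous blob in which genuinely critical services
are invisible. Converting absolute scores to *relative* shares, and
replacing the point threshold with an interval, extracts the volatility
information that the absolute methods mask.

## The model

With `q` respondents and `n` items, forward answers are coded `M_i = i`
and reverse answers `M_i = 6 - i` (so strong objection to *absence* scores
high dissatisfaction). Coded scores are summed per item
(`aggregate_scores()`) and normalized (`normalize_scores()`):

$$\beta^{+}_j = \frac{\alpha^{+}_j}{\sum_j \alpha^{+}_j}, \qquad
  \beta^{-}_j = \frac{\alpha^{-}_j}{\sum_j \alpha^{-}_j}.$$

Each direction sums to 1, so both share the grand mean
$\theta = 1/n$. The floating range
$\phi = \max\{\beta^{+},\beta^{-}\} - \min\{\beta^{+},\beta^{-}\}$
is taken over the *combined* `2n` values, and the classification interval
is $[\theta^{low}, \theta^{up}] = [\theta - v\phi,\ \theta + v\phi]$ with
floating ratio `v` (default 1/6). Items are then classified
(`classify_candy()`):

| position of $(\beta^{+}, \beta^{-})$        | label |
|---------------------------------------------|-------|
| both inside the interval                    | O     |
| both above $\theta^{up}$                    | C     |
| both below $\theta^{low}$                   | I     |
| satisfaction side in the higher region      | A     |
| dissatisfaction side in the higher region   | M     |

C — Critical — is the category the interval adds: items with
above-interval sensitivity in *both* directions. The model assumes a
structured instrument (all answers in 1..5), enough respondents that no
item's aggregate is zero, and that relative (not absolute) sensitivity is
the quantity of interest; shares are only comparable *within* one
normalized population.

Comparators implemented behind the same interfaces: the point-threshold
ratio quadrants (`classify_ratio()`, boundaries to the lower side), the
evaluation-table frequency method (`classify_pair()`,
`frequency_classify()`), and Better–Worse coefficients
(`bw_coefficients()`, `bw_classify()`).

## Tunable parameters

* `v` (floating ratio, dimensionless, default **1/6**): half-width of the
  interval in units of the share range φ. The default follows the
  convention established for interval thresholds in comparable studies;
  `v = 0` degenerates to the ratio model with C replacing its O region
  (a tested property). Larger `v` widens the O band at the expense of C/I.
* `cut` (BW quadrant cutoff, share of A+O+M+I, default **0.5**,
  boundary-inclusive): the conventional Better–Worse rule. No printed
  cutoff exists to calibrate against, so it is a parameter, not a claim.
* Filter rules (`filter_invalid()`): `completeness`, `straightline`,
  `q_dominance` (Questionable share > 0.5 by default). The source study
  reports only the 425 → 370 reduction, not its criteria; these three are
  standard survey hygiene, individually switchable, and the effective rate
  uses completed questionnaires as denominator.
* `pooled_thresholds` (stratified analysis, default **FALSE**): β shares
  are relative within a normalized population, so subgroup classification
  recomputes normalization *and* thresholds inside each subgroup; the
  pooled option exists for sensitivity analysis.
* Correlation CI method: Fisher z by default, percentile bootstrap as an
  option. Neither is calibrated to any printed interval.

## Numerical conventions

* All computation is at full double precision. Printed-value comparisons
  use `round_half_up()` (half away from zero, matching how the source
  tables are rounded): 4 decimals for β and importance means, 5 for
  thresholds.
* Boundary handling: the defining inequalities of the five regions are
  strict, which would leave interval boundaries unlabeled. Interval
  membership is therefore boundary-inclusive, making `(θ, θ)` an O point,
  and the conditions are evaluated in the order O, C, I, A, with M as the
  final else-branch. The A-before-M order follows the listing order of the
  category definitions; the else-branch assigns the measure-zero corner
  points (e.g. $\beta^{+} = \theta^{low}$ exactly with
  $\beta^{-} < \theta^{low}$) to M. Property tests check agreement with an
  independently coded region oracle off the boundaries.
* φ scope: the range is taken over the combined 2n shares, not per
  direction — the only reading that reproduces the printed interval
  `[0.02057, 0.02291]` from the packaged profile (φ = 0.0249 − 0.0179).
* Frequency-method ties break by M > O > A > I > R > Q, the conservative
  worst-case priority from the Kano literature; ranking ties in importance
  reports break by item code for deterministic output.
* Degenerate inputs: empty response sets, all-zero counts, zero score
  variance and singular correlation matrices raise informative errors
  rather than propagating NaN.

## The packaged fixtures and the D2 discrepancy

`get_fixture()` ships the 46-item catalog, the 5×5 evaluation table, the
46-row profile table (importance, β⁺, β⁻, and the printed label columns of
all four methods) and the stratified label matrix with difference flags.
Recomputing from the profile's 4-decimal shares reproduces the ratio
labels 46/46 and the Candy labels 45/46: item D2 (β⁺ = 0.0229) sits within
rounding distance of θ_up = 0.02291, and the printed A label implies the
authors classified from unrounded shares. The package documents rather
than hides this: regression tests accept exactly this one discrepancy, and
the Critical/Must-be/Indifferent counts (5/7/7) are unaffected. The
traditional-method and BW label columns are shipped as data only — they
cannot be re-derived without the unpublished raw questionnaires.

## What the synthetic generator emulates — and what it does not

`synthetic_design()` plants a requirement category per item (optionally
per subgroup) as a multinomial answer distribution, linearly interpolated
between uniform (strength 0) and a pure pattern (strength 1): C piles
forward mass on "Be fond of" and reverse mass on "I don't like it"; A is
forward-only; M is reverse-only; I concentrates on the neutral option; O
places *moderate* mass on both extremes (pure pattern
(0.1, 0.1, 0.1, 0.2, 0.5) forward and its mirror reversed, coded mean 3.9
per direction — between C's 5 and I's 3, so O items land inside the
interval while C clears it). Importance ratings default to a fixed
baseline distribution independent of the Kano answers; an optional
coupling coefficient draws them from category-linked distributions to
emulate the strong importance–sensitivity correlation seen in real data.

The generator emulates per-item multinomials, subgroup effects and seeded
determinism. It does **not** emulate respondent-level correlation across
items (each answer is independent given the item), acquiescence or fatigue
effects, or the real study's joint demographic distribution. A green
recovery test therefore establishes that the classifier identifies
separated archetypes at realistic sample sizes (≥ 90% planted-label
recovery at strength 0.9, q = 500, 20 replicates, seeded) — not that real
populations are this well separated. Likewise, the psychometric statistics
on synthetic data are near their independence baselines (α ≈ 0, KMO ≈ 0.5)
precisely because the generator lacks a common factor; the reliability
tests inject one explicitly.

## Known limitations

* The interval geometry depends on φ, hence on the two most extreme items;
  a single outlier item widens the O band for everyone. This is inherent
  to the range-based definition.
* With very small `q`, shares are noisy and the interval is driven by
  sampling extremes; `recovery_experiment()` quantifies this (recovery is
  monotone in `q` in the tested designs).
* Stratified comparisons flag label differences without a significance
  test, mirroring the source methodology; sizes of borderline subgroups
  should be judged with the chain-distance report, not over-read.
* The effective-rate convention (valid / completed) and the three validity
  rules are package choices where the source is silent; both are
  configurable.
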