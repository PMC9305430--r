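---
title: "Methods: FSA-NPS receipt scoring, avatar rules and trial simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FSA-NPS receipt scoring, avatar rules and trial simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsanps)
```

This vignette documents the models, rules and numerical conventions the
package implements, and the design decisions taken where the underlying
intervention design left them open.

## Product scoring

Products are scored per 100 g under the FSA-NPS point scheme. The band
table shipped in `inst/extdata/fsa_thresholds_2005.yaml` is the published
2005 UK FSA nutrient-profiling table; it is a versioned config so that
alternative tables (for instance beverage-specific bands) can be swapped in
without touching code. Fiber bands use the AOAC column, the variant adopted
by the Nutri-Score framework.

Conventions pinned here:

* **Band membership** is lower-exclusive, upper-inclusive: a value equal to
  a band's upper bound scores that band's points. A sugars value of exactly
  4.5 g therefore scores 0 points; 4.51 g scores 1.
* **Sodium is taken in mg** per 100 g. Catalogs listing salt can use
  `salt_to_sodium()` (393.4 mg sodium per g NaCl, the molar ratio).
* **The protein cap** — protein points uncounted when negative points reach
  11 unless fruit/vegetable points are at 5 — is enabled by default and
  switchable (`protein_cap = FALSE`), because component points are also
  reported separately as subcategory outcomes and a user may want the
  uncapped decomposition.
* Points are integers; nutrient inputs are real-valued; negative nutrient
  values and fruit/vegetable fractions outside [0, 100] are validation
  errors naming the offending field.

The interval lookup is checked in the test suite against an exhaustive
linear scan over the band table on dense nutrient grids, including every
finite boundary.

## Basket scoring and the dietary index

A basket's DI is the weighted mean of per-product total scores over its
items, computed separately for solid foods and beverages; all headline
outputs use solid foods only, with the beverage DI retained for
completeness. The intervention design this package reimplements did not
state numerically what "weight-averaged" means for the DI, so both
weightings are provided: **energy weighting is the default** (the DI is an
energy-intake-weighted construct in the calculation method it cites), with
purchased-mass weighting as an option. When all products share an energy
density the two coincide exactly, which the tests pin.

Receipt lines without a nutrient profile (non-food products) are skipped
and counted, never scored as zero. A basket whose solid items carry no
scoreable mass yields an absent score (`NA`), not 0. Period aggregates
(`period_di()`) pool items across baskets — an item-level weighted mean,
deliberately not a mean of basket means — because a 4-week period is a
single purchasing window, and small baskets should not carry the weight of
large ones.

Windows are counted in baskets where the rules say baskets (12 for the
avatar, 7 for the recommender) and in calendar time where they say so
(4-week baseline and trial periods).

## Avatar rules

The five features map behaviour to states 1–5 (5 best): fitness from the
7-day mean of daily steps; heart health from 50% sodium + 50%
saturated-fat points; mental well-being from 50% fruit/vegetable + 50%
fiber points; bone health from protein points; blood sugar from sugar
points — the nutritional drivers read off the equally-weighted mean of the
last 12 baskets' component means. The 50/50 weights are applied to
*points*, not raw nutrient amounts, following the units in which the rules
are stated.

The exact state cut-offs of the original app are not public, so the
defaults are declared, not inferred:

| scale | direction | cuts (lower-inclusive) |
|---|---|---|
| fitness (steps/day) | higher better | 2500, 5000, 7500, 10000 |
| negative points (0–10) | lower better | 2, 4, 6, 8 |
| positive points (0–5) | higher better | 1, 2, 3, 4 |

The fitness cuts are anchored on the 7500 steps/day activity target the
intervention promoted (state 3 begins there by construction of the equal
2500-step bins); point scales use equal bins. All cut points are
overrideable via a YAML config, and the tests pin the defaults. A feature
without data in its window is a distinct "no data" condition — it is never
conflated with the worst state, and its feedback message prompts the user
to connect the data source. Feedback templates interpolate the driver value
and keep an encouraging tone at every state, including the lowest.

## Recommender

Over the pooled items of the last (up to) 7 baskets, the contribution of
category $c$ to negative dimension $d$ is
$\sum_{i \in c} m_i p_{d,i} / \sum_i m_i$ with $m_i$ the purchased mass, so
contributions sum over categories to the basket-set weighted mean points of
each dimension; that conservation identity is asserted to 1e−9 in the
tests. "Weight-averaged" is implemented as mass weighting within dimensions
and an unweighted mean across the four dimensions (sugar, sodium, saturated
fat, energy density); both are config-exposed because the design does not
define them numerically. Energy density participates here even though the
avatar uses only six subcategories — the two uses of points are
deliberately distinct.

Ranking is deterministic: descending combined contribution, ties broken by
larger mass share, then smaller category id; zero-contribution categories
are never reported and at most four categories are returned (fewer rather
than padded). Alternatives are same-category products scoring strictly
below the mass-weighted mean score of the user's purchases in that
category, sorted ascending (ties by product id); purchased products are
excluded, so buying the category-best yields an empty list and the report
still carries a tip. Tip selection walks the ranked categories to the first
with mapped tips and picks the least-recently-used one, so weekly calls
rotate through the mapped tips before repeating.

Whether the original analysis normalized contributions within each basket
before averaging, or pooled items across baskets, is not stated; this
implementation pools.

## Synthetic cohort generator

The generator exists so the whole pipeline is testable without any real
loyalty-card data. Defaults are the emulated trial's conditions: 95
participants allocated 42/53, 12 weeks, 6 step-days and 4 food-weeks of
baseline, baseline medians of 4624 steps/day and 6.13 DI points, 15/13
loyalty-card and 1/2 accelerometer connection failures per group, and
per-period app-usage retention of 35/18/12 (intervention) and 43/24/18
(control), which reproduces the funnel from 95 randomized to 30 completers
exactly and deterministically given a seed.

* **Steps** are lognormal: participant random effect (log-SD 0.7, chosen so
  the cohort IQR of baseline means is of the same order as the baseline
  median, matching the reported dispersion shape), AR(1) weekly effects
  (SD 0.25, correlation 0.3) and daily noise (SD 0.4). Group effects are
  additive drifts in steps/day per 4-week period, applied to the
  intervention arm.
* **Baskets** arrive weekly (cadence configurable; shopping frequency was
  not reported, so one basket per week is an explicit assumption). Products
  are drawn with participant-level category preferences (Gamma weights)
  exponentially tilted so that the *expected energy-weighted solid-food DI*
  equals the configured target — baseline plus a participant offset
  (SD 2.5 DI points) plus the per-period DI drift. The tilt parameter is
  solved by root-finding against weights `preference x unit mass x energy
  density`, which makes the realized pooled DI an asymptotically unbiased
  ratio estimator of the target; the finite-basket bias is well inside the
  Monte-Carlo tolerance the recovery tests use.
* **Attrition** is missing-completely-at-random by default (the emulated
  trial's own sensitivity analysis concluded MCAR); an `age_linked` mode
  biases dropout toward older participants, mirroring the observed younger
  completers, and is exercised directionally in the tests.
* **Catalog**: 2000 products over 125 categories (a desk-scale stand-in
  for a 55,000-product retail database), built from six archetypes with
  category- and product-level lognormal variation so that within-category
  score spread exists and healthier alternatives are findable. Categories
  whose index is a multiple of six hold beverages. A handful of non-food
  products exercise receipt-line skipping.

What the generator does **not** emulate: seasonality and pandemic-period
effects, household sharing of loyalty cards, out-of-home consumption, food
waste, price structure, and real product names. Passing tests therefore
show the pipeline's internal correctness and statistical calibration under
a plausible generative model — not that the effect estimates would transfer
to real shopping data with those confounders.

One deliberate simplification: the printed per-period sample sizes of the
original trial differ *by data stream* in ways that are mutually
inconsistent at face value; the generator models stream availability as
card/accelerometer failures plus a single app-usage retention schedule,
reproducing the overall funnel exactly but not every stream-by-period n.

## Trial statistics

All tests are two-sided at alpha .05, complete-case, never imputing;
every result carries the n actually used.

* **Wilcoxon signed-rank**: zero differences are handled by the **Pratt**
  method (zeros ranked, then discarded), chosen over zero-dropping because
  it retains the information that a pair did not change; the choice is
  configurable in effect through the documented statistic and is pinned in
  tests. The exact distribution (`psignrank`) is used when there are no
  zeros, no tied absolute differences and n ≤ 25; otherwise a
  tie-corrected normal approximation without continuity correction. All
  differences zero gives p = 1. Fewer than 5 usable pairs flags the result
  underpowered while still returning p.
* **Mann-Whitney U**: exact (`pwilcox`) when tie-free and both groups are
  ≤ 25; otherwise tie-corrected normal approximation without continuity
  correction. The statistic is U of the first group.
* **Pearson chi-square**: `sum((O−E)^2/E)`, df = (r−1)(c−1), no continuity
  correction, warning when any expected count is below 5, error on a zero
  marginal.
* **Quantiles** for median/IQR summaries use linear interpolation (R
  type 7). The convention is pinned and documented; it is not claimed to
  match the default of any other statistics package.
* **Sample size**: per-group `ceil(2 sd² (z_{1−α/2}+z_{power})² / δ²)`,
  doubled, and inflated by `ceil(total/(1−dropout))`. At δ = 1566 and
  sd = 2620 this gives 44 per group, 88 total — the upper end of the design
  range the emulated trial reported. Its lower end (74) and its inflation
  of 88 to 100 under 20% dropout do not follow from this formula under any
  convention tried here (88/0.8 rounds to 110); the package reports its own
  conventions rather than reverse-engineering the published arithmetic.
* **Multiple testing**: none, matching the analysis being reproduced.

The exact small-sample paths are verified in the test suite against
exhaustive enumeration (all $2^n$ sign assignments; all
$\binom{n+m}{n}$ group assignments) for fixtures up to n = 10, and the
normal paths against `stats::wilcox.test(exact = FALSE, correct = FALSE)`.

## Statistical calibration of the simulator

Three loop-closing checks run in the acceptance portion of the test suite,
at problem sizes chosen to keep the suite fast while leaving Monte-Carlo
error well below the assertion tolerances:

* **Effect recovery**: 500 replicate intervention participants with an
  injected step drift of +500/period (recovered within ±100 steps/day,
  about 3 Monte-Carlo standard errors) and a DI drift of −0.5/period
  (recovered within ±0.1 points).
* **Type-I error**: 400 null two-arm cohorts (12 + 12, steps only);
  the T1 between-group Mann-Whitney rejection rate must lie within about
  two binomial standard errors of 5%.
* **Power closure**: 1000 simulated two-arm trials of 88 participants with
  an additive 1566 steps/day effect on lognormal participant means
  moment-matched to SD 2620 must reject at ≥ 80% — the design power of the
  sample-size formula above. The lognormal model is the package's own step
  model; rank-test power under it exceeds what a normal model would give,
  which is why the closure is stated under the model the package actually
  simulates.

## Known limitations

* The FSA-NPS bands are the 2005 solid-food table for all products;
  beverage-specific Nutri-Score bands are out of scope (beverages are
  scored but excluded from headline outputs anyway).
* Avatar state cut-offs are declared defaults, not the original app's
  (unpublished) scheme; comparisons of state distributions against the
  original intervention are therefore not meaningful.
* The sugars field scores whatever the catalog provides; whether fructose
  and lactose were excluded upstream is a property of the catalog, not of
  the engine.
* Letter-grade (A–E) labeling, per-portion scoring, OCR of receipts,
  allergy-aware substitution and price-aware recommendations are
  non-goals.
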