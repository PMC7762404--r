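---
title: "Scoring Mediterranean-diet adherence from weekly food diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring Mediterranean-diet adherence from weekly food diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medscore)
```

## The scoring model

`medscore` implements a serving-based Mediterranean-diet adherence index: a
weekly score on a 0–24 scale built from fourteen food groups, each judged
over one of three time windows.

**Meal basis** (fruit, vegetables, cereals, olive oil; up to 3 points each).
Only the three main meals — breakfast, lunch, dinner — can contribute. A
main meal earns a group's point when the group's summed servings in that
meal reach its per-meal minimum: one serving of fruit, two of vegetables,
one of cereals, one of olive oil. Extra servings or extra categories of the
same group within one meal earn nothing more, and snacks never contribute.

**Daily basis** (nuts, dairy, fermented beverages). Servings are tallied
over the whole day regardless of meal. Nuts give 2 points at one serving or
more. Dairy gives 1 point for one serving and 2 for two or more. Fermented
beverages (wine and beer only — spirits never count) give 1 point for one
or two glasses and 0 otherwise: this is a *range* rule, so abstinence earns
nothing and three or more glasses cancel the point.

**Weekly basis** (seven groups, 1 point each). Servings are summed over the
week. Legumes, eggs, fish and white meat score with two or more servings.
Red meat (≤ 1), sweets (≤ 2) and potatoes (≤ 3) are *caps*: eating less —
including nothing at all — keeps the point. An empty diary therefore scores
exactly 3, the three cap points.

The weekly total is

$$\text{total} \;=\; \frac{\sum_{\text{days}}(\text{meal points} + \text{daily points})}{n_{\text{days}}} \;+\; \text{weekly points},$$

with $n_{\text{days}} = 7$ for a complete week, giving the 0–24 range
(12 + 5 points per day at most, plus 7 weekly points). Totals map to a
traffic-light band: LOW (red) below 9, MEDIUM (orange) from 9 to below 16,
HIGH (green) from 16 up. The integer bands 0–8 / 9–15 / 16–24 have a unique
interval completion on real-valued totals, which is what `classify_adherence()`
uses; displayed totals are rounded to one decimal but classification always
uses the unrounded value.

```{r}
w <- generate_week(preset_profile("high"), seed = 1)
score_week(w)
```

### Interpretation choices behind the rules

The rule set leaves a few cases genuinely open, and the package fixes them
as follows (each alternative reachable through `md_rules()`):

* **"A meal contains a group."** The normative reading — the group's summed
  servings must reach the per-meal minimum from the serving table — is the
  default. The looser reading, any positive amount, is available as
  `meal_presence_rule = "presence"`.
* **Caps and abstinence.** Cap-style weekly rules use ≤, so zero consumption
  satisfies them. Range-style rules (fermented beverages) do not reward
  zero.
* **Eggs.** The default scores eggs at two or more weekly servings;
  `eggs_rule = "range"` restores a 2–4 band that penalizes heavy egg
  consumption.
* **Fractional servings** compare against thresholds on real values: 1.5
  servings of sweets is within the ≤ 2 cap; 0.5 servings of nuts does not
  reach the ≥ 1 minimum.
* **Partial weeks.** `preliminary_trend()` divides the meal and daily sums
  by the observed number of days, and judges weekly groups on raw observed
  servings — conservative for the beneficial groups, lenient for caps.
  `extrapolate_weekly = TRUE` scales the observed servings by $7/n$ first.

## The taxonomy

Diaries are written against a controlled vocabulary of 31 food and beverage
categories — the image-recognizable set — plus "olive oil", a manual-entry
item: oil is invisible in a meal photo but indispensable to the scoring, so
the data model requires `source = "manual"` for it. The map from categories
to the fourteen scoring groups is total and deterministic: all bread, pasta,
rice and breakfast-cereal categories feed the cereals group (their
wholegrain flags are stored but not scored — no rule in the classical index
consumes them); both potato categories, fries included, feed the weekly
potato cap; sweetened soft drinks count as sweets; wine and beer as
fermented beverages. Water, coffee, tea, milky coffee, spirits and breaded
food are recorded but unscored: spirits are not a fermented beverage, and
breaded food has no dominant component to assign.

Serving sizes (fruit 80 g, milk 200 mL, wine glass 100 mL, …) live in a
versioned CSV under `inst/extdata/`, not in code, so a different national
reference can be swapped in. Where the source tables give ranges we ship the
midpoint: yoghurt 135 g (120–150), nuts 25 g (20–30). Cheese uses the hard
30 g size; soft and cottage cheese sizes are alternative values a
replacement taxonomy file can supply.

## The synthetic diary generator

There is no deposited diary data, so `generate_week()` fabricates it: seven
consecutive days, three main meals plus up to two snacks, driven by a
`consumption_profile()` — per-meal inclusion probabilities for the four
meal-basis groups, mean daily serving counts for the three daily groups,
mean weekly counts for the seven weekly groups. Counts are truncated
Poisson draws (daily at 6, weekly at 12), matching the small-integer style
of serving annotations; `count_dist = "fixed"` makes draws deterministic,
which is how the saturating (score 24) and abstinent (score 3) reference
diaries arise. Snacks carry only daily-group items, keeping the meal-basis
probabilities directly interpretable. Identical profile and seed give
identical weeks, and the generator restores the caller's RNG state.

The presets were calibrated once, by computing the expected score
analytically from the Poisson tail probabilities and checking by
Monte-Carlo: `low` ≈ 3.3, `medium` ≈ 12.7, `high` ≈ 19.3 mean weekly total,
comfortably inside their bands. Typical preset days produce on the order of
3–7 consumption events, the daily bundle size the recognition study
protocol describes; extreme profiles necessarily exceed it.

What the generator does **not** emulate: within-person day-to-day
correlation (days are i.i.d.), seasonal or weekend structure, co-occurrence
patterns between categories in a meal, mixed dishes, or recognition noise.
Passing property suites on generated weeks therefore demonstrates the rule
engine's correctness over the reachable diary space, not the field accuracy
of any image recognizer.

## Evaluation metrics

For recognition experiments the package carries the standard evaluation
stack:

* `aggregate_annotations()` turns several annotators' label/serving sets
  for one image into a ground truth. Label sets cannot be averaged, so a
  label is kept on a **strict majority** (3 of 5 in the usual design) and
  its serving is the mean over the annotators who marked it. The
  aggregation is invariant to annotator order.
* `mean_average_precision()` ranks images per category by confidence and
  computes all-points interpolated average precision — the maximum
  precision at each achieved recall level — averaged over categories with
  at least one positive image. Categories never present are excluded from
  the mean by default (`include_absent = TRUE` counts them as AP 0).
  Confidence ties are broken by the fixed image order, making the metric
  deterministic; it is invariant to any rank-preserving rescaling of
  confidences.
* `mape_servings()` is the mean absolute relative serving error over
  **correctly predicted** items only — predicted at confidence ≥ the
  detection threshold (default 0.5, configurable; no canonical value
  exists) and present in the truth. False positives and missed labels are
  excluded; zero-serving truths are dropped with a warning since the
  relative error is undefined there. The metric is invariant to rescaling
  all servings by a common factor.

`build_cooccurrence()` estimates the label co-occurrence graph used by
graph-based recognizers from training annotations. The default adjacency is
the conditional frequency $a_{ij} = n(i \wedge j)/n(i)$ — asymmetric, unit
diagonal for observed categories, zero rows for unseen ones; a symmetric
joint-frequency form is available via `mode = "joint"`. No binarization or
re-weighting is applied.

`oracle_recognizer()` and `assemble_diary()` close the loop: the oracle
emits confidence 1 on true labels with the true servings, and the assembler
groups dated, meal-tagged predictions back into a scoreable diary. For any
generated week, rendering it to per-meal truths, passing through the oracle
and the assembler, and scoring reproduces the direct score exactly — the
round-trip invariant the test suite enforces. Meal tags are never guessed:
predictions without a tag are rejected.

## Numerical and degenerate-input choices

* Threshold comparisons use exact ≥/≤ on doubles; serving values arise
  from sums and division by tabulated sizes, so no tolerance is applied.
* `classify_adherence()` rejects totals outside [0, 24] rather than
  clamping.
* Empty meals are legal and score zero; an empty week is legal and scores
  3. A zero-day week cannot be constructed, so the empty-input error
  surfaces at construction.
* In average precision, a category with no positive instance has undefined
  AP and is excluded (or counted 0 on request); if no category has a
  positive, the metric errors rather than returning a silent 0.
* The flat CSV diary dialect cannot distinguish two snacks on one day; they
  merge on reading, which provably never changes any score (all rules sum
  within day or week). The nested JSON dialect is lossless and canonical.

## Problem sizes in the test suite

The suite checks bounds and caps over 1000 generated weeks, brute-force
rule-engine equivalence over 500 randomized diaries against an
independently coded literal evaluator, exhaustive average-precision
equivalence over every positive/negative pattern with up to 6 images (and
mixed cases up to 3 categories), and the pipeline round-trip over 100
weeks — sizes chosen to cover the discrete rule space many times over while
keeping the default run fast.

## Known limitations

* The classical index ignores wholegrain distinctions and over-consumption
  of beneficial groups beyond the three caps; both are carried in the data
  model but unscored.
* Vegetarian or other diet variants score poorly by construction (fish and
  white-meat points are unreachable), a known property of this index
  family.
* Ice cream has no category of its own; it is reachable only through
  `sweets`, although dairy-based serving tables sometimes list it.
* The recognizer itself is out of scope: the package evaluates and bridges
  recognition output but ships no trained model.
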