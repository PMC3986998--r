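---
title: "Methods: nutrient estimation, validation and scoring for the 16-item food intake questionnaire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient estimation, validation and scoring for the 16-FIQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiq16)
```

## The instrument and the problem

Short dietary screeners trade the precision of a 7-day food record for
something a nurse can hand a patient during a routine appointment.  The
16-item food intake questionnaire (16-FIQ) asks about meals per day and
five consumption frequencies, four fat-related choices (cooking fat,
cream, spread on bread, salad dressing), and six open-ended counts
(weekly dishes, daily milk, cheese, cold cuts, bread and cereal,
beverages), each count split by fat, fibre or sugar/alcohol class.
`fiq16` implements the full methodology around such an instrument: turning
answers into estimated daily nutrient intakes, validating those estimates
against food-record reference data, building integer-weighted scoring
models that predict nutrient intake from the answers, and generating
synthetic paired cohorts so every stage is testable without
participant-level data.

## Nutrient estimation

Each answer is converted to grams per day as frequency × portion weight ×
composition:

* frequency categories map to numeric midpoints via the codebook
  (`fiq_codebook()`), with weekly midpoints divided by 7 and monthly by
  30 — the simplest defensible constants, and replaceable because the
  codebook is configuration, not code;
* open counts multiply the per-unit weight of the item (a slice of rye
  ≈ 25 g, a decilitre of milk ≈ 100 g, a bottle of beer ≈ 330 g in the
  shipped table);
* three add-on rules handle fats that no count captures: spread = portion
  × bread slices when a spread is used, cooking fat = cooked dishes per
  week / 7 × portion attributed to the reported fat type, and one
  dressing portion per day when a dressing is used.

Energy is computed as 37 kJ/g × fat + 17 × carbohydrate + 17 × protein +
29 × alcohol, and each macronutrient's energy share (E%) as grams ×
factor / total kJ × 100.  Sucrose is treated as a subset of carbohydrate:
it gets the 17 kJ/g factor in its own E% numerator but does not add to
total energy a second time, otherwise the fat + protein + carbohydrate +
alcohol shares could not sum to 100 — an invariant the test suite asserts
to 1e-9 on every cohort it generates.  A participant whose answers imply
zero energy has no defined E%; such rows are flagged and skipped
downstream rather than silently scored as zero.

The shipped composition table (`read_composition()`) holds plausible
fixture values for typical Finnish foods.  It is documentation-level
stand-in data — the original analysis used a national food composition
database that is not redistributable — so absolute nutrient outputs are
fixture-dependent; everything anchored to published numbers goes through
the scoring path instead, which is independent of the composition table.
The `meal_average` entry for the meals-per-day item defaults to zero
densities to avoid double counting dishes already covered by the weekly
dish counts; users who want meals to contribute can supply a nonzero row.

## Validation statistics

`fiq_validate()` compares paired instruments the way screener validation
studies conventionally do:

* **Spearman rank correlation** per food group (questionnaire frequency
  vs record g/day) and per nutrient, with average ranks for ties and a
  two-sided p-value from the t approximation
  `t = r √((n−2)/(1−r²))` on n−2 degrees of freedom, α = 0.05, no
  multiple-testing correction.  A vector that is constant on either side
  has no defined rank correlation and is reported as `NA` rather than
  failing the run.
* **Tertile cross-classification**: the cohort is split into three
  rank-based groups whose sizes differ by at most one, larger groups at
  the lower end (77 participants → 26/26/25).  Ties are broken by stable
  input order, so a participant on an exact cut goes to the lower
  tertile — an arbitrary but deterministic convention, and determinism is
  what reproducibility needs.  Exact agreement is the diagonal share of
  the 3×3 table; opposite misclassification is the share landing in
  opposite extreme tertiles.
* **Weighted kappa** with disagreement weights `|i−j|/2` (linear,
  default) or `(i−j)²/4` (quadratic).  The source analysis cites a
  textbook without naming the scheme, so it is an explicit option and the
  report records which was used.

All three statistics are implemented directly (they are the point of the
package) and verified in the test suite against deliberately naive
brute-force oracles — hand-computed ranks, explicit double loops, term-by-
term kappa sums — to 1e-12 over a thousand random instances.

## Scoring models

A scoring model predicts one nutrient from a sum score
`SC = Σ mᵢ xᵢ`, where `xᵢ` are answers in their native units (dishes per
week, portions per day, slices per day, a 0/1 male indicator) and `mᵢ`
are small integers a clinician can sum by hand.  The published fat model
ships as `published_fat_model()`: prediction `36.66 + 0.45 × SC`, with
sausage dishes ×1, fruit portions ×(−12), cheese slices ×1, frankfurters
×3 and −5 points for men.  Its worked example — 2 sausage dishes/week, no
butter in cooking, 1 fruit portion/day, 6 cheese slices/day, no
frankfurters, male — gives `SC = 2 + 0 − 12 + 6 + 0 − 5 = −9` and an
estimated fat intake of `36.66 − 9 × 0.45 = 32.6 E%`, which the
acceptance script recomputes end-to-end.  One caveat is stored explicitly:
only the "no butter → 0 points" branch of the butter-in-cooking term is
printed in text; its "yes" coefficient sits in an image table and is kept
as `NA`, so scoring a butter-using participant with the published model
raises an informative error instead of guessing.  Sex is folded into the
sum score as an indicator item because that is the arithmetic the
published example performs; a separate-covariate treatment would change
the printed worked example and is therefore not the default.

### The multiplier search

`optimize_multipliers()` fits the integers by coordinate-wise hill
climbing on R²: visit items in fixed questionnaire order, try +1 before
−1, keep stepping while R² of the simple regression of the reference
intake on the resulting sum score improves, and repeat passes until a
full pass changes nothing.  Initialization is all-ones.  Three numerical
choices matter:

* **Improvement tolerance** (`tol`, default 1e-4).  An integer sum score
  identifies only the *direction* of the weight vector: doubling every
  multiplier and halving the slope changes nothing.  Consequently
  ever-larger integer configurations can approximate the optimal real
  direction ever more finely, each step buying a strictly positive but
  vanishing R² gain; judged at machine precision the loop inflates
  multipliers without bound (and, when a wrong-signed coordinate is
  temporarily held fixed, a single coordinate's conditional optimum can
  even sit at infinity).  Judging "improved" at the fourth decimal of
  R² — the precision at which fit statistics are reported — terminates
  the search at human-scale integers.  The same tolerance defines the
  ±1 local optimality that `is_local_optimum()` checks exhaustively.
* **Safety caps**: |multiplier| ≤ 100 and ≤ 500 passes.  Exceeding either
  raises a non-convergence error; a silently truncated search would look
  like a fitted model.
* **Strictness**: ties keep the current multiplier, which together with
  the fixed order and fixed direction preference makes the search fully
  deterministic.

Because only the direction is identified, parameter recovery is assessed
scale-free: the recovered vector is projected onto the true one
(least-squares scale `s = ⟨m,t⟩/⟨t,t⟩`) and the normalized weights `m/s`
must lie within ±1 of the truth.  Under the test harness — 500
observations, Poisson(3) item values, true weights (3, 1, −2), Gaussian
noise SD 3 — the suite requires recovery in at least 90 of 100 seeded
replicates.

### Log-scale models and bias correction

Right-skewed nutrients can be fitted on the natural-log scale
(`log_flag`).  Back-transforming `exp(intercept + slope × SC)`
underestimates the conditional mean, so predictions are multiplied by
`exp(MSE/2)`, where MSE is the regression error-variance estimate
`SSE/(n−2)`.  Which nutrients warrant the transform is a per-nutrient
choice (default off); `suggest_log_flag()` offers a residual-normality
heuristic (Shapiro–Wilk W on both scales) rather than a hard rule.
Residual diagnostics (`residual_diagnostics()`, `autoplot()`) are
reported on the back-transformed scale and deliberately do not clamp
negative predictions — a fitted line dipping below zero is what the plot
should show — whereas patient scoring clamps at zero with a warning,
since a negative intake estimate is not reportable.

## The synthetic cohort generator

`generate_cohort()` emulates the validation study's design: by default 77
participants (52 men, 25 women), each with a 7-day food record and a
questionnaire.  Per food group, a participant's latent true intake is
log-normal (dietary intakes are right-skewed, and the family gives the
log-transform option something honest to work on); the record value is
the mean of 7 daily log-normal draws around the latent; the questionnaire
answer is the latent perturbed by reporting noise and then discretized
into codebook categories and integer or half-unit counts.

The reporting noise is parameterized by a target Spearman correlation per
group, defaulting to the range a validation study of this type reports
(0.08–0.75 across 26 groups).  The target is mapped to a latent Pearson
correlation with the bivariate-normal identity `ρ_p = 2 sin(πρ_s/6)` and
divided by the analytic attenuation from 7-day averaging,
`σ_T/√(σ_T² + σ_d²/7)`.  Discretization then attenuates the realized
correlation slightly below target — coarse items (a few categories, or
counts that round to zero for most of the cohort) lose the most, which is
exactly what coarse questionnaire items do in real data.  The acceptance
suite requires the fruit group, targeted at ρ_s = 0.65, to realize within
±0.1 of its target on average over 200 seeded cohorts of 77; the
pre-discretization values are returned as `latent` so the noise-free
rank-identity limit can be verified directly.

What the generator does *not* emulate: zero-inflation (everyone consumes
a little of everything, where real cohorts have true never-consumers),
correlation between food groups (a health-conscious participant is
health-conscious across groups), record-side contributions of spreads and
cooking fats (record nutrients derive exactly from the 26 group gram
totals, which keeps the group-to-nutrient conservation invariant
checkable), or seasonal and day-of-week structure.  Passing tests
therefore demonstrate that the statistical machinery behaves correctly
under the stated generative model, not that the shipped fixture
questionnaire would achieve any particular validity in a real population.

## Problem sizes and reproducibility

The test and acceptance workloads are sized for interactive runs: oracle
equivalence on 1000 random tables, the search contract at n = 500 with 5
items, recovery over 100 replicates, calibration over 200 cohorts of 77.
Every stochastic step is seed-controlled; `generate_cohort()` and
`generate_known_model_data()` are deterministic given their spec, the
pipeline stages rerun byte-identically on fixed inputs, and scoring
models serialize to YAML with enough precision to reproduce predictions
bit-for-bit.

## Known limitations

The default codebook is a documented stand-in for the original
questionnaire's unpublished category lists; swap in an exact
transcription via `fiq_codebook(path)` without code changes.  The
composition fixture is not a national database, so absolute intake levels
are illustrative.  Only the fat scoring model is published in
transcribable form; models for other nutrients must be refitted
(`fit_scoring_model()`) against a user's own reference data, and at the
original study's size (n = 77) such models describe the fitting cohort —
cross-validation on independent data, which that sample size precludes,
would be needed before individual-level use.
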