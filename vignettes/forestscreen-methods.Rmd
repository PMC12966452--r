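---
title: "Methods: repeated random forests for predicting adult autism diagnosis"
author: "forestscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated random forests for predicting adult autism diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adults — especially late-diagnosed adults — are the hardest group to identify
with standard autism screening instruments, and effect sizes for single
behavioral measures comparing autistic and non-autistic groups have been
shrinking for two decades.  One response is to stop looking at measures one
at a time: administer a broad online battery of cognitive and perceptual
tasks (multisensory integration, facial and prosodic emotion recognition,
executive function), feed all of the resulting measures to a tree-ensemble
classifier, and ask (a) how well the battery predicts a formal diagnosis,
(b) which measures carry the prediction, and (c) how much the battery adds
to the best-established screening questionnaire for adults, the abbreviated
Autism-Spectrum Quotient (AQ-28).

`forestscreen` implements that workflow end to end as reusable, tested
code.  Because registry data of this kind cannot be redistributed, the
package pairs the analysis with a synthetic cohort generator that emulates
the relevant statistical structure, so every stage can be exercised,
benchmarked and stress-tested on data with known ground truth.

## The classification procedure

The unit of analysis is a participant-by-feature table: 54 task-derived
measures in 8 task blocks (`mcg`, `kdf`, `rme`, `psd`, `gng`, `agc`,
`cbd`, `tmt`), plus age and gender, giving 56 classifier inputs; the AQ-28
total can be appended as a 57th feature for the combined model.  Features
enter unscaled — decision trees are invariant to monotone rescaling, and the
scale-invariance of fitted trees and importances is asserted in the test
suite.

The pipeline stages are:

1. **Exclusion.** Participants missing any task block are dropped
   (`exclude_incomplete()`); missingness is block-structured because
   attrition happens per experiment, not per measure.
2. **Matching (optional).** A 100% age- and gender-matched subsample is
   built by randomized greedy bipartite matching (`match_age_gender()`):
   autistic participants are visited in random order and paired with a
   uniformly drawn unused non-autistic participant of the same gender and
   the same age in whole years.  The matching algorithm is a design choice
   — only "random selection" of a fully matched subsample is specified by
   the source design — and greedy random matching reproduces its defining
   property (identical age and gender marginals by construction) while
   remaining transparent and fast.  An age tolerance and a target pair
   count are exposed for sensitivity analyses.
3. **Split.** One fixed 80/20 train/test split (`split_train_test()`),
   with `|test| = round(n/5)`: 552 participants split 442/110 and 250
   split 200/50.  The default master seed is 1974.  The split is
   unstratified; balance is checked post hoc rather than enforced.
4. **Forest fitting.** CART trees with the Gini criterion, per-split
   feature subsampling (`max_features = "sqrt"`: 7 of 56), optional
   bootstrap resampling, a depth cap and a minimum leaf size
   (`fit_forest()`).  Prediction is by majority vote with ties going to
   the non-autistic class — the conservative direction for a screening
   instrument.  Reference hyperparameters are `rf_hyperparams()` (100
   trees, bootstrap, depth 4, min leaf 60) for the full sample and
   `matched_hyperparams()` (bootstrap off, depth 3) for the matched
   subsample; `tune_hyperparameters()` re-derives them by 3-fold
   cross-validated grid search on F1, reporting the train/validation gap
   per grid point as the overfitting diagnostic.
5. **Repetition.** The whole classification procedure is repeated R times
   (1000 by default) with the split held fixed; only forest-internal
   randomness varies, through per-repetition seeds derived from the master
   seed (`repeat_fit()`).  The best model is the repetition with the
   highest test F1 (`select_best()`); because this is a maximum over R
   noisy evaluations on a small test set, it is upward-biased, a property
   the test suite demonstrates on label-free data.
6. **Metrics.** Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`,
   specificity `TN/(TN+FP)` and F1 `2TP/(2TP+FP+FN)`, with "autistic" the
   positive class throughout.  F1 as printed is algebraically the harmonic
   mean of precision and sensitivity (not of sensitivity and specificity —
   a description sometimes attached to it); the implementation follows the
   formula.  Degenerate denominators return 0 with a warning so that
   thousand-repetition runs fail loudly without crashing.

### The forest engine

The forest is implemented natively (in compiled code) rather than wrapped
from an existing R ensemble package, because the analysis depends on exact
constraint semantics that the available implementations do not provide
together: a hard guarantee that every leaf holds at least
`min_samples_leaf` training rows (counting bootstrap multiplicity), a hard
depth cap, full-training-set trees when `bootstrap = FALSE`, and an
explicit per-tree node table for the structural analyses below.  Split
thresholds are midpoints between adjacent distinct values; `value <=
threshold` goes left; split search is exhaustive over admissible cut
points of the sampled candidate features.  Importance is the impurity
(Gini) decrease attributed to each feature, summed over all splits of all
trees and normalized to sum to one.  The engine is validated in the test
suite against brute-force R traversal and enumeration oracles on small
forests, and its chance-level behavior, determinism and constraint
invariants are property-tested.

## Feature-importance inference

To ask which features matter *beyond chance*, the same procedure is run
R times with the training labels freshly permuted at every repetition
("null forests", `null_forest_importances()`), with hyperparameters and
split unchanged, and performance still evaluated against the original
labels (these null models perform at chance, which the acceptance suite
checks).  Per feature, a two-tailed Welch t-test compares the R real
importances with the R null importances; p-values are Bonferroni-corrected
over the 56 features, and a feature is flagged only when it is also
directionally elevated (`mean_real > mean_null`).  Welch rather than
pooled variance because the null importances are systematically more
dispersed; `var_equal = TRUE` restores the pooled test.

**A statistical caveat that users should understand.**  The real-label run
reuses one fixed labeling, so any chance association between a feature and
that labeling shifts the feature's importance in *every* repetition, while
the repetition-to-repetition standard deviation reflects only forest
randomness.  The t-test treats repetitions as independent replicates and
will therefore flag such chance associations given enough repetitions: on
fully null synthetic data (no group signal anywhere) it flags roughly
15–20% of features at R = 100.  This is a property of the procedure, not
of the implementation.  For dataset-level calibration the package provides
`test_significance(method = "permutation")`, which compares the mean real
importance against the null run's importance distribution
(`p = (1 + #{null >= mean real}) / (R + 1)`); under the same fully null
conditions it flags essentially nothing.  The t-test remains the default
because it is the procedure this analysis is defined by; the permutation
method is recommended when the goal is a calibrated claim about a new
dataset.

`partial_dependence()` clamps one feature to each grid value across the
training rows and averages the forest's positive vote share, exposing the
direction and shape of each flagged feature's contribution.

## Feature co-occurrence

Beyond ranking single features, the package quantifies which features are
used *together*: for every tree in the ensemble(s), every unordered pair of
distinct features appearing among that tree's split variables counts once,
and the pair counts are normalized so all entries sum to one
(`cooccurrence()`).  Presence, not node multiplicity, is counted — that is
what makes the sum-to-one normalization well-defined — and the diagonal is
excluded; a multiplicity-weighted variant sits behind a flag.  By default
the matrix aggregates over all repetition forests rather than the single
best model, matching how the importance profile is averaged.  The matrix
is *not* a correlation matrix: a heavy pair means the decision logic uses
the two features jointly, which is exactly where features with no marginal
group difference can earn predictive value.  `cooccurrence_null_contrast()`
puts the real-label matrix next to the randomized-label one, whose pair
weights are approximately uniform.

## Questionnaire comparison

The AQ-28 total is a classifier by itself: score at or above a threshold
means "classified autistic".  `aq_sweep()` evaluates every integer
threshold in the instrument's range 28..112 (sensitivity is non-increasing
and specificity non-decreasing in the threshold, exactly);
`compare_sources()` tabulates best-model test metrics for the objective
battery alone, the AQ-28 alone (evaluated on the full group by default,
with a test-only flag), and the combined model, which appends the AQ total
as one extra feature and re-runs the identical repeated-forest procedure
with hyperparameters frozen so that any change is attributable to the
feature set.  (With 57 features the square-root rule still samples 7
features per split, so the frozen setting is genuinely unchanged.)  The
combined code path run with AQ withheld is bit-identical to the plain run,
which the test suite asserts.

## The synthetic cohort generator

`synthetic_config()` / `generate_cohort()` produce cohorts with the
marginal structure of the motivating registry sample: 286 autistic and 266
non-autistic adults; ages 44.2 (13.6) vs 32.2 (12.0) years; 71.0% vs 48.9%
women; AQ-28 totals 83.4 (10.7) vs 60.1 (11.6), simulated as a truncated
normal on the instrument's range and rounded to integers; ICAR (proportion
correct on an abbreviated intelligence test) 0.54 (0.20) vs 0.53 (0.17),
truncated to [0, 1].  Task features are multivariate normal with unit SD,
equicorrelated within task blocks (default 0.3) and independent across
blocks, with autistic-group mean shifts given per feature in Cohen's d
units.

Per-feature effect sizes for the 54 task measures are not published, so the
default profile is an explicit, documented guess encoding only qualitative
structure: moderate shifts (d 0.3–0.55) on response-time-like
emotion-recognition measures and several executive-function measures, zero
elsewhere including all multisensory measures.  A log-normal option per
feature provides response-time-like skew.  Block counts (10, 7, 7, 7, 6,
6, 6, 5) are likewise a fixed plausible allocation summing to 54.

**Joint signals** reproduce the phenomenon the analysis is really after:
features useful only in combination.  A joint-signal pair shifts autistic
records outward by `shift` SD on both features in the two same-sign
quadrants (both above, or both below, their group means).  The two mirrored
shifts cancel in expectation, so marginal means — and marginal Cohen's d —
are preserved exactly, while the pair's joint distribution separates the
groups (a forest trained on the default pair alone reaches over 60% test
accuracy at 1000 per group).  A one-sided quadrant shift was considered
and rejected: it moves the marginal mean by `shift/4`, which at the
default `shift = 1` is a detectable marginal effect and defeats the
purpose of the construct.  The default configuration plants one such pair
(`gng_03`, `cbd_04`) at 1 SD.

Missingness emulates per-experiment attrition: exactly
`round(missing_rate * n)` records lose one randomly chosen task block
entirely.  The count is exact rather than Bernoulli so that exclusion
bookkeeping is reproducible: a 959-record cohort at rate 407/959 always
leaves 552 complete records.

What the generator deliberately does not emulate: trial-level task data,
item-level AQ responses, non-Gaussian marginals beyond the log-normal
option, correlations between task blocks, co-occurring conditions, or any
dependence of task performance on age, gender, AQ or IQ.  Passing tests on
this generator therefore show that the *machinery* behaves as specified
and recovers planted structure — not that real cohorts carry such
structure.

## Numerical and design choices

- **Split sizes.** `|test| = round(n (1 - fraction))`, clamped so both
  sides are non-empty; this is the convention under which 552 yields
  442/110 exactly.
- **Tie-breaks.** Equal vote shares classify non-autistic; equal test F1
  selects the lowest repetition index; equal cross-validated F1 selects
  fewer trees, then shallower trees; equal sweep accuracy selects the
  lowest AQ threshold.
- **Seeds.** Every stage derives from one master seed (default 1974);
  repetition r uses `seed + r`, so any repetition's forest can be refit
  bit-identically (`refit_repetition()`) without storing 1000 forests.
- **Zero-division sentinel.** Metrics with empty denominators report 0
  with a warning rather than NaN.
- **Degenerate inputs.** Single-class training data, empty grids, unknown
  features, missing AQ values and infeasible matchings are errors naming
  the offending object; an all-incomplete cohort excludes to an empty
  table with a warning.
- **Problem sizes in the shipped checks.** The test and acceptance suites
  run the full procedure at reduced scale — typically 125 per group with
  100–300 repetitions, 20 null datasets for calibration checks, and 10
  simulated cohorts for the source comparison — sizes chosen to exercise
  every code path at stable statistical resolution.

## Known limitations

- The repeated-fit t-test's lack of dataset-level type-I control,
  discussed above, is the salient inferential limitation; the permutation
  method is the calibrated alternative.
- Best-model metrics are selection-biased upward by construction; the
  repetition mean and SD reported alongside are the honest summary of
  typical performance.
- Greedy matching does not maximize the number of matched pairs (that
  would be maximum bipartite matching); with realistic overlap it comes
  close, and the randomized order makes the selection unbiased among
  feasible pairs.
- The generator's Gaussian, block-equicorrelated world is far simpler than
  real task batteries; effect-size defaults are labeled guesses, and
  conclusions about real data require real data.
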