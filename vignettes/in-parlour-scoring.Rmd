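---
title: "Methods: evaluating in-parlour lameness scoring against locomotion scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating in-parlour lameness scoring against locomotion scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parlourscore)
library(dplyr)
```

## The problem

Locomotion scoring (LS) grades a walking cow's gait on the DairyNZ 0–3 scale
(0 sound, 1 imperfect, 2 lame, 3 severely lame). It is the reference method
for lameness detection but is labour-intensive in pasture-based herds, where
cows can realistically be observed only around milking. In-parlour scoring
(IPS) instead checks the hind limbs of a cow standing on the milking
platform for four binary indicators: shifting weight (SW), abnormal weight
distribution (AWD), swollen heel or hock joint (SHH) and overgrown hoof
(OH). Three further checklist indicators (claw injury, coronary band
swelling, arched back) are carried in the data model but excluded from
analysis: in parlour conditions they are observed too rarely or not at all,
so they contribute no usable signal. Because severely lame cows are rare
(well under 1% of observations), scores 2 and 3 are amalgamated and
"lame" means LS ≥ 2 throughout.

The package answers two questions. How well does a composite count of IPS
indicators screen for lame cows? And how well can a decision tree over the
four indicators recover the full three-class outcome {0, 1, ≥2}?

## Composite screening and its statistics

A cow is screening-positive at threshold *k* when at least *k* of the four
indicators are present (`classify_composite()`). An "exactly *k*" mode also
exists because a published results row labelled "three indicators" equals
the ≥3 rule only in populations where no cow shows all four; the report
states which mode it used. Against the lame reference, each rule is
summarised by sensitivity, specificity, PPV and NPV (`test_metrics()`).

Confidence intervals follow the conventions of the diagnostic-test
literature:

* **Se/Sp: Clopper–Pearson exact**, via beta quantiles. The choice is
  verifiable from degenerate published rows: with all 133 lame cows
  positive, the exact lower bound is `qbeta(0.025, 133, 1)` = 0.9726
  (printed as 97.3), and with all 3992 non-lame cows negative it is 0.9991
  (printed 99.9). A Wald or Wilson interval reproduces neither.
* **PPV/NPV: standard-logit** (Wald on the logit scale, back-transformed),
  with no interval reported for degenerate proportions — matching reports
  that print a bare "100.0". The tool used for the original analyses does
  not document its predictive-value method; our reconstructed point
  estimates match the published ones exactly, but interval tails for
  predictive values are not promised digit-for-digit.

Collinearity among indicators is screened with the Phi coefficient, which
for 2×2 tables equals the Pearson correlation of the two binary columns.
Metrics with zero denominators are reported as undefined (`NA`), never as 0
or 1.

### Reconstructing the ≥2-composite table

The joint 2×2 table of the ≥2 rule against lameness is not published, but
its margins are: 133 lame cows, 181 composite-positive cows, 4125 total, and
a sensitivity printed to one decimal (93.2%). `reconstruct_composite_table()`
finds the unique true-positive count consistent with the rounded
sensitivity (TP = 124) and errors if the margins do not identify one. The
resulting table reproduces all four published point estimates (Se 93.2,
Sp 98.6, PPV 68.5, NPV 99.8) and the published exact Se/Sp interval limits.

## The decision-tree classifier

The tree (`grow_tree()`, `prune_tree()`, `predict()`) is written from
scratch because its exact growth and pruning protocol is the object under
study, not an interchangeable step:

* **Impurity.** Gini, 1 − Σ p_c² over the three outcome classes; 0 at a
  pure node, at most 2/3.
* **Growth.** Greedy recursive splitting on the indicator with maximal
  impurity decrease (parent impurity minus observation-weighted child
  impurities). Growth stops only at purity, feature exhaustion on the path,
  or when no split decreases impurity; with four binary features the depth
  is at most four and no feature repeats on a path.
* **Pruning.** Bottom-up post-pruning with two criteria: an internal node
  must hold strictly more than 20 observations (`min_node_size = 21`), and
  its realized split decrease must be at least 0.005. The wording is taken
  literally: a 20-observation node is collapsed; a decrease of exactly 0.005
  is kept. 0.005 balances accuracy against complexity — a shallower tree
  underfits, a deeper one makes decisions on leaves too small to trust.
  Grow-to-maximum-then-prune is used rather than pre-pruned growth; the two
  differ when a weak split enables a strong descendant split.
* **Tie-breaks.** Equal split decreases resolve in the fixed listing order
  SW, AWD, SHH, OH; equal leaf class counts resolve toward the lower class.
  Both choices exist purely for determinism.
* **Selection.** Stratified 4-fold cross-validation
  (`stratified_kfold()`, `cross_validate_select()`): within each outcome
  class, observations are shuffled with a seeded RNG and dealt round-robin,
  so per-class fold counts differ by at most one and each fold holds ≈25%
  of the data. Each fold serves once as the held-out test set; the
  classifier with the highest held-out accuracy is selected (ties to the
  lowest fold index). Stratification is on the three-class outcome; the
  underlying 0–3 scale would stratify score 3 separately, but with so few
  score-3 cows the amalgamated stratification is the stabler choice.

Per-class performance is summarised one-vs-rest: TPR (class sensitivity),
FPR (one minus the one-vs-rest specificity) and precision, plus overall
accuracy. Accuracy is algebraically the class-count-weighted mean of the
TPRs, which the tests verify.

## The synthetic herd generator

`simulate_herd()` makes every stage runnable and testable without on-farm
records. Per scored cow-visit it draws LS from a 4-class probability vector,
then generates the indicators by thresholding a latent Gaussian 4-vector
with exchangeable correlation `latent_rho`: indicator *i* is present when
its latent coordinate falls below `qnorm(p[class, i])`. With `latent_rho =
0` the indicators are conditionally independent given class, and the
composite rate has the exact Poisson-binomial closed form implemented in
`composite_tail_probability()`, which the simulator is tested against.

The default preset reproduces the design of the two-farm reference study it
is calibrated to: nine monthly visits at the published per-visit scored-cow
counts (3006 and 1119 observations; 4125 pooled), per-farm LS distributions
(e.g. 70.9 / 26.0 / 2.9 / 0.2% on farm 1), and lame-class indicator
probabilities equal to the published per-indicator sensitivities (0.421,
0.474, 0.767, 0.429); scores 2 and 3 share probabilities since no finer
breakdown exists.

Two calibration decisions were genuinely open:

* **Score-1 indicator rates.** Setting both non-lame classes to one minus
  the published specificities is the minimal choice
  (`resolve_class1 = FALSE`), but it makes scores 0 and 1 indistinguishable
  from the indicators, which contradicts the published three-class
  classifier performance and the published indicator-count distribution
  (2807 zero-indicator observations against 2873 score-0 cows — sound cows
  almost never show an indicator, so the non-lame positives must sit almost
  entirely in score-1 cows). The default therefore gives score-0 cows low
  background rates (0.010, 0.010, 0.004, 0.040; OH highest, as a hoof
  conformation trait visible in sound cows) and solves the score-1 rates by
  moment-matching the published pooled per-indicator marginals (0.193,
  0.233, 0.092, 0.430).
* **`latent_rho` default 0.** The published inter-indicator Phi
  coefficients are negligible to weak, which conditional independence plus
  class mixing already reproduces. Note a structural fact: with the
  marginals fixed, *positive* exchangeable dependence lowers the composite
  ≥2 rate among lame cows (in the comonotone limit it falls to the
  second-largest sensitivity, 0.474), so the gap between the independence
  closed form (0.730) and the published composite sensitivity (0.932)
  cannot be closed by any `latent_rho` in [0, 1) — it would require
  negative within-class dependence (an indicator count concentrated near
  its mean). The knob is therefore a sensitivity-analysis device, not a fit
  parameter.

### What the generator does and does not emulate

It emulates class-conditional indicator prevalence, the published class
distributions and study scale, seeded determinism, systematic every-k-th
sampling, and a tunable common-cause dependence within class. It does not
emulate: negative within-class dependence (see above), so simulated
composite sensitivity sits near 0.73 rather than 0.93 and simulated
composite specificity is a few points below the published value; seasonal
lameness dynamics; repeated-measures correlation within cow across months
(observations pool as independent draws, as the original analysis pooled
them); or farm-management artefacts such as an excluded lame-cow group.
Passing tests on simulated herds therefore validate the *statistical
machinery* under known truth — interval coverage, estimator consistency,
protocol correctness — not the real-data effect sizes, which enter only
through the shipped published count tables.

## Numerical and interface choices

* Validation errors are classed conditions (`parlourscore_config_error`,
  `parlourscore_argument_error`, `parlourscore_validation_error`).
* Reports and comparisons round half-up to one decimal on the percent scale
  (`percent_1dp()`); all stored values keep full precision, and the
  report files round-trip losslessly.
* Record pairing is an inner join on `(farm, month, cow_id)`; the original
  24-hour LS-then-IPS timing collapses into the month label since exact
  dates are not published. Duplicate keys are an error naming the key; a
  cow scored in several months contributes independent records.
* All randomness flows through explicit seeds (`withr::with_seed`); no
  global RNG state leaks.
* Problem sizes in the test suite were chosen to make Monte-Carlo bounds
  sharp at three standard errors: 10^5 draws for calibration checks,
  2 × 10^5 for the composite closed-form check, 200 replicates of ≈4000
  observations for coverage of known truth, and 100 random instances for
  the brute-force split-search equivalence.

## Known limitations

* The published Phi matrix itself is not reproducible from published
  marginals (the OH–lameness Phi implied by the published OH
  sensitivity/specificity and 3.2% prevalence is ≈0.14 at any sample size,
  versus a published 0.57), so association structure is checked
  qualitatively: strong indicator–lameness association, SHH strongest, weak
  inter-indicator association.
* The exact published tree topology and fold composition depend on the
  unpublished joint data; the package checks the protocol (brute-force
  split equivalence, pruning predicates, stratification balance) and the
  qualitative structure (a cow without SHH is never classified lame),
  not the published figure node-for-node.
* Cross-validated accuracy on the synthetic preset is ≈0.85–0.88 — above
  the ≈0.70 majority-class floor but below the published 96.6%, because
  within-class independence spreads the score-1 indicator count so that
  roughly a quarter of score-1 cows show no indicator and are classified
  sound. This is a documented consequence of the generator's independence
  assumption, not of the tree implementation.
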