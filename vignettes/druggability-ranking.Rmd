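---
title: "Ranking gene druggability with a stochastic positive-unlabelled ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking gene druggability with a stochastic positive-unlabelled ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most of the human exome has never been the target of a drug programme,
yet nobody believes the ~600 genes behind approved drugs exhaust the
druggable genome.  Predicting which untried genes could support a
therapeutic programme is therefore a *positive-unlabelled* (PU)
learning problem: we have a trusted positive class (genes with approved
or clinical-stage drugs — "seed genes"), and everything else is
unlabelled, not negative.  Treating the unlabelled exome as a negative
class would teach a classifier that today's drug portfolio is the
ceiling of druggability; PU learning instead asks which unlabelled
genes *look like* known targets across hundreds of gene-level
annotations.

`drugrankr` implements this as a fitted estimator: `pu_ensemble()`
takes a gene-by-feature table and a positive label set and returns a
classed model object whose primary coefficient-like output is a
per-gene druggability score in [0, 1].

## The model

Let P be the positive set and U the unlabelled remainder of the gene
universe (the universe is simply the rows of the feature table).  One
stochastic iteration:

1. Shuffle U and cut it into chunks of about $\rho\,|P|$ genes
   (`rho`, default 1.5).  Each chunk, paired with the *full* positive
   set, forms a balanced partition.  Chunks are disjoint and cover U.
2. On each partition, run stratified k-fold cross-validation
   (`k`, default 10): the classifier is trained on k−1 folds and
   predicts probabilities for the held-out fold.  Every partition
   member therefore receives exactly one out-of-bag (OOB) prediction
   per partition.
3. Log every OOB probability.

This is repeated for `L` stochastic iterations (default 10) with fresh
shuffles, and the final score of a gene is the arithmetic mean of all
its logged OOB probabilities.  An unlabelled gene accrues exactly L
predictions (it sits in one chunk per iteration); a positive accrues
one per partition per iteration.  We average positives' many
predictions with a plain mean — down-weighting schemes are conceivable
but add a parameter without an obvious criterion, and the mean keeps
the score scale identical for both groups.

The balanced design matters for two reasons: class balance inside each
partition keeps probability estimates calibrated enough to average,
and cycling every unlabelled gene through some partition gives the
whole exome an honest OOB score rather than an in-sample one.

### Classifiers

Five base learners are registered (`registered_classifiers()`):
gradient boosting (default), random forest, extremely randomised
trees, an RBF support-vector classifier with calibrated probabilities,
and Gaussian naive Bayes.  All expose the same contract —
`fit(X, y, seed)` and `predict_probability(model, X)` — so the engine
is classifier-agnostic.

The gradient-boosting defaults are the outcome of the two-stage grid
search that `grid_search_gb()` replays: tree depth is scanned first
(1, 2, 3, 5) with the other settings at their inherited values
(500 estimators, learning rate 0.1, `sqrt` feature subsampling, 4
samples per leaf), then the estimator-count × learning-rate grid
(10…500 × 0.001…1) is scanned at the chosen depth.  Selection is by
mean CV AUC with ties broken toward fewer estimators, since the AUC
plateaus while extra trees only skew the probability distribution.
The resulting defaults are 200 estimators, learning rate 0.1, depth 5.

The boosting backend is xgboost, with the scikit-learn-style
hyperparameter names translated: `max_features = "sqrt"` becomes
per-node column subsampling at $\lfloor\sqrt p\rfloor/p$, and
`min_samples_leaf` maps to `min_child_weight`.  `min_samples_split`
has no xgboost counterpart; it is carried in the specification for
completeness but is inert, which on data of this shape changes the
fitted trees negligibly (the leaf constraint binds first).

### Determinism

All randomness flows from the single `seed` in `run_config()` through
named substreams per module (`substream_seed`), and each model fit
draws its own seed from the engine's stream.  Two runs with the same
config and inputs are bit-identical; the test suite asserts this on
the full score table.  A fold whose training half lacks one of the two
classes would be degenerate, but under the enforced preconditions
(|P| ≥ k and ρ|P| ≥ k) the stratified fold dealer always places both
classes in every training set, so the engine treats that situation as
an internal error rather than re-drawing.

## Pre-processing

`preprocess_features()` applies a fixed pipeline; the composed
operation is idempotent and never touches the gene set:

1. **Sparsity filter** (`missing_data_thres`, default 0.99): a feature
   survives as long as at least 1% of its cells are observed.  The
   permissive default is deliberate — sparse annotations (e.g. assay
   panels run on a few hundred genes) still carry signal for the genes
   they cover.
2. **Correlation pruning** (`correlation_threshold`, default 0.8):
   pairwise Pearson correlation on jointly observed cells; for every
   pair with |r| strictly above the threshold exactly one member is
   dropped.  Features are visited in column order and the earlier
   column wins — an arbitrary but deterministic tie-break.  Pairs with
   fewer than 3 jointly observed cells cannot be tested and are left
   alone.
3. **Imputation by feature class**: binary flags, subset-restricted
   signals and network features are filled with 0 (absence of
   evidence); globally defined continuous features are filled with
   their median, the safest extrapolation when a feature's reference
   set differs from the exome.
4. **Standardisation** to zero mean, unit (sample) variance.  Features
   that end up constant are zeroed rather than dropped so the report's
   column bookkeeping stays exact.

## Network feature engineering

Protein–protein interaction neighbourhoods are among the strongest
druggability signals: interaction partners of druggable genes tend to
be druggable.  `overlap_features()` turns a graph into three features
per evidence channel:

* `r1`: fraction of a gene's direct neighbours that are seed genes;
* `r2`: fraction of its *exactly* distance-2 neighbours that are
  seeds.  The shell excludes the gene and its direct neighbours —
  "two edges apart" names a distance, and mixing shells would
  double-count.  We stop at two hops because the neighbour count grows
  exponentially with distance while the specificity of the signal
  decays;
* their harmonic mean `2 r1 r2 / (r1 + r2)`, with the convention that
  it is 0 whenever either ratio is 0.  The harmonic mean rewards genes
  whose neighbourhoods are seed-rich at *both* radii and is
  annihilated by a zero, which is the conservative reading of a
  combined overlap score; the exact combination rule is a design
  choice of this package.

A gene's own seed membership never contributes to its ratios (only
neighbours are counted), so the feature cannot leak the label.  Genes
with an empty shell at a given distance — including isolated genes —
score 0 there.

Categorical annotation tables are featurised with percentile rules:
interaction types whose exome-wide frequency reaches the 50th
percentile of the type-frequency distribution become individual count
features (the rest are aggregated into `other_types`, plus a per-gene
`unique_interactions` count); pathways at or above the 90th percentile
of the size distribution become boolean flags (the rest a count); and
protein domain/family memberships become unfiltered flags.
Percentiles use linear interpolation and "at or above" is `>=`.

## Boruta feature selection

`boruta_select()` implements shadow-feature selection with a random
forest base learner.  Each iteration appends an independent per-column
permutation of every feature (the "shadows"), fits the forest on the
combined design, and scores a *hit* for every original feature whose
impurity importance strictly exceeds the best shadow.  After R
iterations, hit counts are referred to Binomial(R, ½): Confirmed above
the 95th-percentile bound, Rejected below the 5th, Tentative between.
All features stay in play for all R iterations and are classified once
at the end; classic Boruta also removes features mid-run, but the
terminal binomial rule is the quantitative criterion, and keeping the
design fixed makes the per-iteration importances comparable.  Feature
rankings use `z = (mean importance − mean shadow importance) /
sd(importance)` across iterations, with a `+Inf` sentinel for
zero-variance features.

## Validation statistics

* `auc_score()` — Mann–Whitney AUC with ties counted ½.
* `delong_test()` — paired DeLong comparison of two models' AUCs on
  the same cases, via the covariance of placement values; identical
  scores give p = 1 by convention.
* `fisher_2x2()` — sample odds ratio (a·d)/(b·c), Haldane +0.5 applied
  to all cells only when a zero cell is present, and the two-sided
  exact p by the minimum-likelihood convention (the dominant exact-test
  convention).  The sample OR reproduces the worked intracellular
  under-representation case (182, 999, 7544, 7057 → OR 0.17), which is
  why it is preferred over the conditional-MLE OR.
* `rank_interval_enrichment()` — the ranking is cut into B
  (default 20) near-equal intervals; sizes differ by at most one and
  the larger intervals sit at the *bottom*, so on a 19,846-gene exome
  the top-5% interval holds exactly 992 genes.  Each interval gets a
  2×2 Fisher test against the evidence set.  Ties in the ranking are
  resolved by input order so interval membership is deterministic.
* `evidence_cdf()` — cumulative fraction of evidence genes found at or
  above each interval.
* `stepwise_hypergeom()` — upper-tail hypergeometric p at cutoffs
  step, 2·step, …, N (default step 50, a resolution fine enough for
  exome-scale rankings without flooding the curve).  The
  enriched-region AUC is the Riemann sum of −log₁₀(p) over cutoffs
  with p < 0.05, with cutoff widths measured as fractions of N.  This
  summary (mask, log scale, normalisation) is a reconstruction of an
  "area under the enriched region" statistic and is documented here as
  this package's definition.

## The synthetic benchmark

`synth_spec()` and the `gen_*` generators produce all four input kinds
with planted structure, so the whole pipeline is testable offline:

* **Features**: informative columns are Normal(effect, 1) for
  positives vs Normal(0, 1) otherwise (`effect` is in SD units,
  default 3 — a strong, clearly recoverable signal); noise columns are
  Normal(0, 1) everywhere; a few binary flags have their odds tilted
  by half the effect on the logit scale.  Missingness is completely at
  random (default 10%) on the continuous columns.
* **Graph**: Erdős–Rényi at the requested mean degree (default 8,
  typical of curated interactomes), with the positive–positive edge
  probability multiplied by `boost` (default 5) to plant the
  assortative druggable neighbourhoods the overlap features are
  designed to detect.
* **Annotations**: Zipf-decaying type frequencies and pathway sizes,
  so the 50th/90th-percentile featurisation rules have non-trivial
  cut points.

What the generator does *not* emulate: structured (per-source)
missingness, correlated feature blocks, the heavy-tailed marginals of
real annotation resources, and literature bias that couples the
positive labels to annotation richness.  A pass on this benchmark
therefore demonstrates that the machinery recovers a planted signal
and stays calibrated under a null — not that any particular real AUC
would be reproduced.

The end-to-end runs in the tests and in `scripts/acceptance.R` use the
generator defaults (1000 genes, 100 positives) with the engine
defaults L = 10, k = 10; Boruta recovery uses n = 400, R = 40 and 25
seeds.  The full averaging depth matters for the null case: positives'
OOB scores share models, so their scores move together, and shallower
runs (smaller L, fewer positives) give the null AUC a standard
deviation well above what the [0.4, 0.6] band tolerates.  At the
default depth the signal run reaches OOB AUC ≥ 0.9 and the null run
stays inside the band.

## Known limitations

* PU scores are *relative* likelihoods under the chosen label set; a
  different seed list (approved-only vs clinical-stage) shifts the
  ranking, which is why the label set is a first-class input.
* Like all annotation-driven approaches, the model inherits study
  bias: under-annotated genes cannot rank highly regardless of their
  true tractability.
* The SVC's probability calibration is internal to the backing
  library; its probabilities are usable for averaging but less well
  calibrated than the tree ensembles'.
* `fisher_2x2()` p-values are exact but the DeLong test is asymptotic;
  for very small positive sets prefer the bootstrap.
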