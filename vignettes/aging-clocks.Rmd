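---
title: "Multi-view stacked aging clocks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view stacked aging clocks: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A microbiome aging clock is a regression model that predicts a host's
chronological age from molecular profiles of their gut community — here,
two *views* of the same stool metagenome: species-level relative
abundances and metabolic-pathway relative abundances. Two features of
such data drive every design decision in this package:

1. **The profiles are compositional.** Each sample's abundances are
   relative (they sum to one), so raw values live on a simplex and
   correlations between features are partly artefactual. We work in
   centered log-ratio (CLR) coordinates, `clr(x) = log(x) - mean(log(x))`,
   after multiplicative zero replacement.
2. **Cohorts are observational and geographically structured.** When
   sampling geography is correlated with age — some regions contribute
   mostly young donors, others mostly old — a model can "predict" age from
   whatever separates regions, and apparent age biomarkers may be
   geography markers. The screening module quantifies host-factor effects
   (PERMANOVA on Bray-Curtis dissimilarities) and removes the
   geography-age association before any clock is fitted.

## The clock: two-stage stacking with late multi-view fusion

Stage 1 fits a panel of heterogeneous base regressors (default: Lasso,
elastic net, Bayesian ridge, RBF-kernel SVR, random forest, depth-wise
gradient boosted trees, two xgboost variants, and leaf-wise histogram
gradient boosting) under one shared k-fold split of the training set
(k = 5). Each learner is fitted k times on k−1 folds; its held-out-fold
predictions form its *out-of-fold (OOF)* column — a prediction for every
training sample made by a model that never saw that sample. On new data,
each learner contributes the mean of its k fold models.

Stage 2 fits a *generalizer* on the OOF columns — ordinary linear
regression by default, learning one weight per (view, learner) pair. The
OOF construction is what makes this sound: had the generalizer been fit
on in-sample stage-1 predictions, it would simply learn to trust the most
overfit base learner.

Two fusion strategies combine the species and pathway views:

* **EM1 (early fusion)** concatenates the per-view design matrices and
  stacks the combined matrix. It requires every sample to have both
  views.
* **EM2 (late fusion, the default)** stacks each view independently and
  concatenates the OOF columns at the generalizer. Stage-1 models use
  every sample their view has; only the generalizer needs the overlap, so
  partially matched multi-omics collections are used in full.

```{r}
library(agestack)
ch <- simulate_cohort(n_samples = 400, n_species = 60, n_pathways = 40,
                      n_signal_features = 8, signal_effect = 0.04, seed = 1)
views <- list(species = clr_transform(multiplicative_replacement(ch$species_view)),
              pathway = clr_transform(multiplicative_replacement(ch$pathway_view)))
fit <- agestack(views, setNames(ch$metadata$age, ch$metadata$sample_id),
                strategy = "EM2", generalizer = "LR", seed = 2)
summary(fit)
```

## Confounder screening

Host-factor effects on each view are quantified by sequential (Type-I)
PERMANOVA of the Bray-Curtis dissimilarity matrix, one model per
covariate with the technical confounders (sequencing platform, DNA
extraction kit) in the same formula and 9999 free permutations;
p-values are Bonferroni-corrected across the covariates tested. The
formula places the covariate first by default; `covariate_first = FALSE`
assesses it on the residual after the confounders instead — both
orderings are legitimate sequential decompositions and we do not guess
between them.

Geography is then decoupled from age in two steps. Countries are
coarsened to UN M49 subregions (mapping shipped in
`inst/extdata/m49_subregions.tsv`), small bins are dropped
(`min_bin_size`, default 200 — scale it with the cohort), and an
iterative loop fits a random forest predicting age from the one-hot
subregion encoding, removing the subregion with the largest impurity
importance until the 10 x 5 cross-validated association R² falls below
`threshold` (default 0.01) or one bin remains. Importance is summed over
a subregion's indicator columns and normalized; normalization does not
affect the ranking. The retained sample set shrinks monotonically and
every epoch is recorded.

## Cross-validation, metrics and model comparison

All performance numbers are repeated k-fold cross-validation scores
(default 10 repeats x 5 folds), R² and MAE per held-out split, with R²
computed against the held-out fold's own mean. Fold assignments are a
deterministic function of `(seed, n_folds, n)`, so two models evaluated
under the same scheme see identical splits and per-split pairing is
valid. Models are compared with the two-sided Wilcoxon signed-rank test
on paired per-split scores (zero differences discarded; exact null
distribution up to 25 informative pairs, normal approximation above) with
Bonferroni correction across the family of comparisons. We read the
"paired rank-sum" comparison of the literature as the signed-rank test:
the rank-sum test has no pairing, and pairing is what the shared splits
provide.

When the full stacking procedure is itself evaluated, the outer CV wraps
everything — stage-1's internal 5-fold split lives inside each outer
training set. This nesting is the only leakage-free reading and is what
`compare_stacking()` implements; it also computes each stage-1 OOF matrix
once per outer split and shares it across all generalizers and fusion
strategies, so those comparisons are paired by construction.

## Feature selection

Seven selectors are compared: univariate linear F statistics (FR), a
binned mutual-information estimate (MI), and model-based importances
(RF impurity; split gain for GBRT/XGB/XGBRF/LGB). The default keep rule
retains features scoring above the mean score — the literature states no
threshold, so the rule is explicit and configurable (`top_k`
alternative). A method is *degraded*/*improved* for a learner when the
paired test on CV scores is significant after Bonferroni across
learners, *unchanged* otherwise; the adjudicator picks the method with
the fewest degraded learners, breaking ties by most improved learners,
then smallest selected dimension. When selection feeds a downstream CV,
it should be fitted on training folds only; the pipeline applies
selection before the final model fit and documents this choice.

## Biomarker interpretation

Permutation feature importance (PFI) shuffles one feature column at a
time across the evaluation samples (50 independent shuffles), re-runs
the frozen ensemble, and records the R² reduction. Evaluation uses
samples held out from generalizer training, so deltas are not
optimistic. Shuffling operates on the model's input representation
(post-CLR, post-selection); one-hot subregion columns are covariates,
not biomarkers, and are excluded by default. Per feature, a Wilcoxon
signed-rank test compares the 50 permuted R² values with the unshuffled
baseline; Bonferroni correction spans all tested features of both views
jointly (the stricter reading); features whose permutation *improves*
the model are never significant. Significant features are ranked by mean
R² reduction and annotated with tie-corrected Spearman rank correlations
against age (Bonferroni across the reported set).

**A known limitation.** With correlated inputs — and CLR coordinates are
always correlated, by the row-sum-zero constraint and by shared
covariate structure — the ensemble spreads weight over proxies of the
true markers, and permuting a proxy consistently degrades R² by a small
amount. A consistency test at 50 shuffles will call such features
significant however small the effect; the same happens through chance
alignment between fitted noise-dependence and a finite evaluation set.
Bonferroni controls test multiplicity, not this phenomenon. In practice
the planted/true markers separate by orders of magnitude in effect size
(our property tests assert a 10-fold margin), so ranking is reliable;
the significant *set* should be read together with the `mean_delta_r2`
column, not as an exhaustive marker list. Grouped or conditional
permutation schemes would address this and are out of scope.

## The synthetic cohort generator

`simulate_cohort()` emulates the features of pooled stool-metagenome
collections that matter to this pipeline, with ground truth recorded for
recovery tests:

* **Ages** follow a Beta marginal scaled to `age_range` (default 18-107
  years) whose second shape parameter is solved so the median matches
  `age_median` (default 52) — an adult cohort skewed toward mid-life.
* **Abundances** are log-normal per feature (`mu ~ N(0, 2)` baseline,
  per-entry log noise `noise_dispersion`, default 1), sparsified below
  `sparsity_floor` (default 1e-5) and closed to unit rows — sparse,
  heavy-tailed profiles that exercise the zero-replacement step.
* **Planted signal**: `n_signal_features` per view get a log-abundance
  trend in age — linear slope `signal_effect` per year (default 0.03), or
  a mid-life step for a `threshold_fraction` of them (step height
  equivalent to a 30-year linear drift, so both shapes have comparable
  magnitude). Trend directions are balanced (as many enriched as depleted
  markers) so the planted drift cancels in the per-sample geometric mean
  rather than bleeding into every CLR coordinate through closure. The two
  views' planted sets are disjoint by construction.
* **Geographic confounding**: each confounded subregion owns an
  age-quantile window (widths proportional to sampling weights, packed
  from the old end); with a calibrated mixing probability a sample inside
  a window takes that window's label, all other draws are
  age-independent. The mixing fraction is found by bisection on the
  realized ages so the between-subregion R² of age equals
  `confound_strength` essentially exactly; infeasible targets raise an
  error. Because unconfounded labels draw independently of age, removing
  the confounded bins provably decouples geography from age — the
  structure the screening loop is designed to find. A random 10% of
  features also receive subregion-specific offsets, giving geography a
  real microbiome signature independent of age.

What the generator does **not** emulate: taxon co-occurrence networks,
phylogenetic structure, per-cohort batch effects, or library-size
variation (a single pooled population is drawn). Tests passing on these
cohorts demonstrate that the machinery is correct and that the planted
structure is recoverable; they do not certify real-data accuracy.

## Numerical choices and degenerate inputs

* Zero replacement: `delta = "auto"` uses `1/D²` capped at half the
  smallest positive observed value; rows summing to ~100 are renormalized
  with a notice; an all-zero row is an error (the composition is
  undefined).
* Base-learner hyperparameters are the conventional defaults of each
  algorithm family (serialized with every learner spec): penalized linear
  models tune their penalty by internal 5-fold CV with deterministic
  folds; the Bayesian ridge maximizes the evidence by MacKay fixed-point
  updates on the SVD; SVR scales predictors and response; forests use
  100 trees; boosting 100 rounds (depth 3 / learning rate 0.1 for the
  depth-wise variant, 31 leaves / 0.1 for the leaf-wise histogram
  variant).
* Every stochastic step draws from a seed derived deterministically from
  the caller's seed and structural indices (repeat, fold, view), so
  reruns are byte-identical and stage-1 folds are shared across learners
  within a split.
* A decision-tree generalizer is allowed but warns: an unconstrained
  tree on nine highly correlated OOF columns overfits stage 2, and the
  comparison harness shows it underperforming the simple-average
  baseline.
* Held-out R² of a null model is slightly negative by construction
  (the fold's own mean is not the training mean); property tests treat
  "no predictability" as R² at or below zero rather than exactly zero.

## Problem sizes used by the test-suite experiments

The package's scientific checks run on cohorts sized for reliable
effects at desk scale, chosen once: decoupling on n = 900 with five
subregions and confound R² 0.35 (bin threshold 100, scaled to the
cohort); the stacking comparison on one n = 800 two-view cohort
(60 + 40 features, 8 planted markers per view, half threshold-shaped)
under a 2 x 5 outer CV; biomarker recovery over 20 seeded n = 220
cohorts with 50-shuffle PFI; PERMANOVA calibration against exhaustive
enumeration at n = 6 and a 500-replicate null at n = 24. The full-data
defaults (10 x 5 CV, 9999 permutations, bin threshold 200) remain the
package defaults.
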