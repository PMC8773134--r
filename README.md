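# agestack

Multi-view stacking-ensemble aging clocks for gut metagenomes.

`agestack` builds regression models that predict host chronological age
from compositional metagenomic profiles — species-level taxonomic
abundances and metabolic-pathway abundances of the same stool samples —
and identifies the features that drive the prediction. It is aimed at
microbiome researchers working with pooled, multi-cohort shotgun
metagenomics collections, where two obstacles dominate: the data are
compositional, and sampling geography is often confounded with age.

## What it implements

**Confounder-aware screening.** Host-factor effects on community
composition are quantified by sequential PERMANOVA of Bray-Curtis
dissimilarities (`adonis_permanova()`, 9999 permutations, Bonferroni
across covariates, technical confounders in the formula). Countries are
coarsened to UN M49 subregions (`regroup_to_subregion()`), and
`screen_subregions()` iteratively removes the subregion with the highest
random-forest importance for age until the cross-validated
geography-to-age association R² falls below 0.01 — so the final clock
cannot cheat off the sampling design.

**Compositional preprocessing.** Multiplicative zero replacement and the
centered log-ratio transform,

    clr(x)_i = log x_i − (1/D) Σ_j log x_j,

which maps each composition to unconstrained coordinates with zero row
sum (`multiplicative_replacement()`, `clr_transform()`), plus one-hot
subregion covariates and design assembly (`assemble_design()`).

**Two-stage stacking** (`agestack()`, the fitting function). Stage 1
fits nine heterogeneous base regressors (Lasso, EN, BR, SVM, RF, GBRT,
XGB, XGBRF, LGB) under a shared 5-fold split and collects out-of-fold
(OOF) predictions: the entry for sample *i* always comes from a model
whose training folds excluded *i*. Stage 2 learns generalizer weights
w over the OOF columns (linear regression by default):

    ŷ = Σ_{view v} Σ_{learner l} w_{v,l} · f_{v,l}(x_v)

Two multi-view fusions: **EM1** concatenates the view matrices before
stacking; **EM2** (default) stacks each view independently and fuses OOF
columns at the generalizer — so views covering different sample subsets
are used in full, and only the generalizer needs the overlap.

**Benchmarking and selection.** A repeated 10 x 5 cross-validation
harness with paired Wilcoxon signed-rank model comparison
(`repeated_cv()`, `paired_cv_test()`, `compare_stacking()`), and seven
feature-selection methods with an adjudication rule (fewest degraded
learners, then most improved, then smallest dimension;
`select_features()`, `adjudicate_selection()`).

**Interpretation.** Permutation feature importance on the frozen
ensemble (50 shuffles per feature, R² reduction), Wilcoxon significance
against the unshuffled baseline with joint Bonferroni correction, and
Spearman age-association annotation (`permutation_importance()`,
`test_biomarkers()`, `biomarker_report()`).

**Synthetic cohorts.** `simulate_cohort()` generates two-view
compositional cohorts with planted, ground-truth age trends and
calibrated geographic confounding, so the whole pipeline is testable
without external data.

## Worked example

```r
library(agestack)

ch <- simulate_cohort(n_samples = 300, n_species = 60, n_pathways = 40,
                      n_signal_features = 8, signal_effect = 0.04,
                      confound_strength = 0.2, seed = 7)
views <- list(species = clr_transform(multiplicative_replacement(ch$species_view)),
              pathway = clr_transform(multiplicative_replacement(ch$pathway_view)))
fit <- agestack(views, setNames(ch$metadata$age, ch$metadata$sample_id),
                strategy = "EM2", generalizer = "LR", seed = 11)
summary(fit)
```

```
Stacked aging clock — OOF diagnostics (n=300)
  ensemble: R2 = 0.900, MAE = 5.07 years
  base-learner OOF R2:
    species.Lasso   0.809
    species.EN      0.809
    pathway.EN      0.789
    ...
    species.XGB     0.641
```

The summary reports, per base learner and view, the R² of its
out-of-fold age predictions, and for the ensemble the R² and mean
absolute error (in years) of the generalizer applied to those OOF
columns: the stacked clock (R² = 0.90, MAE = 5.1 y on this synthetic
cohort) beats its best single constituent (Lasso on species, R² = 0.81),
which is the point of stacking. `coef(fit)` returns the generalizer
weights, `predict(fit, newdata)` applies the frozen fold models and
generalizer to new samples, and `biomarker_report(fit, ...)` ranks
features by how much shuffling them degrades the prediction.

A full pipeline — screening, preprocessing, selection, training,
interpretation — runs from one configuration object via
`run_pipeline(pipeline_config(...))`, writing per-stage TSV reports and
a JSON manifest.

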