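# sehybrid

Hybrid gut-microbiome modeling of selenium-absorption efficiency.

Selenium absorption varies widely between people, but it can only be
measured *after* a supplementation period (for example as the relative
change in hair selenium content). `sehybrid` is for microbiome
researchers and nutrition-modeling practitioners who want to predict,
from a **pre-intervention** genus-level gut-microbiome profile plus
routine host metadata, whether a subject will be a **low-efficiency
(LE)** or **high-efficiency (HE)** absorber, where HE is defined by an
absorption rate

```
rate = (Se_after − Se_before) / Se_before × 100  ≥  10%
```

The two practical obstacles the package addresses are sequencing
**batch effects** and **regional** differences in the microbiome,
which silently degrade a classifier shipped from one cohort to
another.

## The method

1. **Biomarker refinement.** A gradient-boosted tree ensemble
   (XGBoost) is trained on all genera; features are ranked by their
   *weight* importance (number of tree splits using the genus) and the
   top *k* = 10 genera are kept as biomarkers, guided by a
   cross-validated learning curve over top-*k* subsets.
2. **Host-variable fusion.** Gender, age (Young ≤ 35 / Middle 36–59 /
   Old ≥ 60), BMI (Low < 18.5 / Middle 18.5–23.9 / High ≥ 24),
   probiotics intake and health status are one-hot encoded
   (Male → `(1, 0)`, Female → `(0, 1)`, …) and concatenated with the
   biomarker abundances; each row is L2-normalized to unit norm.
3. **Hybrid cross-batch calibration.** To apply a model to a new
   sequencing batch, *n* randomly chosen new-batch samples
   (*n* = 5 … 30) are mixed into the training data and the model is
   retrained with unchanged hyperparameters; a held-out 30% of the new
   batch, redrawn over 5 randomizations, traces mean AUC against *n*.
4. **Cross-cohort shared-feature screening.** Biomarkers are ranked
   per batch, intersected (Venn-style), and the model is rebuilt on
   the region-stable shared genera (metadata still fused) before
   transfer to a new region.

Supporting statistics: Shannon / Simpson / Chao1 alpha diversity,
Bray–Curtis beta diversity (any precomputed dissimilarity matrix can
be substituted), one-factor PERMANOVA (Adonis) with per-variable
effect sizes (R²), Spearman correlation and Wilcoxon rank-sum tests,
with α = 0.01 as the significance threshold. A ground-truthed
synthetic multi-batch, multi-region cohort generator
(logistic-normal compositions with planted discriminative genera and
batch/region/host effects) makes the whole pipeline testable at desk
scale.

## Worked example

```r
library(sehybrid)

cohort   <- generate_cohort(synthetic_spec(seed = 42))   # 156/43/7 subjects, 2 regions
labelled <- derive_absorption_labels(cohort$metadata)    # LE/HE at the 10% threshold
table(labelled$efficiency[labelled$stage == "before"])
#>  LE  HE
#> 117  89

b1  <- labelled$batch == "Batch1" & labelled$stage == "before"
ab1 <- cohort$abundance[match(labelled$sample_id[b1], cohort$abundance$sample_id), ]

ranking <- rank_features(ab1, labelled$efficiency[b1], seed = 42)
head(ranking, 5)
#>   feature     importance  rank
#> 1 g__Genus002     0.106      1
#> 2 g__Genus007     0.0968     2
#> 3 g__Genus006     0.0829     3
#> 4 g__Genus005     0.0783     4
#> 5 g__Genus001     0.0737     5

recipe <- feature_recipe(select_biomarkers(ranking, k = 10))
model  <- tune_and_train(apply_recipe(recipe, ab1, labelled[b1, ]),
                         labelled$efficiency[b1], recipe = recipe, seed = 42)
model
#> <se_model> 22 features; CV AUC 0.975; depth 2, eta 0.1, 150 rounds, lambda 1
```

The fitted model carries its feature recipe, so it can be shipped to a
new batch directly or with hybrid calibration:

```r
b2  <- labelled$batch == "Batch2" & labelled$stage == "before"
ab2 <- cohort$abundance[match(labelled$sample_id[b2], cohort$abundance$sample_id), ]

transfer_evaluate(model, ab2, labelled[b2, ], labels = labelled$efficiency[b2])
#> <se_eval> AUC = 0.881 on 43 samples (LE=21, HE=22)

curve <- calibrate_hybrid(model, ab2, labelled[b2, ],
                          labels = labelled$efficiency[b2], seed = 42)
curve
#>   n_mixed  auc_mean     auc_sd n_repeats
#> 1       5 0.8979365 0.11851681         5
#> 2      10 0.9492063 0.07045188         5
#> ...
autoplot(curve)
```

The top-5 ranked genera above are planted signal genera of the
synthetic cohort (`cohort$truth$signal_genera`), the CV AUC of 0.975
is the in-batch 5-fold estimate of the fused biomarker + metadata
model, the transfer AUC of 0.881 is the uncalibrated cross-batch
performance, and the calibration curve shows the AUC recovered by
mixing 5–30 Batch-2 samples into training.

`run_pipeline(pipeline_config(spec = synthetic_spec(seed = 1), seed = 1))`
executes every stage (labels → diversity and effect-size scan →
ranking → learning curve → fusion → tuning → transfer → calibration →
shared-feature refinement) and writes per-stage TSV/JSON artifacts
plus a provenance manifest. A thin command-line front-end for
simulate / run / demo lives at `inst/cli/sehybrid.R`.

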