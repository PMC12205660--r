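# stimr

Early, noninvasive prediction of pathological complete response (pCR) to
neoadjuvant chemotherapy (NAC) in breast cancer from two-timepoint dynamic
contrast-enhanced MRI (pre-treatment **T0** and early-treatment **T1**),
for imaging scientists and methodologists working on longitudinal tumor
response models.

At the core is a **spatiotemporal interaction (STI) model**. Each tumor is
partitioned into K kinetic *habitats* by per-tumor k-means on voxelwise
kinetic features — wash-in slope, wash-out slope and peak relative
enhancement E(t) = (S(t) − S(t₀)) / S(t₀), with the enhancement forcing
modelled as E(t) = pe·(1 − e^(−a t))·e^(−b t). The whole tumor and every
habitat, at both timepoints, pass through one shared (Siamese) 3D
convolutional encoder; bidirectional multi-head cross-attention fuses each
region's T0/T1 tokens into per-habitat *change tokens*; multi-head spatial
self-attention mixes the region tokens; and a small classifier head emits
a pCR probability in [0, 1]. Ablation switches reproduce the full variant
grid (T0-only, T1-only, T0+T1 late fusion, ±subregions, ±spatial
attention, ±temporal attention). Around the model sit a clinical/GA-SVM
fusion stage (logistic screening of clinical factors, genetic-algorithm
selection of deep features, RBF-SVM), the complete evaluation stack
(Mann–Whitney AUC, average precision, exact Clopper–Pearson intervals,
DeLong tests, subgroup reports, clinical baseline-table tests with the
doubled-one-tail Fisher dialect) and survival analysis (Kaplan–Meier,
log-rank, univariate Cox) stratified by model score.

Because patient data cannot ship with the package, a reproducible
**longitudinal phantom cohort generator** with planted habitat structure,
treatment-response phenotypes, clinical covariates and linked survival
exercises every stage end-to-end; see `vignette source in vignettes/` for
the full methods account.

## Worked example

```r
library(stimr)

# a reproducible phantom cohort: 120 patients for training, 60 held out
train <- generate_cohort(phantom_config(n_patients = 120, seed = 1))
test  <- generate_cohort(phantom_config(n_patients = 60,  seed = 2))

fit <- sti_fit(train, sti_config(seed = 1), variant = "sti", cv = FALSE)
print(fit)
#> STI model (variant: sti)
#>   timepoints: T0+T1 | regions: whole + 3 habitats | spatial att: TRUE | temporal att: TRUE
#>   embed_dim 32, heads 4/4, threshold 0.999
#>   training AUC: 1.000 (n = 120, 24% pCR)

pred <- predict(fit, test)
head(pred, 3)
#>   patient_id        score label_pred threshold
#> 1      P0001 3.246624e-06      FALSE  0.998773
#> 2      P0002 7.098285e-07      FALSE  0.998773
#> 3      P0003 3.521856e-07      FALSE  0.998773

rep <- score_metrics(pred$score, cohort_labels(test),
                     threshold = pred$threshold[1])
print(rep)
#> Thresholded classification metrics (positive event = pCR)
#>   counts: TP=17 FP=1 TN=38 FN=4
#>   accuracy    0.917 (0.816-0.972)
#>   sensitivity 0.810 (0.581-0.946)
#>   specificity 0.974 (0.865-0.999)
#>   ppv         0.944 (0.727-0.999)
#>   npv         0.905 (0.774-0.973)
```

The score is the model's pCR probability; `label_pred` applies the
Youden-index threshold chosen on the training scores (here the training
set separates fully, so the threshold sits high); every proportion
carries an exact Clopper-Pearson 95% interval and the AUC a DeLong
interval. Survival stratification of the held-out cohort:

```r
sv <- survival_by_score(pred$score, cohort_survival(test))
sv$rfs$logrank$p   # 0.028 - high- vs low-score RFS curves separate
sv$rfs$cox
#> Cox univariate: HR 0.717 (0.454-1.134) per SD, Wald p = 0.1548, LR p = 0.1357
```

`run_experiment(experiment_config(...))` chains the whole pipeline —
cohort, habitats, the nine model variants, DeLong comparisons, subgroup
reports, clinical fusion, survival — into one seeded, reproducible
report, and `inst/cli/sti-response` wraps generation, the full
experiment and evaluation for shell use.

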