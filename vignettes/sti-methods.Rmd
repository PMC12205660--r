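---
title: "Spatiotemporal interaction modelling of longitudinal DCE-MRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal interaction modelling of longitudinal DCE-MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients with breast cancer receiving neoadjuvant chemotherapy (NAC) are
imaged with dynamic contrast-enhanced MRI before treatment (T0) and again
after one or two cycles (T1). Whether a patient will reach pathological
complete response (pCR) at surgery is only known months later; an accurate
early prediction from the two imaging studies lets non-responders switch
regimens and may spare responders aggressive surgery. `stimr` implements a
spatiotemporal interaction (STI) model for this task: tumors are
partitioned into kinetic habitats, each habitat (plus the whole tumor) is
encoded by a shared Siamese 3D convolutional encoder at both timepoints,
multi-head attention fuses the region tokens across time and space, and a
small classifier head produces a pCR probability. Around the model sit the
full evaluation stack (ROC/AUC, average precision, exact Clopper-Pearson
intervals, DeLong comparisons, subgroup reports, baseline association
tests) and survival stratification (Kaplan-Meier, log-rank, univariate
Cox).

Because patient data cannot ship with a package, every stage is exercised
end-to-end on a synthetic longitudinal phantom cohort with planted,
recoverable structure. The phantom is first-class, tested code; its role
is to make every claim of the pipeline falsifiable at desk scale.

## The phantom cohort

`phantom_config()` / `generate_cohort()` emulate the essential structure
of a two-timepoint NAC imaging cohort:

* **Geometry.** Each tumor is an ellipsoid with a smooth random boundary
  perturbation on a 32 x 32 x 24 grid at 1 mm spacing. Habitats are cells
  of a weighted Voronoi diagram of K = 3 interior seeds; habitat 1 is
  deliberately a *small hyper-enhancing hot spot* (weight 0.62 versus
  1.15), matching the habitat-imaging intuition that a compact
  hyper-perfused subregion carries disproportionate biological signal.
* **Kinetics.** Voxel intensity follows a difference-of-exponentials
  enhancement curve `E(t) = pe (1 - exp(-a t)) exp(-b t)` with per-habitat
  `(wash_in, wash_out, pe)` triples of (0.045/s, 0.0040/s, 2.9),
  (0.018, 0.0015, 1.5) and (0.007, 0.0004, 0.6), five phases at
  0-240 s, and additive Gaussian noise (SD 5% of baseline tissue signal).
  Patient-level log-normal jitter (SD 0.25 on wash rates, 0.12 on peak
  enhancement, plus per-habitat contrast jitter) models scanner and
  physiological variability; it is the reason a baseline study is needed
  to interpret the early-treatment study.
* **Inter-visit nuisance.** Every patient — responder or not — shows
  visit-to-visit changes: a global enhancement drift (log-SD 0.10), a
  tumor-outline wobble (re-delineation), re-drawn voxel texture, and a
  ±6% volume jitter. Whole-tumor level changes therefore do not identify
  responders by themselves.
* **Response.** Responders split into two phenotypes
  (`localized_fraction = 0.45`): a *redistribution* phenotype with little
  shrinkage in which the hot-spot habitat collapses toward the dimmest
  habitat's enhancement level (necrosis of the formerly hyper-perfused
  core) while wash rates stay in place, and a *diffuse* phenotype with
  strong shrinkage (45 ± 10% volume) plus graded attenuation
  (0.30/0.15/0.05 per habitat). The redistribution phenotype barely moves
  whole-tumor statistics — it is essentially only readable by comparing
  *matched habitats* across time, which is exactly the capability the STI
  architecture claims. Non-responders change only at nuisance level.
* **Clinical covariates and labels.** Molecular subtype is sampled with
  frequencies 0.47/0.42/0.11 (HR+/HER2-, HER2+, TNBC) and tilts the pCR
  odds (multipliers 1/18.5/4.7), calibrated by root-finding so the
  marginal prevalence equals the configured 0.30 — inside the 24-36%
  range real NAC cohorts span. ER/PR/HER2/Ki-67 are drawn consistently
  with the subtype. Survival times are exponential with log-hazard
  `survival_link` (-1 by default) times the latent response, under
  administrative censoring.

Effect sizes are free parameters of the phantom, not estimates of any real
cohort; they were fixed once at design time such that the planted signals
are recoverable at the package's reference sample sizes, and the defaults
ARE the study conditions for all shipped tests. What passing tests show is
that the implementation detects the structures it claims to detect, at the
stated sizes, under realistic nuisance; they say nothing about effect
sizes in real patients.

## Preprocessing

The peak-enhancement phase (maximum mean within-mask enhancement relative
to the first phase, earliest index on ties) is resampled to isotropic 1 mm
by trilinear interpolation (nearest-neighbour for masks), and each region
(whole tumor + K habitats) is cropped around its bounding box with a 4 mm
margin and resized to a 32^3 patch. All patches of one study are z-scored
with the *whole-tumor* mean/SD, so each habitat's enhancement level
relative to its own tumor is preserved — per-region normalization would
erase precisely the level differences the subregion tokens are meant to
carry. An empty habitat yields a zero patch with `mask_fraction = 0`
(warning), keeping the region count fixed at K + 1. No T0-T1 registration
is performed: the model compares embeddings, not voxels.

## Habitat segmentation

Per-voxel kinetic features (wash-in slope up to the peak, post-peak
wash-out slope, peak relative enhancement) are z-scored within the tumor
and clustered by per-tumor k-means (K = 3, 10 restarts, fixed seed).
Clusters are relabeled canonically by descending mean peak enhancement,
and T1 labels are matched to T0 by optimal assignment over the habitat
mean-profile distance matrix. Matching uses the full kinetic profile; the
wash rates anchor region identity even when enhancement levels
redistribute, which is what lets matched-habitat comparison see the
redistribution phenotype. Planted-partition recovery (adjusted Rand index
against the generator's truth) is the accuracy yardstick.

## The network

* **Tokens.** Each of the K + 1 region patches enters the shared encoder
  as three channels: normalized intensity, region mask, masked intensity.
  The masked-intensity channel makes each region's mean enhancement level
  directly readable from global-average-pooled features. The encoder is a
  three-stage 3x3x3 conv / ReLU / 2x-average-pool stack (8, 16, 32
  channels), global average pooling and a linear projection; identical
  parameters serve every region and timepoint (the Siamese contract,
  asserted in tests). Learned additive type embeddings encode region
  identity and timepoint.
* **Feature standardization.** Encoder GAP features are standardized with
  training-cohort statistics before the projection. Without this the
  between-patient variation is <1% of the constant feature offset and the
  head collapses; the statistics are stored on the model and reused at
  prediction time.
* **Fusion order.** By default (`fusion_order = "temporal_first"`) each
  region's T0/T1 tokens are fused first by bidirectional multi-head
  cross-attention (each timepoint queries over the normalized pair, so
  the softmax is content-dependent; residuals carry the raw tokens;
  outputs are concatenated and projected), producing per-region *change
  tokens*; multi-head spatial self-attention with mean pooling then mixes
  the region tokens. The alternative order (spatial pooling per timepoint,
  then temporal fusion) is available as `"spatial_first"`. Temporal-first
  was adopted because the method's central object is the habitat-wise
  change; with spatial-first pooling the per-habitat changes are averaged
  away before the temporal comparison, and on the phantom the full model
  then fails to beat plain two-timepoint fusion.
* **Normalization.** Pre-LN blocks (layer norm without learned affine on
  attention inputs and on the classifier input) keep softmax logits and
  ReLU preactivations in range; without them the attention variants
  collapse to constant output.
* **Head and ablations.** A two-layer MLP (hidden 32) with a
  zero-initialized final layer (an untrained model scores exactly 0.5)
  produces the logit. Ablation flags reproduce the full variant grid
  (`sti_variants()`): single-timepoint models, with/without subregions,
  with/without each attention. With temporal attention off there is no
  token-level temporal interaction left, so the model reverts to late
  fusion — per-timepoint spatial pooling followed by concatenation +
  linear (or subtraction, per `fusion_when_no_temporal_attention`). This
  is the simple-fusion baseline the interaction mechanism is contrasted
  against, and it is why removing temporal attention costs the most
  sensitivity on the redistribution responders.

## Training

Class-weighted binary cross-entropy, Adam (lr 0.01, weight decay 5e-4,
batch 32, 80 epochs), dropout 0.2 on the fused embedding, one seed
controlling initialization, fold assignment and data order. Default
`embed_dim` is 32 with 4 + 4 attention heads: at a few hundred training
cases a larger embedding (128) measurably overfits, so the small width is
the package default and larger widths remain configurable. Hyperparameter
lists in `training$grid` are scored by stratified k-fold cross-validated
AUC and the best combination is refit on the full cohort; the decision
threshold is the Youden index on training scores. By default the conv
encoder stays at its seeded random initialization and only projection,
attention and head train (a random-feature regime that keeps the
reference experiment on one CPU); `layerwise_unfreeze = TRUE` implements
plateau-triggered progressive unfreezing of conv stages (monitored AUC
improvement < 0.005 over 3 epochs), i.e. layer-wise fine-tuning, with the
feature cache refreshed whenever conv weights move. `grad_cam()` returns
channel-gradient-weighted, ReLU-rectified, upsampled and min-max
normalized activation maps per region and timepoint, plus per-region
attribution weights (mean absolute score gradient at each region's
features) for region-level localization checks.

## Evaluation statistics

AUC is the Mann-Whitney concordance (ties half); AP the step-wise
precision-recall area with grouped ties; both are checked against
exhaustive oracles in tests. Proportion intervals are exact
Clopper-Pearson via beta quantiles. AUC intervals and AUC comparisons use
the DeLong placement-value estimator. Published relative model
improvements follow the *ratio* convention, `100 (new/ref - 1)`, reported
to one decimal; error-rate reductions accept either raw fractions or
pre-rounded percentages, since mixed conventions appear in published
reports and give different last digits. The AP interval uses a stratified
bootstrap (no standard closed form exists). Baseline association tests
dispatch as in clinical baseline tables: Pearson chi-square with Yates
correction for 2x2 tables when expected counts allow, otherwise Fisher's
exact test with the two-sided p computed as double the smaller one-tailed
hypergeometric probability capped at 1; continuous covariates use
Student's t or Mann-Whitney after a Shapiro-Wilk pre-check at 0.05. The
univariate screening stage of the clinical model uses likelihood-ratio
p-values (better calibrated than Wald at moderate n); factors causing
perfect separation are flagged and retained through a ridge-penalized fit
rather than silently dropped.

## Clinical fusion and survival

The clinical model encodes receptor status, Ki-67, menopause, T stage,
subtype one-hots and standardized age/diameter, screens factors by
two-stage logistic regression, and classifies with an RBF-kernel SVM
(grid-searched cost/gamma by stratified CV). Deep features (the fused
pre-classifier embedding) are selected by a binary-chromosome genetic
algorithm — tournament selection of size 3, uniform crossover (0.8),
bit-flip mutation (0.02), elitism of 2, fitness = k-fold SVM AUC with the
clinical block always appended (so selection is clinically conditioned)
minus a per-feature penalty — and combined with the screened clinical
features in the same SVM wrapper. Survival stratification splits patients
at the median score (configurable fixed threshold), with Kaplan-Meier
curves (Greenwood variance), the log-rank test, and univariate Cox
(Efron ties; scores standardized so hazard ratios are per SD, since
published per-unit conventions vary).

## Reference experiment and problem sizes

`run_experiment()` chains the stages: cohort generation, stratified 8:2
split (or an independently generated shifted "external" cohort via
`external_phantom_config()`), shared encoding, the nine-variant grid,
overall/subgroup/DeLong evaluation, clinical fusion and survival. The
shipped property experiments use 300 training and 150 test patients,
32^3 patches and three seeds for the variant-ordering claim; 20 phantoms
for habitat recovery; 10 seeded GA runs on 2 informative + 20 noise
features; n = 1000 for Cox recovery; 2000-10000 replicates for the
calibration checks. These sizes were chosen as the smallest at which the
planted effects are comfortably detectable, so the whole suite runs on a
single CPU in well under an hour.

## Known limitations

* The phantom's kinetics are a stylized forcing, not a pharmacokinetic
  (Tofts-type) model; there is no breast anatomy, no multi-lesion
  disease, and Gaussian rather than Rician noise.
* The default training regime does not learn conv filters; it relies on
  random-feature encoding plus trained attention/head. Full fine-tuning
  exists (`layerwise_unfreeze`) but is not exercised at reference scale.
* Contrastive pretraining is represented only by a warm-start hook
  (initial parameters of `sti_untrained()` can be replaced), not by an
  external pretraining corpus.
* Statistical conventions replicate common clinical-paper dialects (e.g.
  the doubled-one-tail Fisher p); where a published procedure is
  underdetermined (AP confidence intervals), a documented substitute
  (stratified bootstrap) is used.
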