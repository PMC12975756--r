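# NeuroFusion

Multimodal fusion of structural MRI and clinical metadata for
three-class Parkinson's disease staging (normal control / prodromal /
diagnosed PD), implemented and verified at desk scale.

Real PD imaging cohorts are access-restricted, so this package pairs a
faithful implementation of the analysis architecture with a synthetic
cohort generator whose planted structure makes every mechanism
checkable on one CPU: volumes with two deep-brain-like signal regions
whose contrast degrades monotonically across classes, and clinical
tables with planted informative, near-duplicate redundant, and
pure-noise features plus missingness and outliers.

## What is implemented

* **Image branch** — an EfficientNet-B0 backbone (exact parameter
  accounting: 5,288,548 parameters at a 1000-class head, vs 11,689,512
  for ResNet-18 and 138,357,544 for VGG-16) with Mobile CBAM attention
  inserted after every MBConv expansion: sequential channel/spatial
  attention built from depthwise-separable convolutions,
  `M_c(F) = sigma(DWConv(AvgPool F) + DWConv(MaxPool F))` and
  `M_s(F) = sigma(DWConv_7x7[AvgPool_c F'; MaxPool_c F'])`, applied
  multiplicatively.
* **Text branch** — a transformer encoder for the serialized clinical
  record with LoRA adapters `W' = W0 + (alpha/r) A B` (r = 8,
  alpha = 16 on the query/value projections of all 12 layers:
  294,912 trainable parameters, a >= 96% reduction versus full
  fine-tuning), projected to a shared 256-d space by
  `F_t = W_proj E_t + b_proj`.
* **Fusion** — bidirectional multi-head cross-attention between image
  and text tokens with optional learnable head-count selection
  (candidates 2–6, fixed 4 by default) and a sigmoid gate
  `fused = g * u + (1 - g) * v`.
* **Feature selection** — three stages: ensemble importance ranking
  with weighted inverse-rank aggregation `V_f = sum_m w_m / r_{f,m}`
  (or top-50% majority voting), redundancy pruning by normalized mutual
  information `NMI = 2 MI / (H_i + H_j) > 0.8` (or raw MI > 0.85), and
  Shapley validation (exact coalition enumeration or permutation
  sampling) gating at mean |phi| >= 0.01. Both published
  parameterizations ship as profiles `"paper-4.2"` (default) and
  `"paper-3.5"`, with a full audit trail.
* **Training** — focal (gamma = 2) + triplet (margin 0.3, batch-hard) +
  cosine-consistency loss; AdamW with cosine annealing (T_max 50,
  eta_min 1e-6); label smoothing 0.1, dropout 0.5, stochastic depth
  0.2, mixup, geometric/intensity augmentation; subject-level 20%
  held-out split plus stratified 5-fold CV; early stopping on
  validation focal loss (patience 20).
* **Interpretability** — Grad-CAM++ saliency over the final
  convolutional stage, validated against the generator's planted
  signal masks.

All trainable components run on a small reverse-mode autodiff engine
(`R/autodiff.R`), finite-difference checked in the tests.

## Worked example

```r
library(NeuroFusion)

# a planted cohort: 5 informative, 5 redundant, 10 noise features
spec <- cohortSpec(nSubjects = 1000L, missingRate = 0, outlierRate = 0,
                   seed = 42L)
co  <- generateCohort(spec, volumes = FALSE)
M   <- scaleAndEncode(co$clinical, fitPreprocess(co$clinical))
audit <- selectFeatures(M, co$labels, profile = "paper-4.2", seed = 1L)
audit
#> SelectionAudit [paper-4.2 profile]
#>   stage 1: 20 ranked -> 10 survivors
#>   stage 2: 5 removals -> 5 survivors
#>   stage 3: selected MoCA, UPDRS, Age, Weight, HY_stage
selectedFeatures(audit)
#> [1] "MoCA"     "UPDRS"    "Age"      "Weight"   "HY_stage"
```

The pipeline recovers exactly the five planted informative features:
stage 1's ensemble vote drops the noise columns, stage 2's NMI gate
(threshold 0.8) removes the redundant near-duplicates while keeping
each source (the duplicate has lower mutual information with the
diagnosis), and stage 3's Shapley gate confirms every survivor at
mean |phi| >= 0.01.

Exact backbone accounting:

```r
totalParamsM(buildBackbone(backboneSpec("efficientnet-b0"))$report)
#> [1] 5.3
dwconvParamRatio(64, 3)
#> [1] 7.890411
```

Training the desk-scale multimodal model end to end (about five
minutes on one CPU):

```r
spec <- cohortSpec(nSubjects = 300L, gridShape = c(32L, 32L, 32L),
                   seed = 42L)
co    <- generateCohort(spec)
model <- buildMultimodalModel(seed = 1L)
subs  <- prepareSubjects(co, imputeTable(co$clinical), model)
plan  <- makeSplit(co$subjectIds, co$labels, seed = 7L)
fit   <- trainModel(model, subs, plan,
                    trainConfig(epochs = 30L, seed = 11L, lr = 2e-3))
held  <- which(scanAssignment(plan,
          vapply(subs, `[[`, character(1), "subjectId")) == "heldout")
evaluateModel(fit$model, subs[held])$accuracy
#> [1] 0.9508197
```

Held-out accuracy of 95.1% against a 41.0% majority-class rate — a
capability floor on planted synthetic signal, not a clinical
performance claim. `gradCamPP()` saliency maps on the same fit rank
the planted signal regions above background for every correctly
classified held-out PD subject.

## Command line

A thin CLI over the exported functions lives at
`inst/cli/neurofusion.R`:

```sh
Rscript inst/cli/neurofusion.R generate --out cohort/ --n 50 --grid 32 --seed 7
Rscript inst/cli/neurofusion.R select-features --in cohort/clinical.csv --label label
Rscript inst/cli/neurofusion.R params --arch efficientnet-b0 --cbam
```

## Documentation

The methods vignette (`vignettes/multimodal-staging.Rmd`) describes the
models, the synthetic-cohort assumptions, the numerical choices, and
the design decisions in detail, including what passing tests do and do
not show about real data.
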