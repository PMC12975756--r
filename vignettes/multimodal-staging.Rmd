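---
title: "Multimodal staging of Parkinson's disease: models, assumptions, and design choices"
author: "NeuroFusion maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal staging of Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Three-class staging of Parkinson's disease — normal control (NC),
prodromal, diagnosed PD — from two complementary data streams: a
structural MRI volume per subject and a table of clinical metadata
(motor and cognitive scales such as UPDRS and MoCA, demographics,
disease staging, genetic flags). NeuroFusion implements the full
analysis architecture at desk scale: an attention-augmented
convolutional image branch, a LoRA-adapted transformer encoder for the
serialized clinical record, gated cross-attention fusion, a three-stage
clinical feature-selection pipeline, a composite training objective with
leakage-safe subject-level splitting, and Grad-CAM++ saliency.

Because the cohorts this family of models is trained on are
access-restricted, every mechanism here is validated against a
synthetic cohort generator whose planted structure makes correct
behaviour checkable: the generator, not any external dataset, defines
the package's study conditions.

# The synthetic cohort

`cohortSpec()` / `generateCohort()` emulate:

* **Volumes.** A background Gaussian field (sd 0.2) with two compact
  ellipsoidal signal regions at deep-brain-like fractional coordinates
  ("nigra-like" and "putamen-like"). The mean intensity offset inside
  the regions is 0 for NC, 0.5 for prodromal, and 1.0 for PD — a
  monotone contrast gradient mirroring progressive degeneration. The
  default grid is 64^3 voxels (configurable; the bundled experiments use
  32^3) so that forward passes and training epochs run on one CPU.
* **Clinical features.** Five informative features named after the
  deployed clinical set (UPDRS, Age, MoCA, HY_stage, Weight), each with
  a one-standard-deviation mean shift per class step. The uniform
  effect size is deliberate: the cohort is a validation instrument, and
  "planted informative" has to mean unambiguously recoverable — with
  mixed weak/strong effects the weakest planted features become
  statistically indistinguishable from noise at the selection
  thresholds in use, and the recovery experiment would then measure
  effect size, not pipeline correctness. MoCA is stored
  impairment-oriented so all informative features share the monotone
  direction; the direction itself carries no scientific weight.
* **Redundant features.** Copies of informative columns with a small
  fraction of swapped rows (record mix-ups), the way re-exported
  columns disagree in real tables. This shape is what jointly satisfies
  the three redundancy contracts: near-exact equality on most rows
  keeps the binned normalized mutual information above the 0.8
  redundancy gate (uniform Gaussian copy noise at r = 0.99 only reaches
  binned NMI ~0.65, so a "noisy Gaussian copy" generator cannot trip
  the gate at all); the swapped rows degrade the copy's dependence on
  the diagnosis consistently, so pruning keeps the source; and the swap
  fraction is calibrated (and checked per draw) against the
  `redundancyRho` correlation floor.
* **Noise, missingness, outliers.** Independent N(0,1) columns;
  missing-completely-at-random cells on continuous features (default
  10%, a typical clinical-registry rate); a small fraction of rows
  (default 2%) shifted 8 sd on one feature.

What the generator does **not** emulate: MRI physics, scanner and site
effects, longitudinal visits, genetic linkage, and realistic
inter-feature correlation beyond the planted duplicates. Passing tests
therefore demonstrate mechanism correctness — recovery of planted
structure under the stated assumptions — not clinical performance.

# Clinical preprocessing

`imputeTable()` fills continuous cells with the mean of the k = 5
nearest rows (Euclidean distance over standardized, mutually observed
continuous features; ties broken by row order) and categorical cells
with the column mode. `flagOutliers()` scores rows with an isolation
forest (100 trees, subsample 256) over the continuous features and
flags the top 5%; flagged rows are winsorized to the 1st/99th
percentile per feature rather than dropped, so the cohort size is
preserved — "handling" outliers by deletion would silently change n.
`fitPreprocess()` / `scaleAndEncode()` min-max scale continuous
features by training-set extrema (out-of-range values clamp; constant
features map to 0), rank-encode ordinals by their declared level order,
and one-hot nominals with an explicit unknown-category column. The
state is fitted on training rows only; applying it never reads held-out
statistics.

`serializeRecord()` renders a record as one clause per feature in fixed
order ("UPDRS total score is 34. Age is 67 years. ..."). The template
is configurable; the default covers the five deployed features. The
tokenizer splits numerals into digit tokens so unseen values never fall
out of vocabulary.

# Three-stage feature selection

Stage 1 ranks features with an ensemble (random forest: 500 trees,
depth 10, Gini; xgboost-style boosting: lr 0.1, depth 6, 300 rounds,
gain; LightGBM-style boosting run through xgboost's leaf-wise lossguide
mode: 31 leaves, lr 0.05, 400 rounds; the five-ranker profile adds
extra-trees and a SAMME AdaBoost on stumps). Two survivor rules are
provided as named profiles: weighted inverse-rank aggregation
V_f = sum_m w_m / r_{f,m}, normalized to S_f, keeping the top 10
("paper-3.5" style); and top-50% majority voting in at least two
rankers ("paper-4.2" style, the default — its redundancy threshold is
bounded and its hyperparameters fully determined). Ranker weights
default to 1; rank ties break by importance value then name order. The
boosting rankers use per-tree feature subsampling (0.8): greedy
boosting otherwise funnels all gain into one member of a duplicated
pair, blinding the ensemble vote to the other — exactly the failure
mode an ensemble ranker exists to avoid.

Stage 2 scans survivors in descending stage-1 score and removes one
member of every pair whose dependence exceeds the threshold. The
estimator is plug-in (normalized) mutual information over 10
equal-frequency bins; NMI = 2 MI / (H_i + H_j) is bounded in [0, 1]
and thresholded at 0.8 by default; raw-MI thresholding at 0.85 is kept
as an option but is scale-sensitive. The removed member is the one with
lower MI against the diagnosis (or simply the lower-ranked one,
configurable). Constant features have zero entropy; their NMI is
defined as 0 with a warning.

Stage 3 fits a gradient-boosted classifier on the survivors
(depth 3, lr 0.1, minimum split gain 5, validation early stopping — the
regularization matters: an unregularized booster memorizes noise
columns and hands them spurious attributions) and computes each
feature's mean absolute Shapley value for the predicted probability of
the sample's true class. Exact mode enumerates all 2^d coalitions
(d <= 15); sampling mode uses permutation walks with a recorded seed;
both share one value function. Two background-completion surrogates are
provided: *marginal* (interventional; low variance, the default) and
*conditional* (kernel-weighted background, bandwidth 0.5 standardized
units), which restores the symmetry axiom for functionally duplicated
features at the cost of estimator variance. Features with mean |phi|
below 0.01 are dropped.

On the default planted cohort (5 informative + 5 redundant + 10 noise,
n = 1000) the full default pipeline returns exactly the five
informative features; the test suite checks this end to end. The
recovery experiment runs on complete data: imputation jitter lowers the
binned NMI of duplicated pairs below the 0.8 gate at any realistic
missingness, so running selection after imputation would test the
imputer, not the selector. Missingness and outliers are exercised by
the preprocessing tests.

# Image branch

`buildBackbone()` constructs an EfficientNet-B0 (stem 32ch; seven
MBConv stages with expansion {1,6}, kernels {3,5}, widths
16/24/40/80/112/192/320; squeeze-excitation at a quarter of the block
input width; 1280ch head) with exact parameter accounting: 5,288,548
parameters at a 1000-class head, against 11,689,512 for ResNet-18 and
138,357,544 for VGG-16 (both constructed for accounting and baselines).
Rounding to 0.1M is half-up; the 2-D slice mode is the configuration
under which these printed counts hold, and a volumetric 3-D mode is
provided for synthetic experiments but excluded from count targets.

Mobile CBAM blocks are inserted after the expansion convolution of
every MBConv block. Channel attention applies a *shared*
depthwise-separable 1-D convolution (kernel 5) across the pooled
channel descriptor for the average- and max-pooled branches and gates
through a sigmoid; spatial attention applies a depthwise 7x7 over the
two channel-pooled maps with a pointwise combiner. The 1-D separable
design was chosen over a C -> C/16 bottleneck because the bottleneck
costs ~C^2/8 parameters — identical to the standard-CBAM shared MLP it
is meant to undercut — whereas the separable form costs ~109 parameters
per block independent of width, strictly below standard CBAM at every
stage width of the backbone. All attention coefficients lie strictly in
(0, 1) and refinement never changes tensor shape.

`encodeVolume()` encodes evenly spaced axial slices independently,
mean-pools, and projects to the shared 256-d space; stochastic depth
(drop 0.2, equivalently survival 0.8) applies only in training mode and
is seed-deterministic.

# Text branch

A BERT-base-shaped transformer (12 layers, hidden 768, 12 heads,
~108.6M parameters at the default vocabulary) encodes the serialized
record; small configurations train at desk scale. LoRA adapters
W' = W0 + (alpha/r) A B with r = 8, alpha = 16 target the query and
value projections of every layer: 12 x 2 x (768*8 + 8*768) = 294,912
trainable parameters, a 99.7% reduction versus full fine-tuning —
comfortably beyond the 96% bound the configuration is known for. B is
zero-initialized so injection leaves outputs bit-identical; merging
(alpha/r) A B into W0 reproduces the adapted encoder within 1e-5. The
base weights stay frozen (checked bit-exactly after training). A
768 -> 256 affine head (196,864 parameters) projects the pooled
embedding into the shared space. Pretrained clinical-domain weights can
be loaded from disk when available; the package never downloads them,
and all bundled experiments use seeded random initialization.

# Fusion

Image tokens (per-slice embeddings) and text tokens (projected token
states) interact through bidirectional scaled-dot-product multi-head
cross-attention in the 256-d space. The design is the minimal faithful
reading of "dynamic multi-head attention with learnable head selection
and gated fusion": head counts that do not divide 256 (3, 5, 6) use
per-head width floor(256/h) with a learned output re-projection, which
keeps the candidate set 2..6 intact; a small controller maps the
pooled embeddings to a probability vector over candidates (training
mixes candidates by probability — continuous in the controller logits —
and inference takes the argmax); the default is fixed mode with 4 heads,
the configuration the head-count ablations favour. The fused vector is
g * u + (1 - g) * v with g = sigmoid(affine([u; v])): an elementwise
convex combination whose gate is recorded for interpretability.

# Objective and training

The composite loss is lambda_f * focal + lambda_t * triplet +
lambda_c * consistency with lambda = (1, 0.5, 0.5), gamma = 2,
margin = 0.3, label smoothing 0.1. The consistency term is
1 - cos(u, v) between the two attended modality embeddings — the
alignment objective's functional form is the package's choice, made
explicit and configurable. Triplet mining is batch-hard. Focal and
triplet reduce to their textbook forms at the documented parameter
anchors (gamma = 0 recovers cross-entropy; the single-sample value at
p_t = 0.9 is 1.0536e-3), which the tests pin.

Training uses AdamW with cosine annealing (T_max 50 to eta_min 1e-6)
and global gradient-norm clipping at 1.0 (small batches under the
composite loss occasionally produce spiking gradients that otherwise
collapse the run), dropout 0.5 on the classifier, geometric/intensity
augmentation (flips,
±15° rotations, ±10% affine, elastic deformation with alpha = 50 /
sigma = 5 in the 224-pixel convention — where alpha scales a
sigma-smoothed unit field, giving ~1.6 px of smooth displacement at
224 px — rescaled to the working slice size with the field
re-normalized so the smoothing floor cannot inflate the amplitude,
intensity 0.9–1.1) on training images only, and mixup
(Beta(0.2, 0.2) images, Beta(0.1, 0.1) metadata). During mixup the text
branch receives the *dominant* component's serialization —
re-serializing a mixed record is ill-defined, and handing the model the
minority component's text would contradict the mixed target on half the
batch — and triplet mining likewise uses the dominant component's
label. Early stopping monitors validation focal loss
exactly (not the total), patience 20, with best-weight restoration.
Splitting is subject-level: 20% stratified held-out, five stratified
folds over the development set, and all scans of a subject co-locate.

# Desk-scale study conditions

The bundled experiments use: the 32^3-voxel grid with four axial slices
drawn from the central 25–75% of the z-extent (skull-stripped,
spatially normalized brains carry the informative deep structures
centrally; extreme slices are background) at a 16x16 working
resolution; a 1-layer / hidden-32 text encoder with
rank-4 adapters; 256-d fusion with 4 heads; n = 300 subjects, 30
epochs, batch 16, learning rate 2e-3 (the cosine schedule's initial
rate scaled for the small model; the 1e-4 default remains for larger
instantiations). The end-to-end check asks whether the trained pipeline
beats the 40% majority-class rate by at least 30 points on held-out
subjects — a capability floor, deliberately far below the headline
accuracies reported on restricted cohorts, which this package makes no
claim to reproduce. The selection experiments use n = 1000 subjects.

# Interpretability

Grad-CAM++ over the image stem's final convolutional activations, with
gradients taken from the target-class logit through the full fused
model: per-location alpha = g^2 / (2 g^2 + (sum A) g^3) (denominator
floored at 1e-8), channel weights sum(alpha * relu(g)), rectified
weighted activation sum, bilinear upsampling, max-normalization to
[0, 1]. With one feature map and a spatially uniform positive gradient
the closed form reduces to Grad-CAM, which the tests verify
numerically. Localization is validated only against the generator's
planted signal mask (saliency inside vs outside, hit rate over
correctly classified held-out PD subjects); claims about real
substantia-nigra localization would require restricted imaging data and
anatomical atlases, and are out of scope.

# Numerical core

No deep-learning runtime is available to R in this package's dependency
set, so the trainable components run on a small reverse-mode autodiff
tape implemented in `R/autodiff.R` (environments as nodes, closed-form
backward per operation). The engine is finite-difference checked across
all operation families; layer normalization, softmax rows, gather ops
and the attention algebra are exercised in the composite gradient test.
AdamW, the cosine schedule, and all losses are built on it.

# Known limitations

* Synthetic volumes are Gaussian fields with constant-offset
  ellipsoids; nothing about scanner physics, anatomy, or registration
  error is represented.
* The desk-scale model is a faithful miniature, not a performance
  claim; held-out accuracy on synthetic data says nothing about PPMI.
* The conditional Shapley surrogate trades variance for duplicate
  symmetry; its attributions need generous backgrounds to stabilize.
* Binned NMI saturates well below 1 for correlated-but-noisy pairs;
  redundancy detection at the 0.8 gate genuinely requires near-duplicate
  structure, which is a property of the estimator, not a bug.
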