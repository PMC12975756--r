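#' Cohort specification for the synthetic-data generator
#'
#' Describes the statistical structure of a synthetic multimodal cohort:
#' three-class labels (normal control, prodromal, diagnosed PD), MRI-like
#' volumes with two planted ellipsoidal signal regions whose contrast degrades
#' monotonically across classes, and a clinical table with planted
#' informative, near-duplicate redundant, and pure-noise features.
#'
#' @slot nSubjects number of subjects.
#' @slot classProbs length-3 probability vector (NC, prodromal, PD).
#' @slot gridShape integer length-3 voxel grid dimensions.
#' @slot roiCenters 2x3 matrix of ellipsoid centres in fractional coordinates.
#' @slot roiRadii 2x3 matrix of ellipsoid radii in fractional coordinates.
#' @slot contrastDeltas per-class mean intensity offset inside the ROIs
#'   (NC 0, prodromal delta1, PD delta2 with delta2 > delta1 >= 0).
#' @slot noiseSd background Gaussian standard deviation.
#' @slot nInformative,nRedundant,nNoise clinical feature counts.
#' @slot redundancyRho target Pearson correlation of redundant copies.
#' @slot missingRate MCAR missingness probability on continuous features.
#' @slot outlierRate fraction of rows planted as extreme outliers.
#' @slot repeatScans volumes emitted per subject (for leakage tests).
#' @slot seed integer random seed; identical specs give identical cohorts.
#' @export
setClass("CohortSpec", representation(
  nSubjects = "integer", classProbs = "numeric", gridShape = "integer",
  roiCenters = "matrix", roiRadii = "matrix", contrastDeltas = "numeric",
  noiseSd = "numeric", nInformative = "integer", nRedundant = "integer",
  nNoise = "integer", redundancyRho = "numeric", missingRate = "numeric",
  outlierRate = "numeric", repeatScans = "integer", seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (length(object@classProbs) != 3L ||
      abs(sum(object@classProbs) - 1) > 1e-9 || any(object@classProbs < 0))
    msg <- c(msg, "classProbs must be 3 nonnegative probabilities summing to 1")
  d <- object@contrastDeltas
  if (length(d) != 3L || d[1] != 0 || !(d[3] > d[2] && d[2] >= 0))
    msg <- c(msg, "contrastDeltas must be (0, d1, d2) with d2 > d1 >= 0")
  if (object@redundancyRho <= 0.9 || object@redundancyRho >= 1)
    msg <- c(msg, "redundancyRho must lie in (0.9, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be 3 dimensions, each >= 8 voxels")
  if (length(msg)) msg else TRUE
})

#' One subject's synthetic MRI-like volume
#'
#' @slot subjectId subject identifier (shared across repeat scans).
#' @slot voxels 3-D intensity array matching the cohort grid shape.
#' @slot label integer class: 0 = NC, 1 = prodromal, 2 = PD.
#' @slot roiMask logical array marking the planted signal voxels; ground
#'   truth for saliency localization tests only, never an input to models.
#' @export
setClass("VolumeSample", representation(
  subjectId = "character", voxels = "array", label = "integer",
  roiMask = "array"
))

setValidity("VolumeSample", function(object) {
  if (!object@label %in% 0:2) return("label must be 0, 1 or 2")
  if (!identical(dim(object@voxels), dim(object@roiMask)))
    return("voxels and roiMask dimensions differ")
  TRUE
})

#' Clinical metadata table
#'
#' Subjects x features table with per-feature kind (continuous, ordinal,
#' nominal). Missingness is carried as \code{NA} cells; \code{missingMask}
#' returns the explicit indicator. Ordinal features carry an explicit level
#' ordering in \code{levelsList}.
#'
#' @slot values data.frame of feature columns (numeric or character).
#' @slot kinds named character vector in
#'   \{"continuous", "ordinal", "nominal"\}.
#' @slot levelsList named list of level orderings for ordinal/nominal features.
#' @slot subjectIds one id per row.
#' @export
setClass("ClinicalTable", representation(
  values = "data.frame", kinds = "character", levelsList = "list",
  subjectIds = "character"
))

setValidity("ClinicalTable", function(object) {
  nm <- names(object@values)
  if (anyDuplicated(nm)) return("feature names must be unique")
  if (!identical(sort(nm), sort(names(object@kinds))))
    return("kinds must be named for exactly the value columns")
  if (!all(object@kinds %in% c("continuous", "ordinal", "nominal")))
    return("kinds must be continuous/ordinal/nominal")
  ord <- names(object@kinds)[object@kinds == "ordinal"]
  if (!all(ord %in% names(object@levelsList)))
    return("every ordinal feature needs an explicit level ordering")
  if (length(object@subjectIds) != nrow(object@values))
    return("subjectIds length must equal the number of rows")
  TRUE
})

#' Fitted preprocessing state
#'
#' Per-feature statistics fitted on training rows only: min/max for scaling,
#' category vocabularies for nominal features, KNN imputation neighbour
#' count, isolation-forest contamination, and training mean/sd used for the
#' imputation distance metric.
#'
#' @export
setClass("PreprocessState", representation(
  mins = "numeric", maxs = "numeric", means = "numeric", sds = "numeric",
  vocab = "list", ordinalLevels = "list", kinds = "character",
  k = "integer", contamination = "numeric", fitted = "logical"
))

setValidity("PreprocessState", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (object@contamination < 0 || object@contamination >= 0.5)
    return("contamination must lie in [0, 0.5)")
  ok <- !is.na(object@mins) & !is.na(object@maxs)
  if (any(object@mins[ok] > object@maxs[ok])) return("min > max for a feature")
  TRUE
})

#' Audit trail of the three-stage feature selection
#'
#' Records every intermediate quantity of the pipeline: per-ranker ranks,
#' aggregated and normalized importance scores, stage-1 survivors, pairwise
#' dependence values and removal events from the redundancy stage, per-feature
#' mean absolute Shapley values, and the final feature list.
#'
#' @slot ranks features x rankers matrix of ranks (1 = most important).
#' @slot weights per-ranker aggregation weights.
#' @slot scoreV,scoreS aggregated and normalized importance scores.
#' @slot stage1Survivors features surviving stage 1.
#' @slot dependence data.frame of evaluated pairs (feature i, feature j, value).
#' @slot removals data.frame of removal events (kept, removed, value, threshold).
#' @slot stage2Survivors features surviving stage 2.
#' @slot shapValues named mean |Shapley| per evaluated feature.
#' @slot selected final feature list, ranked by mean |Shapley|.
#' @slot profile parameterization profile used.
#' @slot seeds named integer seeds used at each stage.
#' @export
setClass("SelectionAudit", representation(
  ranks = "matrix", weights = "numeric", scoreV = "numeric",
  scoreS = "numeric", stage1Survivors = "character",
  dependence = "data.frame", removals = "data.frame",
  stage2Survivors = "character", shapValues = "numeric",
  selected = "character", profile = "character", seeds = "integer"
))

setValidity("SelectionAudit", function(object) {
  if (length(object@scoreS) && abs(sum(object@scoreS) - 1) > 1e-9)
    return("normalized scores must sum to 1")
  if (length(object@stage2Survivors) &&
      !all(object@stage2Survivors %in% object@stage1Survivors))
    return("stage-2 survivors must be a subset of stage-1 survivors")
  if (length(object@selected) && length(object@stage2Survivors) &&
      !all(object@selected %in% object@stage2Survivors))
    return("final selection must be a subset of stage-2 survivors")
  if (nrow(object@removals) &&
      anyDuplicated(object@removals$removed))
    return("each removed feature must appear in exactly one removal event")
  TRUE
})

#' Exact parameter accounting for a model
#'
#' @slot modules named integer-ish numeric vector of per-module parameter
#'   counts (the names itemize stem/stages/head/classifier or equivalent).
#' @slot total total parameter count; equals \code{sum(modules)}.
#' @slot totalM total rounded half-up to 0.1 million.
#' @slot trainable,frozen trainable/frozen split.
#' @slot macs multiply-accumulate count at \code{inputSize}, \code{NA} when
#'   not computed.
#' @slot inputSize character description of the input the MAC count assumes.
#' @export
setClass("ParamReport", representation(
  modules = "numeric", total = "numeric", totalM = "numeric",
  trainable = "numeric", frozen = "numeric", macs = "numeric",
  inputSize = "character"
))

setValidity("ParamReport", function(object) {
  if (abs(sum(object@modules) - object@total) > 0.5)
    return("per-module counts must sum to the total")
  if (abs(object@trainable + object@frozen - object@total) > 0.5)
    return("trainable + frozen must equal total")
  TRUE
})

#' Subject-level split plan
#'
#' @slot assignment named character vector subject -> "heldout" or "dev".
#' @slot fold named integer vector over development subjects (1..nFolds).
#' @slot strata named character vector subject -> class label used for
#'   stratification.
#' @slot nFolds number of cross-validation folds.
#' @export
setClass("SplitPlan", representation(
  assignment = "character", fold = "integer", strata = "character",
  nFolds = "integer"
))

setValidity("SplitPlan", function(object) {
  dev <- names(object@assignment)[object@assignment == "dev"]
  if (!setequal(names(object@fold), dev))
    return("folds must cover exactly the development subjects")
  if (length(object@fold) && any(object@fold < 1L | object@fold > object@nFolds))
    return("fold indices out of range")
  TRUE
})

#' Grad-CAM++ saliency map
#'
#' @slot relevance nonnegative array aligned to the input grid, max-normalized
#'   to [0, 1].
#' @slot targetClass integer class the map explains.
#' @slot maxValue maximum relevance before normalization.
#' @export
setClass("SaliencyMap", representation(
  relevance = "array", targetClass = "integer", maxValue = "numeric"
))

setValidity("SaliencyMap", function(object) {
  r <- object@relevance
  if (any(r < -1e-12) || any(r > 1 + 1e-12))
    return("relevance values must lie in [0, 1]")
  TRUE
})
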