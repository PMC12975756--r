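#' @describeIn ClinicalTable-class feature value data.frame
#' @param x a \code{ClinicalTable}
#' @export
clinicalValues <- function(x) x@values

#' @describeIn ClinicalTable-class named per-feature kind vector
#' @export
featureKinds <- function(x) x@kinds

#' @describeIn ClinicalTable-class logical missingness indicator matrix
#' @export
missingMask <- function(x) {
  m <- as.matrix(as.data.frame(lapply(x@values, is.na)))
  dimnames(m) <- list(x@subjectIds, names(x@values))
  m
}

#' @describeIn ClinicalTable-class subject identifiers
#' @export
subjectIds <- function(x) x@subjectIds

#' @describeIn SelectionAudit-class final selected feature list
#' @param audit a \code{SelectionAudit}
#' @export
selectedFeatures <- function(audit) audit@selected

#' @describeIn ParamReport-class total parameter count
#' @param report a \code{ParamReport}
#' @export
totalParams <- function(report) report@total

#' @describeIn ParamReport-class total in millions, rounded half-up to 0.1M
#' @export
totalParamsM <- function(report) report@totalM

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d subjects, grid %s, class probs %s\n",
    object@nSubjects, paste(object@gridShape, collapse = "x"),
    paste(object@classProbs, collapse = "/")))
  cat(sprintf(
    "  contrast deltas %s, noise sd %.3g; clinical %d informative + %d redundant + %d noise\n",
    paste(object@contrastDeltas, collapse = "/"), object@noiseSd,
    object@nInformative, object@nRedundant, object@nNoise))
  cat(sprintf("  missing %.0f%%, outliers %.0f%%, seed %d\n",
              100 * object@missingRate, 100 * object@outlierRate, object@seed))
})

setMethod("show", "VolumeSample", function(object) {
  cat(sprintf("VolumeSample %s: %s voxels, label %d, %d signal voxels\n",
              object@subjectId, paste(dim(object@voxels), collapse = "x"),
              object@label, sum(object@roiMask)))
})

setMethod("show", "ClinicalTable", function(object) {
  k <- table(factor(object@kinds, c("continuous", "ordinal", "nominal")))
  cat(sprintf(
    "ClinicalTable: %d subjects x %d features (%d continuous, %d ordinal, %d nominal); %d missing cells\n",
    nrow(object@values), ncol(object@values), k[1], k[2], k[3],
    sum(missingMask(object))))
})

setMethod("show", "SelectionAudit", function(object) {
  cat(sprintf("SelectionAudit [%s profile]\n", object@profile))
  cat(sprintf("  stage 1: %d ranked -> %d survivors\n",
              nrow(object@ranks), length(object@stage1Survivors)))
  cat(sprintf("  stage 2: %d removals -> %d survivors\n",
              nrow(object@removals), length(object@stage2Survivors)))
  cat(sprintf("  stage 3: selected %s\n",
              paste(object@selected, collapse = ", ")))
})

setMethod("show", "ParamReport", function(object) {
  cat(sprintf("ParamReport: %s parameters (%.1fM), %s trainable / %s frozen\n",
              format(object@total, big.mark = ","), object@totalM,
              format(object@trainable, big.mark = ","),
              format(object@frozen, big.mark = ",")))
  for (nm in names(object@modules))
    cat(sprintf("  %-28s %12s\n", nm,
                format(object@modules[[nm]], big.mark = ",")))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d held-out / %d development subjects, %d folds\n",
              sum(object@assignment == "heldout"),
              sum(object@assignment == "dev"), object@nFolds))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap (class %d): grid %s, pre-normalization max %.4g\n",
              object@targetClass, paste(dim(object@relevance), collapse = "x"),
              object@maxValue))
})
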