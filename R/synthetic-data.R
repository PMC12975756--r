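#' Construct a synthetic-cohort specification
#'
#' The generator emulates the statistical structure the classifier assumes:
#' three diagnostic classes (NC, prodromal, PD) in roughly 40:30:30
#' proportions; MRI-like volumes with two compact deep-brain signal regions
#' ("nigra-like" and "putamen-like" ellipsoids) whose mean intensity offset
#' grows monotonically across classes; and a clinical table with planted
#' informative features (class-conditional means shifting monotonically with
#' label), near-duplicate redundant copies, pure-noise columns, MCAR
#' missingness and a small fraction of extreme outlier rows.
#'
#' @param nSubjects number of subjects.
#' @param classProbs probabilities for (NC, prodromal, PD); must sum to 1.
#' @param gridShape voxel grid dimensions, default 64x64x64 isotropic.
#' @param contrastDeltas per-class ROI intensity offsets \code{c(0, d1, d2)},
#'   \code{d2 > d1 >= 0}.
#' @param noiseSd background Gaussian standard deviation.
#' @param nInformative,nRedundant,nNoise clinical feature counts.
#' @param redundancyRho target Pearson correlation of redundant copies,
#'   in (0.9, 1).
#' @param missingRate MCAR missingness probability on continuous features.
#' @param outlierRate fraction of rows planted as >= 6-sd outliers.
#' @param repeatScans volumes per subject (> 1 exercises subject-level
#'   leakage prevention downstream).
#' @param seed integer seed; identical specs yield identical cohorts.
#' @return a validated \code{\linkS4class{CohortSpec}}.
#' @export
cohortSpec <- function(nSubjects = 200L,
                       classProbs = c(0.4, 0.3, 0.3),
                       gridShape = c(64L, 64L, 64L),
                       contrastDeltas = c(0, 0.5, 1.0),
                       noiseSd = 0.2,
                       nInformative = 5L,
                       nRedundant = 5L,
                       nNoise = 10L,
                       redundancyRho = 0.97,
                       missingRate = 0.1,
                       outlierRate = 0.02,
                       repeatScans = 1L,
                       seed = 42L) {
  # Ellipsoid centres/radii in fractional grid coordinates, mimicking the
  # placement of deep-brain nuclei; exact anatomy is irrelevant to the
  # tested claims.
  centers <- rbind(nigra = c(0.50, 0.45, 0.40),
                   putamen = c(0.63, 0.57, 0.46))
  radii <- rbind(nigra = c(0.07, 0.055, 0.05),
                 putamen = c(0.10, 0.07, 0.06))
  obj <- new("CohortSpec",
    nSubjects = as.integer(nSubjects), classProbs = as.numeric(classProbs),
    gridShape = as.integer(gridShape), roiCenters = centers,
    roiRadii = radii, contrastDeltas = as.numeric(contrastDeltas),
    noiseSd = noiseSd, nInformative = as.integer(nInformative),
    nRedundant = as.integer(nRedundant), nNoise = as.integer(nNoise),
    redundancyRho = redundancyRho, missingRate = missingRate,
    outlierRate = outlierRate, repeatScans = as.integer(repeatScans),
    seed = as.integer(seed))
  validObject(obj)
  obj
}

roi_mask <- function(gridShape, centers, radii) {
  g <- gridShape
  ax <- (seq_len(g[1]) - 0.5) / g[1]
  ay <- (seq_len(g[2]) - 0.5) / g[2]
  az <- (seq_len(g[3]) - 0.5) / g[3]
  mask <- array(FALSE, dim = g)
  for (r in seq_len(nrow(centers))) {
    dx <- ((ax - centers[r, 1]) / radii[r, 1])^2
    dy <- ((ay - centers[r, 2]) / radii[r, 2])^2
    dz <- ((az - centers[r, 3]) / radii[r, 3])^2
    m <- outer(outer(dx, dy, "+"), dz, "+") <= 1
    mask <- mask | m
  }
  mask
}

# Class-conditional structure of the planted informative features. The first
# five mirror the clinically deployed set (UPDRS, Age, MoCA, HY_stage,
# Weight); additional informative columns get generated names. Every
# informative feature shifts its mean upward with label (for MoCA the stored
# quantity is an impairment-oriented score so the monotone direction is
# shared; the direction carries no scientific weight).
informative_layout <- function(nInformative) {
  # Every planted informative feature carries a one-sd-per-class-step
  # effect: the cohort is a validation instrument, and "informative" must
  # mean unambiguously recoverable, not borderline.
  base <- data.frame(
    name = c("UPDRS", "Age", "MoCA", "HY_stage", "Weight"),
    kind = c("continuous", "continuous", "continuous", "ordinal",
             "continuous"),
    mu0 = c(8, 60, 4, 0.5, 70),
    effect = c(6, 6, 3, 0.8, 7),
    sd = c(6, 6, 3, 0.8, 7),
    stringsAsFactors = FALSE)
  if (nInformative <= 5L) return(base[seq_len(nInformative), ])
  extra <- data.frame(
    name = sprintf("clin_%02d", seq_len(nInformative - 5L)),
    kind = "continuous", mu0 = 0, effect = 1, sd = 1,
    stringsAsFactors = FALSE)
  rbind(base, extra)
}

#' Generate a synthetic multimodal cohort
#'
#' @param spec a \code{\linkS4class{CohortSpec}}.
#' @param volumes if \code{FALSE}, skip volume synthesis and return only the
#'   clinical table and labels (useful when exercising the metadata pipeline
#'   at large n).
#' @return a list with elements \code{samples} (list of
#'   \code{\linkS4class{VolumeSample}}, one per scan), \code{clinical}
#'   (\code{\linkS4class{ClinicalTable}}), \code{labels} (integer per
#'   subject), and \code{subjectIds}.
#' @export
generateCohort <- function(spec, volumes = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- spec@nSubjects
  with_seed(spec@seed, {
    labels <- sample(0:2, n, replace = TRUE, prob = spec@classProbs)
    ids <- sprintf("subj_%04d", seq_len(n))

    clinical <- generate_clinical(spec, labels, ids)

    samples <- list()
    if (volumes) {
      mask <- roi_mask(spec@gridShape, spec@roiCenters, spec@roiRadii)
      nv <- prod(spec@gridShape)
      idx <- 1L
      for (i in seq_len(n)) {
        for (s in seq_len(spec@repeatScans)) {
          vox <- array(rnorm(nv, 0, spec@noiseSd), dim = spec@gridShape)
          vox[mask] <- vox[mask] + spec@contrastDeltas[labels[i] + 1L]
          samples[[idx]] <- new("VolumeSample",
            subjectId = ids[i], voxels = vox, label = labels[i],
            roiMask = array(mask, dim = spec@gridShape))
          idx <- idx + 1L
        }
      }
    }
    list(samples = samples, clinical = clinical, labels = labels,
         subjectIds = ids)
  })
}

generate_clinical <- function(spec, labels, ids) {
  n <- length(labels)
  lay <- informative_layout(spec@nInformative)
  vals <- list()
  kinds <- character()
  levelsList <- list()

  for (i in seq_len(nrow(lay))) {
    x <- lay$mu0[i] + lay$effect[i] * labels + rnorm(n, 0, lay$sd[i])
    if (lay$kind[i] == "ordinal") {
      stage <- pmin(pmax(round(x), 0L), 5L)
      vals[[lay$name[i]]] <- as.character(stage)
      kinds[lay$name[i]] <- "ordinal"
      levelsList[[lay$name[i]]] <- as.character(0:5)
    } else {
      vals[[lay$name[i]]] <- x
      kinds[lay$name[i]] <- "continuous"
    }
  }

  # Redundant features: exact copies of continuous informative columns with
  # a small fraction of swapped rows (the way re-exported/derived columns
  # disagree in real clinical tables: identical except for record mix-ups).
  # This shape reconciles the three redundancy contracts at once: most rows
  # identical keeps the 10-equal-frequency-bin NMI above the 0.8 gate
  # (uniform Gaussian copy noise at r = 0.99 only reaches binned NMI
  # ~0.65); the swapped rows are fully label-misaligned, pulling the copy's
  # dependence on the target consistently below the source's so redundancy
  # pruning keeps the source; and the swap fraction keeps the pair
  # correlation above the redundancyRho floor.
  contNames <- lay$name[lay$kind == "continuous"]
  corruptFrac <- 0.7 * (1 - spec@redundancyRho)
  # Swapped pairs always cross class boundaries: a record mix-up between
  # subjects of different stages strictly degrades the copy's alignment
  # with the diagnosis, so "which member of the pair is the original" is
  # decidable from the data rather than a coin flip.
  cross_pairs <- function(k2) {
    perm <- sample(n)
    used <- logical(n)
    out <- matrix(0L, 0L, 2L)
    for (i in perm) {
      if (nrow(out) >= k2) break
      if (used[i]) next
      j <- perm[!used[perm] & labels[perm] != labels[i] & perm != i][1]
      if (is.na(j)) break
      used[c(i, j)] <- TRUE
      out <- rbind(out, c(i, j))
    }
    out
  }
  for (j in seq_len(spec@nRedundant)) {
    src <- contNames[(j - 1L) %% length(contNames) + 1L]
    x <- vals[[src]]
    # fixed swap count targets r ~ 1 - corruptFrac = rho + 0.3 (1 - rho);
    # the sample correlation is checked and the swap shrunk if a draw
    # lands below the floor
    k <- max(2L, round(corruptFrac * n))
    repeat {
      pr <- cross_pairs(max(1L, k %/% 2L))
      y2 <- x
      y2[pr[, 1L]] <- x[pr[, 2L]]
      y2[pr[, 2L]] <- x[pr[, 1L]]
      if (cor(x, y2) >= spec@redundancyRho || k <= 2L) break
      k <- max(2L, floor(k * 0.8))
    }
    nm <- sprintf("%s_dup%d", src, (j - 1L) %/% length(contNames) + 1L)
    vals[[nm]] <- y2
    kinds[nm] <- "continuous"
  }

  for (j in seq_len(spec@nNoise)) {
    nm <- sprintf("noise_%02d", j)
    vals[[nm]] <- rnorm(n)
    kinds[nm] <- "continuous"
  }

  df <- as.data.frame(vals, stringsAsFactors = FALSE, optional = TRUE)
  cont <- names(kinds)[kinds == "continuous"]

  # Planted outliers: shift one continuous feature by 8 sd in selected rows.
  nOut <- floor(spec@outlierRate * n)
  if (nOut > 0) {
    rows <- sample(n, nOut)
    for (r in rows) {
      f <- sample(cont, 1L)
      df[r, f] <- df[r, f] + 8 * sd(df[[f]])
    }
  }

  # MCAR missingness on continuous features.
  if (spec@missingRate > 0) {
    for (f in cont) {
      miss <- runif(n) < spec@missingRate
      df[miss, f] <- NA_real_
    }
  }

  new("ClinicalTable", values = df, kinds = kinds,
      levelsList = levelsList, subjectIds = ids)
}

#' Worked fixture for the inverse-rank aggregation rule
#'
#' A fixed 4-feature x 3-ranker rank matrix with unit weights, small enough
#' that the aggregated importance scores \eqn{V_f = \sum_m w_m / r_{f,m}}
#' can be checked by hand (e.g. ranks (1,2,4) give 1 + 1/2 + 1/4 = 1.75).
#'
#' @return list with \code{ranks} (features x rankers) and \code{weights}.
#' @export
generateWorkedRankingFixture <- function() {
  ranks <- rbind(
    featA = c(1, 1, 1),
    featB = c(1, 2, 4),
    featC = c(2, 4, 2),
    featD = c(4, 3, 3))
  colnames(ranks) <- c("ranker1", "ranker2", "ranker3")
  list(ranks = ranks, weights = c(ranker1 = 1, ranker2 = 1, ranker3 = 1))
}

#' Write a cohort to disk (NIfTI volumes + CSV clinical table + manifest)
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory, created if absent.
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- list()
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    f <- sprintf("%s_scan%02d.nii.gz", s@subjectId,
                 sum(vapply(cohort$samples[seq_len(i)], function(x)
                   x@subjectId == s@subjectId, logical(1))))
    RNifti::writeNifti(RNifti::asNifti(s@voxels), file.path(dir, f))
    entries[[i]] <- list(subject_id = s@subjectId, file = f,
                         label = s@label)
  }
  tab <- cbind(subject_id = cohort$clinical@subjectIds,
               cohort$clinical@values,
               label = cohort$labels[match(cohort$clinical@subjectIds,
                                           cohort$subjectIds)])
  write.csv(tab, file.path(dir, "clinical.csv"), row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(clinical = "clinical.csv", volumes = entries),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
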