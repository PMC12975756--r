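test_that("cohort specification validates its invariants", {
  expect_error(cohortSpec(nSubjects = 0L), "positive")
  expect_error(cohortSpec(classProbs = c(0.5, 0.4, 0.3)), "summing to 1")
  expect_error(cohortSpec(contrastDeltas = c(0, 1, 0.5)), "d2 > d1")
  expect_error(cohortSpec(redundancyRho = 0.5), "redundancyRho")
})

test_that("identical specs give identical cohorts", {
  spec <- cohortSpec(nSubjects = 20L, gridShape = c(16L, 16L, 16L),
                     seed = 5L)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(a$clinical@values, b$clinical@values)
  expect_identical(a$labels, b$labels)
  expect_identical(a$samples[[3]]@voxels, b$samples[[3]]@voxels)
})

test_that("class draws respect the configured mixture", {
  co <- generateCohort(cohortSpec(nSubjects = 2000L, seed = 9L),
                       volumes = FALSE)
  counts <- tabulate(co$labels + 1L, 3L)
  expected <- 2000 * c(0.4, 0.3, 0.3)
  sds <- sqrt(2000 * c(0.4, 0.3, 0.3) * (1 - c(0.4, 0.3, 0.3)))
  expect_true(all(abs(counts - expected) <= 3 * sds))
})

test_that("planted ROI contrast matches the configured delta", {
  co <- generateCohort(cohortSpec(nSubjects = 30L,
                                  gridShape = c(16L, 16L, 16L),
                                  seed = 12L))
  pd <- Filter(function(s) s@label == 2L, co$samples)
  d <- vapply(pd, function(s)
    mean(s@voxels[s@roiMask]) - mean(s@voxels[!s@roiMask]), numeric(1))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1.0), 3 * se + 0.02)
})

test_that("informative features shift monotonically across classes", {
  p <- fx_planted()
  for (f in informative5) {
    means <- tapply(p$M[, f], p$labels, mean)
    expect_true(all(diff(means) > 0), info = f)
  }
})

test_that("redundant copies satisfy both the correlation floor and the NMI gate", {
  p <- fx_planted()
  dups <- grep("_dup", colnames(p$M), value = TRUE)
  expect_length(dups, 5L)
  for (dnm in dups) {
    src <- sub("_dup[0-9]+$", "", dnm)
    expect_gte(cor(p$M[, src], p$M[, dnm]), 0.97)
    expect_gt(dependence(p$M[, src], p$M[, dnm], mode = "nmi"), 0.8)
  }
})

test_that("noise features are uncorrelated with the label", {
  co <- generateCohort(cohortSpec(nSubjects = 2000L, missingRate = 0,
                                  outlierRate = 0, seed = 13L),
                       volumes = FALSE)
  for (f in grep("noise_", names(co$clinical@values), value = TRUE)) {
    expect_lt(abs(cor(co$clinical@values[[f]], co$labels)),
              0.1, label = f)
  }
})

test_that("missingness and outliers are planted as configured", {
  spec <- cohortSpec(nSubjects = 500L, missingRate = 0.1,
                     outlierRate = 0.02, seed = 31L)
  co <- generateCohort(spec, volumes = FALSE)
  mm <- missingMask(co$clinical)
  cont <- names(co$clinical@kinds)[co$clinical@kinds == "continuous"]
  rate <- mean(mm[, cont])
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / (500 * length(cont))))
  expect_equal(sum(mm[, setdiff(colnames(mm), cont)]), 0)
})

test_that("the worked ranking fixture reproduces hand arithmetic", {
  fx <- generateWorkedRankingFixture()
  agg <- aggregateRanks(fx$ranks, fx$weights)
  expect_equal(unname(agg$V["featA"]), 3.0)
  expect_equal(unname(agg$V["featB"]), 1 + 0.5 + 0.25)
  expect_equal(sum(agg$S), 1, tolerance = 1e-12)
})

test_that("cohorts round-trip through NIfTI + CSV + manifest", {
  dir <- withr::local_tempdir()
  co <- generateCohort(cohortSpec(nSubjects = 3L,
                                  gridShape = c(12L, 12L, 12L),
                                  repeatScans = 2L, seed = 2L))
  writeCohort(co, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man$volumes, 6L)
  v1 <- RNifti::readNifti(file.path(dir, man$volumes[[1]]$file))
  expect_equal(dim(v1), c(12L, 12L, 12L))
  expect_equal(max(abs(as.array(v1) - co$samples[[1]]@voxels)), 0,
               tolerance = 1e-6)
  tab <- read.csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("subject_id", "label", "UPDRS") %in% names(tab)))
})

test_that("repeat scans share subject ids and labels", {
  co <- generateCohort(cohortSpec(nSubjects = 4L,
                                  gridShape = c(12L, 12L, 12L),
                                  repeatScans = 3L, seed = 6L))
  ids <- vapply(co$samples, function(s) s@subjectId, character(1))
  expect_equal(length(co$samples), 12L)
  expect_equal(unname(table(ids)), rep(3L, 4L), ignore_attr = TRUE)
  for (s in co$samples)
    expect_equal(s@label, co$labels[match(s@subjectId, co$subjectIds)])
})
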