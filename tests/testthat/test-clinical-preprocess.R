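mk_table <- function(df, kinds = NULL, levelsList = list()) {
  if (is.null(kinds))
    kinds <- setNames(rep("continuous", ncol(df)), names(df))
  new("ClinicalTable", values = df, kinds = kinds,
      levelsList = levelsList,
      subjectIds = sprintf("s%03d", seq_len(nrow(df))))
}

test_that("imputation is the identity on complete data and idempotent", {
  co <- generateCohort(cohortSpec(nSubjects = 80L, seed = 14L),
                       volumes = FALSE)
  imp1 <- imputeTable(co$clinical, 5L)
  expect_equal(sum(missingMask(imp1)), 0)
  imp2 <- imputeTable(imp1, 5L)
  expect_identical(imp1@values, imp2@values)
  # observed cells unchanged
  mm <- missingMask(co$clinical)
  for (f in names(co$clinical@values)) {
    obs <- !mm[, f]
    expect_identical(imp1@values[[f]][obs], co$clinical@values[[f]][obs])
  }
})

test_that("a twin row forces the nearest-neighbour fill at k = 1", {
  df <- data.frame(a = c(1, 1, 9), b = c(5, NA, 40))
  imp <- imputeTable(mk_table(df), k = 1L)
  expect_equal(imp@values$b[2], 5)
})

test_that("categorical cells take the column mode", {
  df <- data.frame(a = c(1, 2, 3, 4),
                   g = c("x", "x", NA, "y"),
                   stringsAsFactors = FALSE)
  tab <- mk_table(df, kinds = c(a = "continuous", g = "nominal"))
  imp <- imputeTable(tab)
  expect_equal(imp@values$g[3], "x")
})

test_that("a fully missing column raises a named error", {
  df <- data.frame(a = 1:4, b = rep(NA_real_, 4))
  expect_error(imputeTable(mk_table(df)), "b")
})

test_that("KNN imputation beats column-mean imputation on planted MCAR", {
  spec <- cohortSpec(nSubjects = 300L, missingRate = 0, outlierRate = 0,
                     seed = 8L)
  truth <- generateCohort(spec, volumes = FALSE)$clinical
  df <- truth@values
  masked <- list()
  withr::with_seed(3, {
    for (f in c("UPDRS", "Age", "MoCA", "Weight")) {
      m <- runif(nrow(df)) < 0.1
      masked[[f]] <- m
      df[m, f] <- NA
    }
  })
  tab <- new("ClinicalTable", values = df, kinds = truth@kinds,
             levelsList = truth@levelsList, subjectIds = truth@subjectIds)
  imp <- imputeTable(tab, 5L)
  sseK <- sseM <- 0
  for (f in names(masked)) {
    m <- masked[[f]]
    sseK <- sseK + sum((imp@values[[f]][m] - truth@values[[f]][m])^2)
    sseM <- sseM + sum((mean(df[[f]], na.rm = TRUE) -
                          truth@values[[f]][m])^2)
  }
  expect_lt(sqrt(sseK), sqrt(sseM))
})

test_that("outlier flagging obeys the contamination quantile", {
  co <- generateCohort(cohortSpec(nSubjects = 200L, missingRate = 0,
                                  outlierRate = 0, seed = 17L),
                       volumes = FALSE)
  fo <- flagOutliers(imputeTable(co$clinical), contamination = 0.05)
  expect_equal(sum(fo$flags), floor(0.05 * 200))
  fo0 <- flagOutliers(imputeTable(co$clinical), contamination = 0)
  expect_equal(sum(fo0$flags), 0L)
  expect_identical(fo0$table@values, imputeTable(co$clinical)@values)
  expect_error(flagOutliers(imputeTable(co$clinical), 0.5), "contamination")
})

test_that("planted extreme rows are all flagged and winsorized", {
  withr::with_seed(10, {
    df <- as.data.frame(matrix(rnorm(100 * 5), 100))
    names(df) <- paste0("f", 1:5)
    rows <- c(7, 23, 48, 66, 91)
    for (r in rows) df[r, sample(5, 1)] <- 8   # 8 sd above the mean
  })
  tab <- mk_table(df)
  fo <- flagOutliers(tab, 0.05)
  expect_setequal(which(fo$flags), rows)
  hi <- vapply(df, quantile, numeric(1), probs = 0.99)
  for (f in names(df))
    expect_true(all(fo$table@values[[f]][fo$flags] <= hi[f] + 1e-9))
})

test_that("min-max scaling maps the midpoint to 0.5 and clamps", {
  train <- mk_table(data.frame(a = c(10, 30)))
  st <- fitPreprocess(train)
  M <- scaleAndEncode(mk_table(data.frame(a = c(20, 5, 50))), st)
  expect_equal(as.numeric(M[, "a"]), c(0.5, 0, 1))
})

test_that("constant training features scale to zero", {
  st <- fitPreprocess(mk_table(data.frame(a = c(4, 4, 4))))
  M <- scaleAndEncode(mk_table(data.frame(a = c(4, 9))), st)
  expect_equal(as.numeric(M[, "a"]), c(0, 0))
})

test_that("scaling round-trips training data and encodes deterministically", {
  co <- generateCohort(cohortSpec(nSubjects = 60L, missingRate = 0,
                                  outlierRate = 0, seed = 19L),
                       volumes = FALSE)
  st <- fitPreprocess(co$clinical)
  M <- scaleAndEncode(co$clinical, st)
  expect_true(all(M >= 0 & M <= 1))
  inv <- inverseScale(M, st)
  for (f in names(co$clinical@kinds)[co$clinical@kinds == "continuous"])
    expect_equal(inv[, f], co$clinical@values[[f]], tolerance = 1e-9,
                 ignore_attr = TRUE)
  expect_identical(M, scaleAndEncode(co$clinical, st))
})

test_that("nominal features expand one-hot with an unknown column", {
  train <- mk_table(data.frame(g = c("a", "b", "a"),
                               stringsAsFactors = FALSE),
                    kinds = c(g = "nominal"))
  st <- fitPreprocess(train)
  M <- scaleAndEncode(mk_table(data.frame(g = c("b", "zzz"),
                                          stringsAsFactors = FALSE),
                               kinds = c(g = "nominal")), st)
  expect_equal(colnames(M), c("g=a", "g=b", "g=__unknown__"))
  expect_equal(unname(M[1, ]), c(0, 1, 0))
  expect_equal(unname(M[2, ]), c(0, 0, 1))
})

test_that("the fitted state never reads held-out rows", {
  co <- generateCohort(cohortSpec(nSubjects = 100L, missingRate = 0,
                                  outlierRate = 0, seed = 23L),
                       volumes = FALSE)
  tr <- new("ClinicalTable", values = co$clinical@values[1:70, ],
            kinds = co$clinical@kinds, levelsList = co$clinical@levelsList,
            subjectIds = co$clinical@subjectIds[1:70])
  stA <- fitPreprocess(tr)
  # perturbing held-out rows must leave the state untouched
  perturbed <- co$clinical@values
  perturbed[71:100, "UPDRS"] <- perturbed[71:100, "UPDRS"] + 1000
  trB <- new("ClinicalTable", values = perturbed[1:70, ],
             kinds = co$clinical@kinds,
             levelsList = co$clinical@levelsList,
             subjectIds = co$clinical@subjectIds[1:70])
  stB <- fitPreprocess(trB)
  expect_identical(stA@mins, stB@mins)
  expect_identical(stA@maxs, stB@maxs)
})

test_that("record serialization is deterministic and clause-local", {
  rec <- list(UPDRS = 34, Age = 67, MoCA = 3.2, HY_stage = "2",
              Weight = 70)
  s1 <- serializeRecord(rec)
  expect_identical(s1, serializeRecord(rec))
  expect_match(s1, "UPDRS total score is 34")
  expect_match(s1, "Age is 67 years")
  rec2 <- rec; rec2$MoCA <- 9.9
  s2 <- serializeRecord(rec2)
  d1 <- strsplit(s1, "\\. ")[[1]]
  d2 <- strsplit(s2, "\\. ")[[1]]
  expect_equal(sum(d1 != d2), 1L)
  expect_match(d1[d1 != d2], "MoCA")
  expect_identical(serializeRecord(rec, character()), "")
  expect_error(serializeRecord(list(Age = 5), defaultTemplate()), "UPDRS")
})
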