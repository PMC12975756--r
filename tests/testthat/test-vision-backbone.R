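test_that("reference parameter counts are exact", {
  b0 <- buildBackbone(backboneSpec("efficientnet-b0",
                                   numClasses = 1000L))$report
  expect_equal(totalParams(b0), 5288548)
  expect_equal(totalParamsM(b0), 5.3)
  r18 <- buildBackbone(backboneSpec("resnet-18", numClasses = 1000L))$report
  expect_equal(totalParams(r18), 11689512)
  expect_equal(totalParamsM(r18), 11.7)
  v16 <- buildBackbone(backboneSpec("vgg-16", numClasses = 1000L))$report
  expect_equal(totalParams(v16), 138357544)
  expect_equal(totalParamsM(v16), 138.4)
  # per-module counts sum to the total
  expect_equal(sum(b0@modules), totalParams(b0))
  expect_error(buildBackbone(backboneSpec("alexnet")), "supported")
})

test_that("percentage reduction from rounded counts reproduces 54.7%", {
  b0 <- totalParamsM(buildBackbone(backboneSpec("efficientnet-b0"))$report)
  r18 <- totalParamsM(buildBackbone(backboneSpec("resnet-18"))$report)
  expect_equal(round(100 * (r18 - b0) / r18, 1), 54.7)
})

test_that("Mobile CBAM adds an itemized parameter delta", {
  plain <- buildBackbone(backboneSpec("efficientnet-b0"))$report
  cbam <- buildBackbone(backboneSpec("efficientnet-b0",
                                     withMobileCbam = TRUE))$report
  expect_gt(totalParams(cbam), totalParams(plain))
  expect_true("mobile_cbam" %in% names(cbam@modules))
  expect_equal(totalParams(cbam) - totalParams(plain),
               unname(cbam@modules["mobile_cbam"]))
})

test_that("Mobile CBAM undercuts standard CBAM at every wide stage", {
  for (C in c(128L, 240L, 480L, 672L, 1152L)) {
    cmp <- cbamParamComparison(C)
    expect_lt(cmp["mobile"], cmp["standard"])
  }
})

test_that("separable-convolution ratio matches its closed form", {
  expect_equal(dwconvParamRatio(64, 3), 36864 / 4672)
  expect_equal(round(dwconvParamRatio(64, 3)), 8)
  expect_equal(dwconvParamRatio(1, 3), 9 / 10)
  expect_gt(dwconvParamRatio(512, 3), dwconvParamRatio(64, 3))
})

test_that("Mobile CBAM preserves shape and produces gates in (0,1) at all stage widths", {
  # expanded widths of the seven MBConv stages
  widths <- c(32L, 96L, 144L, 240L, 480L, 672L, 1152L)
  w <- initMobileCbam(seed = 2L)
  set.seed(1)
  for (C in widths) {
    X <- matrix(rnorm(36 * C), 36, C)
    Y <- mobileCbamForward(X, c(6L, 6L), w)
    expect_equal(dim(Y), dim(X))
    cg <- attr(Y, "channelGate"); sg <- attr(Y, "spatialGate")
    expect_true(all(cg > 0 & cg < 1))
    expect_true(all(sg > 0 & sg < 1))
  }
})

test_that("multiplicative gating maps zero input to zero output", {
  w <- initMobileCbam(seed = 3L)
  Z <- mobileCbamForward(matrix(0, 64, 16), c(8L, 8L), w)
  expect_true(all(Z == 0))
})

test_that("spatially constant input collapses avg and max pooling", {
  # with shared branch weights, AvgPool = MaxPool implies
  # M_c = sigmoid(2 * DWConv(pooled descriptor))
  w <- initMobileCbam(seed = 4L)
  C <- 24L
  X <- matrix(rep(seq_len(C) / C, each = 16), 16, C)  # constant per channel
  Y <- mobileCbamForward(X, c(4L, 4L), w)
  cg <- attr(Y, "channelGate")
  branch <- function(desc) {
    k <- length(w$chDw)
    xp <- c(rep(0, 2), desc, rep(0, 2))
    z <- as.numeric(matrix(xp[outer(seq_len(C) - 1L, seq_len(k), "+")],
                           C, k) %*% w$chDw)
    w$chPw * (z + w$chDwB) + w$chPwB
  }
  expected <- 1 / (1 + exp(-2 * branch(seq_len(C) / C)))
  expect_equal(cg, expected, tolerance = 1e-12)
})

test_that("volume encoding is deterministic with a 256-d contract", {
  co <- fx_volcohort()
  m <- buildBackbone(backboneSpec("efficientnet-b0", numClasses = 3L,
                                  inputSize = 24L), seed = 5L)$model
  e1 <- encodeVolume(m, co$samples[[1]], nSlices = 3L)
  e2 <- encodeVolume(m, co$samples[[1]], nSlices = 3L)
  expect_length(e1, 256L)
  expect_identical(e1, e2)
  expect_error(encodeVolume(buildBackbone(backboneSpec("resnet-18"))$model,
                            co$samples[[1]]), "efficientnet")
})

test_that("stochastic depth is seeded: same seed same path, new seed new path", {
  co <- fx_volcohort()
  m <- buildBackbone(backboneSpec("efficientnet-b0", numClasses = 3L,
                                  inputSize = 24L,
                                  stochasticDepth = 0.5), seed = 5L)$model
  a <- encodeVolume(m, co$samples[[1]], nSlices = 2L, training = TRUE,
                    seed = 11L)
  b <- encodeVolume(m, co$samples[[1]], nSlices = 2L, training = TRUE,
                    seed = 11L)
  c3 <- encodeVolume(m, co$samples[[1]], nSlices = 2L, training = TRUE,
                     seed = 12L)
  expect_identical(a, b)
  expect_false(identical(a, c3))
})

test_that("volumetric mode encodes with the same 256-d contract", {
  co <- fx_volcohort()
  m <- buildBackbone(backboneSpec("efficientnet-b0", inputMode = "3d",
                                  numClasses = 3L, inputSize = 24L),
                     seed = 6L)$model
  e <- encodeVolume(m, co$samples[[2]])
  expect_length(e, 256L)
  expect_true(all(is.finite(e)))
})
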