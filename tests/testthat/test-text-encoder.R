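small_cfg <- function() encoderConfig(layers = 2L, hidden = 32L,
                                      heads = 4L, vocabSize = 40L,
                                      maxLen = 64L, intermediate = 64L)

test_that("tokenizer splits numerals and handles unknowns and empties", {
  v <- defaultVocab()
  ids <- tokenize("UPDRS total score is 34.", v)
  expect_equal(ids[1], match("[CLS]", v))
  expect_equal(ids[length(ids)], match("[SEP]", v))
  expect_true(match("3", v) %in% ids && match("4", v) %in% ids)
  expect_true(match("[UNK]", v) %in% tokenize("zorblat", v))
  expect_equal(length(tokenize("", v)), 2L)   # special tokens only
})

test_that("encoding is deterministic and dimension-faithful", {
  enc <- buildTextEncoder(small_cfg(), seed = 3L)
  txt <- serializeRecord(list(UPDRS = 34, Age = 67, MoCA = 3,
                              HY_stage = "2", Weight = 70))
  a <- encodeText(enc, txt)
  b <- encodeText(enc, txt)
  expect_identical(a$pooled, b$pooled)
  expect_equal(ncol(a$tokens), 32L)
  # default-width configuration pools to 768
  enc768 <- buildTextEncoder(encoderConfig(layers = 1L, vocabSize = 40L),
                             seed = 1L)
  expect_length(encodeText(enc768, "age is 5.")$pooled, 768L)
})

test_that("records differing in one clause encode differently", {
  enc <- buildTextEncoder(small_cfg(), seed = 3L)
  a <- encodeText(enc, serializeRecord(list(UPDRS = 34, Age = 67,
                                            MoCA = 3, HY_stage = "2",
                                            Weight = 70)))
  b <- encodeText(enc, serializeRecord(list(UPDRS = 34, Age = 67,
                                            MoCA = 8, HY_stage = "2",
                                            Weight = 70)))
  expect_gt(max(abs(a$pooled - b$pooled)), 1e-8)
})

test_that("zero-initialized adapters leave outputs bit-identical", {
  enc <- buildTextEncoder(small_cfg(), seed = 3L)
  adapted <- injectLora(enc, loraConfig(r = 4L), seed = 9L)$encoder
  txt <- "updrs total score is 12."
  expect_identical(encodeText(enc, txt)$pooled,
                   encodeText(adapted, txt)$pooled)
})

test_that("LoRA accounting matches the closed form and the 96% bound", {
  bert <- encoderConfig()          # 12 x 768 x 12 heads
  lora <- loraConfig(r = 8L, alpha = 16)
  expect_equal(countLoraParams(bert, lora),
               12L * 2L * (768L * 8L + 8L * 768L))
  expect_equal(countLoraParams(bert, lora), 294912L)
  total <- sum(countTextEncoderParams(bert))
  expect_gte(100 * (1 - countLoraParams(bert, lora) / total), 96)
  rep <- injectLora(buildTextEncoder(small_cfg(), seed = 1L),
                    loraConfig(r = 4L))$report
  expect_equal(rep@trainable,
               countLoraParams(small_cfg(), loraConfig(r = 4L)))
  expect_equal(rep@trainable + rep@frozen, rep@total)
  expect_error(injectLora(buildTextEncoder(small_cfg()),
                          loraConfig(r = 64L)), "rank")
})

test_that("merged adapters reproduce the adapted encoder", {
  enc <- buildTextEncoder(small_cfg(), seed = 3L)
  adapted <- injectLora(enc, loraConfig(r = 4L), seed = 9L)$encoder
  withr::with_seed(5, {
    for (l in 1:2) for (tg in c("query", "value")) {
      adapted$lora$adapters[[l]][[tg]]$B[] <- rnorm(4 * 32, 0, 0.05)
    }
  })
  txt <- serializeRecord(list(UPDRS = 55, Age = 71, MoCA = 6,
                              HY_stage = "3", Weight = 64))
  a <- encodeText(adapted, txt)$pooled
  m <- encodeText(mergeLora(adapted), txt)$pooled
  expect_false(identical(a, encodeText(enc, txt)$pooled))
  expect_lt(max(abs(a - m)), 1e-5)
})

test_that("training updates only the adapters, projection and head", {
  tf <- fx_tinyfit()
  model0 <- buildMultimodalModel(seed = 3L)
  trained <- tf$fit$model
  # frozen transformer base weights are bit-identical to initialization
  expect_identical(trained$enc$w, model0$enc$w)
  # adapters moved
  moved <- vapply(grep("lora_.*_B", names(trained$params), value = TRUE),
                  function(nm) max(abs(trained$params[[nm]] -
                                         model0$params[[nm]])), numeric(1))
  expect_gt(max(moved), 0)
})

test_that("the projection head is affine with the published count", {
  ph <- projectionHead(seed = 2L)
  expect_equal(projectionParams(ph), 768L * 256L + 256L)
  expect_equal(projectEmbedding(ph, rep(0, 768)), ph$b)
  withr::with_seed(8, {
    x <- rnorm(768); y <- rnorm(768)
  })
  lhs <- projectEmbedding(ph, x) + projectEmbedding(ph, y) -
    projectEmbedding(ph, x + y)
  expect_lt(max(abs(lhs - ph$b)), 1e-5)
  expect_error(projectEmbedding(ph, rnorm(10)), "length-768")
})

test_that("vocabulary files load from disk", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(defaultVocab(), path)
  expect_identical(loadVocab(path), defaultVocab())
})
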