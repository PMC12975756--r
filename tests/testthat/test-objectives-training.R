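test_that("focal loss reduces to cross-entropy and matches hand values", {
  withr::with_seed(1, {
    logit <- matrix(rnorm(5 * 3), 5, 3)
    probs <- exp(logit) / rowSums(exp(logit))
    labels <- sample(0:2, 5, replace = TRUE)
  })
  ce <- -mean(log(probs[cbind(1:5, labels + 1)]))
  expect_equal(focalLoss(probs, labels, gamma = 0, epsilon = 0), ce,
               tolerance = 1e-7)
  # single sample at p_t = 0.9, gamma = 2
  p <- matrix(c(0.9, 0.06, 0.04), 1)
  expect_equal(focalLoss(p, 0L, gamma = 2, epsilon = 0),
               0.01 * -log(0.9), tolerance = 1e-9)
  expect_equal(focalLoss(p, 0L, gamma = 2, epsilon = 0), 1.0536e-3,
               tolerance = 1e-4)
  # perfectly confident correct prediction
  expect_lt(focalLoss(matrix(c(1, 0, 0), 1), 0L, gamma = 2, epsilon = 0),
            1e-10)
})

test_that("label smoothing spreads mass as specified", {
  t <- smoothTargets(0L, 3L, 0.1)
  expect_equal(t[1, 1], 1 - 0.1 + 0.1 / 3, tolerance = 1e-12)
  expect_equal(t[1, 2], 0.1 / 3, tolerance = 1e-12)
  expect_equal(sum(t), 1, tolerance = 1e-12)
})

test_that("triplet loss matches its hand cases", {
  # d(a,p) = 1, d(a,n) = 0.5, margin 0.3 -> 0.8
  a <- c(0, 0); p <- c(1, 0); n <- c(0.5, 0)
  expect_equal(tripletLoss(a, p, n, margin = 0.3), 0.8)
  # degenerate triplet collapses to the margin
  expect_equal(tripletLoss(a, a, a, margin = 0.3), 0.3)
  # inactive hinge
  expect_equal(tripletLoss(a, c(0.1, 0), c(5, 0), margin = 0.3), 0)
})

test_that("batch-hard mining picks extremes and rejects degenerate batches", {
  E <- rbind(c(0, 0), c(0.1, 0), c(3, 0), c(0, 4), c(0, 4.5))
  lab <- c(0, 0, 0, 1, 1)
  tri <- mineTriplets(E, lab)
  r1 <- tri[tri$anchor == 1, ]
  expect_equal(r1$positive, 3)   # hardest positive: farthest same class
  expect_equal(r1$negative, 4)   # hardest negative: closest other class
  expect_error(mineTriplets(E, rep(0, 5)), "degenerate")
})

test_that("consistency loss hits its geometric anchors", {
  u <- c(1, 0, 0)
  expect_equal(consistencyLoss(u, u), 0, tolerance = 1e-9)
  expect_equal(consistencyLoss(u, c(0, 1, 0)), 1, tolerance = 1e-9)
  expect_equal(consistencyLoss(u, -u), 2, tolerance = 1e-9)
})

test_that("mixup endpoints and Beta symmetry behave", {
  withr::with_seed(2, {
    X <- matrix(rnorm(8 * 4), 8, 4)
    Mt <- matrix(rnorm(8 * 2), 8, 2)
    tg <- smoothTargets(rep(0:1, 4), 3L, 0)
    m1 <- mixupBatch(X, Mt, tg, lambda = 1)
  })
  expect_equal(m1$images, X)
  expect_equal(m1$targets, tg)
  withr::with_seed(3, {
    m5 <- mixupBatch(X[1:2, ], Mt[1:2, ], smoothTargets(c(0L, 1L), 3L, 0),
                     lambda = 0.5)
  })
  if (m5$permutation[1] == 2L) {
    expect_equal(m5$targets[1, ], c(0.5, 0.5, 0))
  }
  withr::with_seed(4, l <- rbeta(1e5, 0.2, 0.2))
  expect_lt(abs(mean(l) - 0.5), 3 * sd(l) / sqrt(1e5))
})

test_that("the cosine schedule starts at lr0 and bottoms at etaMin", {
  expect_equal(cosineLR(0), 1e-4)
  expect_equal(cosineLR(50), 1e-6, tolerance = 1e-12)
  expect_equal(cosineLR(25), 1e-6 + 0.5 * (1e-4 - 1e-6), tolerance = 1e-9)
  expect_true(all(diff(vapply(0:50, cosineLR, numeric(1))) < 0))
})

test_that("subject-level splits are disjoint, stratified, and scan-coherent", {
  labels <- rep(0:2, c(40, 30, 30))
  ids <- sprintf("s%03d", 1:100)
  plan <- makeSplit(ids, labels, seed = 5L)
  held <- names(plan@assignment)[plan@assignment == "heldout"]
  expect_equal(unname(table(labels[match(held, ids)])), c(8L, 6L, 6L),
               ignore_attr = TRUE)
  # no subject in more than one partition or fold
  expect_equal(sum(duplicated(names(plan@assignment))), 0L)
  dev <- setdiff(ids, held)
  expect_setequal(names(plan@fold), dev)
  # deterministic under the seed
  expect_identical(plan@assignment, makeSplit(ids, labels, 5L)@assignment)
  # repeat scans co-locate with their subject
  scans <- rep(ids, each = 3)
  assign <- scanAssignment(plan, scans)
  bysub <- tapply(assign, scans, function(v) length(unique(v)))
  expect_true(all(bysub == 1L))
  expect_error(makeSplit(ids[1:12], rep(0:2, 4), seed = 1L),
               "stratification")
})

test_that("metrics match hand arithmetic and ignore sample order", {
  truth <- rep(0:2, each = 10)
  conf <- rbind(c(8, 2, 0), c(1, 9, 0), c(0, 0, 10))
  probs <- matrix(0, 30, 3)
  k <- 1
  for (tr in 1:3) for (pr in 1:3) {
    times <- conf[tr, pr]
    if (times > 0) for (i in seq_len(times)) {
      probs[k, ] <- 0.1; probs[k, pr] <- 0.8
      k <- k + 1
    }
  }
  rep1 <- metricsReport(truth, probs)
  expect_equal(rep1$accuracy, 27 / 30)
  expect_equal(unname(rep1$confusion), conf, ignore_attr = TRUE)
  expect_equal(rep1$perClass$precision[1], 8 / 9)
  perm <- sample(30)
  rep2 <- metricsReport(truth[perm], probs[perm, ])
  expect_equal(rep1$accuracy, rep2$accuracy)
  expect_equal(rep1$confusion, rep2$confusion)
  # perfect predictions
  p3 <- matrix(0.05, 30, 3)
  p3[cbind(1:30, truth + 1)] <- 0.9
  rep3 <- metricsReport(truth, p3)
  expect_equal(rep3$accuracy, 1)
  expect_equal(rep3$perClass$recall, rep(1, 3))
  expect_equal(rep3$perClass$auc, rep(1, 3))
  # an absent class reports NA, not zero
  rep4 <- metricsReport(rep(0:1, each = 5),
                        matrix(rep(c(0.8, 0.1, 0.1), 10), 10, 3,
                               byrow = TRUE))
  expect_true(is.na(rep4$perClass$recall[3]))
})

test_that("loss composition is linear in its component weights", {
  tf <- fx_tinyfit()
  subs <- tf$subs[1:8]
  ns <- asNamespace("NeuroFusion")
  full <- ns$mm_batch_loss(tf$fit$model, subs, lossConfig())
  onlyF <- ns$mm_batch_loss(tf$fit$model, subs,
                            lossConfig(lambdaTriplet = 0, lambdaCons = 0))
  expect_equal(onlyF$loss$val, onlyF$focal$val, tolerance = 1e-12)
  expect_equal(full$loss$val,
               full$focal$val + 0.5 * full$triplet$val +
                 0.5 * full$cons$val, tolerance = 1e-10)
})

test_that("early stopping fires exactly patience epochs after the best", {
  tf <- fx_tinyfit()
  subs <- tf$subs[1:14]
  model <- buildMultimodalModel(seed = 8L)
  # a vanishing learning rate freezes the validation focal loss, so the
  # best epoch stays at 1 and training halts at 1 + patience
  plan <- makeSplit(vapply(subs, `[[`, character(1), "subjectId"),
                    vapply(subs, `[[`, integer(1), "label"),
                    seed = 3L, heldoutFrac = 0, nFolds = 2L)
  fit <- trainModel(model, subs, plan,
                    trainConfig(epochs = 12L, patience = 3L, lr = 1e-15,
                                etaMin = 1e-16,
                                augment = FALSE, mixup = FALSE, seed = 2L),
                    lossConfig())
  expect_equal(fit$bestEpoch, 1L)
  expect_equal(fit$stoppedEpoch, 1L + 3L)
  expect_equal(nrow(fit$history), 4L)
})

test_that("held-out labels cannot influence training", {
  tf <- fx_tinyfit()
  subsA <- tf$subs
  subsB <- lapply(tf$subs, function(s) s)
  held <- names(tf$plan@assignment)[tf$plan@assignment == "heldout"]
  for (i in seq_along(subsB)) {
    if (subsB[[i]]$subjectId %in% held)
      subsB[[i]]$label <- (subsB[[i]]$label + 1L) %% 3L
  }
  cfg <- trainConfig(epochs = 2L, seed = 9L, augment = FALSE,
                     mixup = FALSE)
  m0 <- buildMultimodalModel(seed = 4L)
  fitA <- trainModel(m0, subsA, tf$plan, cfg, lossConfig())
  fitB <- trainModel(m0, subsB, tf$plan, cfg, lossConfig())
  expect_identical(fitA$model$params, fitB$model$params)
})

test_that("training history logs every loss component and is seeded", {
  tf <- fx_tinyfit()
  h <- tf$fit$history
  expect_true(all(c("focal", "triplet", "consistency", "total",
                    "valFocal", "trainAccuracy", "lr") %in% names(h)))
  expect_true(all(is.finite(h$total)))
  # loss decreases over training
  expect_lt(mean(tail(h$total, 3)), mean(head(h$total, 3)))
})
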