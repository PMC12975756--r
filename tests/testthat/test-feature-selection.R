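test_that("dependence estimator honours its analytic anchors", {
  set.seed(4)
  x <- rnorm(1000)
  expect_equal(dependence(x, x, mode = "nmi"), 1.0, tolerance = 1e-9)
  expect_lt(dependence(rnorm(5000), rnorm(5000), mode = "nmi"), 0.05)
  expect_warning(v <- dependence(rep(1, 100), rnorm(100), mode = "nmi"),
                 "constant")
  expect_equal(v, 0)
  expect_gte(dependence(x, x, mode = "mi"), 0)
  expect_error(dependence(x[1:5], x[1:5], bins = 10L))
})

test_that("inverse-rank aggregation matches hand arithmetic and normalizes", {
  fx <- generateWorkedRankingFixture()
  agg <- aggregateRanks(fx$ranks, fx$weights)
  expect_equal(unname(agg$V["featB"]), 1.75)
  expect_equal(sum(agg$S), 1, tolerance = 1e-12)
  # weight scale invariance of the normalized score
  agg10 <- aggregateRanks(fx$ranks, fx$weights * 10)
  expect_equal(agg$S, agg10$S, tolerance = 1e-12)
})

test_that("stage 1 validates its preconditions", {
  p <- fx_planted()
  cfg <- list(rankerConfig("random-forest"),
              rankerConfig("gradient-boosting-xgb-style"))
  expect_error(rankStage1(p$M[1:20, ], rep(1L, 20), cfg), "2 classes")
  expect_error(rankStage1(p$M, p$labels, cfg[1]), "2 rankers")
})

test_that("stage 1 ranks planted signal above noise", {
  a <- fx_audit()
  ranks <- a@ranks
  signal <- c(informative5, grep("_dup", rownames(ranks), value = TRUE))
  noise <- grep("noise_", rownames(ranks), value = TRUE)
  # the impurity-based forest separates every planted column from noise
  expect_lt(max(ranks[signal, "random-forest"]),
            min(ranks[noise, "random-forest"]))
  # each ranker produces a complete rank permutation
  for (m in colnames(ranks))
    expect_setequal(ranks[, m], seq_len(nrow(ranks)))
  # the five informative sources survive the majority vote
  expect_true(all(informative5 %in% a@stage1Survivors))
  expect_equal(sum(a@scoreS), 1, tolerance = 1e-9)
})

test_that("stage 2 removes exactly one member of duplicated pairs", {
  p <- fx_planted()
  a <- fx_audit()
  # every removal pairs a planted duplicate with its source family
  expect_true(all(grepl("_dup", a@removals$removed)))
  expect_true(all(a@removals$value > 0.8))
  expect_false(any(grepl("_dup", a@stage2Survivors)))
  expect_true(all(a@stage2Survivors %in% a@stage1Survivors))
  # a removed feature appears in exactly one removal event
  expect_false(anyDuplicated(a@removals$removed) > 0)
})

test_that("an NMI threshold of 1 removes nothing", {
  p <- fx_planted()
  cfgs <- list(rankerConfig("random-forest", seed = 1L),
               rankerConfig("gradient-boosting-xgb-style", seed = 2L))
  cols <- c(informative5, "noise_01", "noise_02")
  a <- rankStage1(p$M[, cols], p$labels, cfgs, "majority_top50")
  a1 <- pruneStage2(a, p$M[, cols], p$labels, threshold = 1.0,
                    mode = "nmi")
  expect_equal(nrow(a1@removals), 0L)
  expect_setequal(a1@stage2Survivors, a1@stage1Survivors)
  expect_error(pruneStage2(a, p$M[, cols], p$labels, threshold = 1.5,
                           mode = "nmi"), "threshold")
})

test_that("an exact duplicate pair loses exactly one member", {
  p <- fx_planted()
  X <- cbind(p$M[, c("UPDRS", "MoCA")], UPDRS_copy = p$M[, "UPDRS"])
  cfgs <- list(rankerConfig("random-forest", seed = 1L),
               rankerConfig("gradient-boosting-xgb-style", seed = 2L))
  # inverse-rank survival keeps the whole small feature set in play so the
  # check isolates the stage-2 rule
  a <- rankStage1(X, p$labels, cfgs, "inverse_rank_top10")
  a2 <- pruneStage2(a, X, p$labels, threshold = 0.8, mode = "nmi")
  pair <- c("UPDRS", "UPDRS_copy")
  expect_equal(sum(pair %in% a2@stage2Survivors), 1L)
  expect_equal(nrow(a2@removals), 1L)
})

test_that("Shapley symmetry holds for byte-identical duplicates under the conditional surrogate", {
  p <- fx_planted()
  X <- cbind(p$M[, c("UPDRS", "MoCA")], UPDRS_copy = p$M[, "UPDRS"])
  phi <- meanAbsShapley(X, p$labels, mode = "exact_enumeration",
                        surrogate = "conditional", nExplain = 25L,
                        nBackground = 120L, seed = 11L)
  rel <- abs(phi["UPDRS"] - phi["UPDRS_copy"]) /
    max(phi["UPDRS"], phi["UPDRS_copy"])
  expect_lt(rel, 0.25)
})

test_that("a pure-noise feature falls below the Shapley gate", {
  a <- fx_audit()
  p <- fx_planted()
  X <- p$M[, c(informative5, "noise_03")]
  audit <- new("SelectionAudit", ranks = matrix(1, 1, 1),
               weights = 1, scoreV = 1, scoreS = 1,
               stage1Survivors = colnames(X),
               dependence = data.frame(), removals = data.frame(),
               stage2Survivors = colnames(X), shapValues = numeric(),
               selected = character(), profile = "paper-4.2",
               seeds = integer())
  out <- validateStage3(audit, X, p$labels, seed = 7L)
  expect_lt(out@shapValues["noise_03"], 0.01)
  expect_false("noise_03" %in% out@selected)
  expect_true(all(informative5 %in% out@selected))
})

test_that("sampling Shapley agrees with exact enumeration within 10%", {
  p <- fx_planted()
  X <- p$M[, c(informative5, "UPDRS_dup1", "noise_01", "noise_02")]
  model <- NeuroFusion:::fit_shap_model(X, p$labels, seed = 7L)
  exact <- meanAbsShapley(X, p$labels, mode = "exact_enumeration",
                          nExplain = 20L, seed = 7L, model = model)
  samp <- meanAbsShapley(X, p$labels, mode = "sampling",
                         nPermutations = 2000L, nExplain = 20L, seed = 7L,
                         model = model)
  big <- exact > 0.02          # relative agreement on material features
  expect_true(any(big))
  expect_lt(max(abs(exact[big] - samp[big]) / exact[big]), 0.10)
})

test_that("exact enumeration is refused beyond 15 features", {
  p <- fx_planted()
  audit <- new("SelectionAudit", ranks = matrix(1, 1, 1), weights = 1,
               scoreV = 1, scoreS = 1, stage1Survivors = colnames(p$M),
               dependence = data.frame(), removals = data.frame(),
               stage2Survivors = colnames(p$M), shapValues = numeric(),
               selected = character(), profile = "paper-4.2",
               seeds = integer())
  expect_error(validateStage3(audit, p$M, p$labels,
                              estimator_mode = "exact_enumeration"),
               "sampling")
})

test_that("the full pipeline recovers exactly the planted informative set", {
  a <- fx_audit()
  expect_setequal(a@selected, informative5)
  # stage ordering is enforced
  expect_true(all(a@selected %in% a@stage2Survivors))
  expect_true(all(a@stage2Survivors %in% a@stage1Survivors))
  expect_true(all(a@removals$removed %in% a@stage1Survivors))
})

test_that("the audit serializes to JSON with its full trail", {
  a <- fx_audit()
  path <- withr::local_tempfile(fileext = ".json")
  writeAudit(a, path)
  j <- jsonlite::read_json(path)
  expect_equal(unlist(j$selected), a@selected)
  expect_length(j$removals, nrow(a@removals))
  expect_equal(sum(unlist(j$score_S)), 1, tolerance = 1e-9)
})

test_that("the alternative profile runs with raw-MI pruning", {
  p <- fx_planted()
  a <- selectFeatures(p$M[, c(informative5, "UPDRS_dup1", "noise_01",
                              "noise_02", "noise_03")],
                      p$labels, profile = "paper-3.5", seed = 2L,
                      nExplain = 15L)
  expect_s4_class(a, "SelectionAudit")
  expect_equal(ncol(a@ranks), 5L)        # five rankers
  expect_lte(length(a@stage1Survivors), 10L)
  expect_true(all(informative5 %in% a@selected))
})
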