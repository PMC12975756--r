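#' Configure one stage-1 importance ranker
#'
#' @param family one of "random-forest", "gradient-boosting-xgb-style",
#'   "gradient-boosting-lgb-style", "extra-trees", "adaboost".
#' @param params named list of hyperparameters (trees, depth, learning rate,
#'   leaves, estimators as applicable; defaults follow the published
#'   configurations: RF 500 trees / depth 10 / Gini, XGB lr 0.1 / depth 6 /
#'   300 rounds / gain, LGB-style 31 leaves / lr 0.05 / 400 rounds / gain).
#' @param weight aggregation weight \eqn{w_m > 0}.
#' @param seed ranker seed.
#' @return a "rankerConfig" list.
#' @export
rankerConfig <- function(family = c("random-forest",
                                    "gradient-boosting-xgb-style",
                                    "gradient-boosting-lgb-style",
                                    "extra-trees", "adaboost"),
                         params = list(), weight = 1, seed = 1L) {
  family <- match.arg(family)
  if (weight <= 0) stopf("ranker weight must be positive")
  defaults <- switch(family,
    "random-forest" = list(trees = 500L, depth = 10L, metric = "gini"),
    "gradient-boosting-xgb-style" =
      list(eta = 0.1, depth = 6L, rounds = 300L, metric = "gain"),
    "gradient-boosting-lgb-style" =
      list(leaves = 31L, eta = 0.05, rounds = 400L, metric = "gain"),
    "extra-trees" = list(trees = 500L, depth = 10L, metric = "gini"),
    "adaboost" = list(estimators = 100L, metric = "gain"))
  p <- utils::modifyList(defaults, params)
  structure(list(family = family, params = p, weight = weight,
                 seed = as.integer(seed)), class = "rankerConfig")
}

default_rankers <- function(profile, seed) {
  base <- list(
    rankerConfig("random-forest", seed = derive_seed(seed, "rf")),
    rankerConfig("gradient-boosting-xgb-style",
                 seed = derive_seed(seed, "xgb")),
    rankerConfig("gradient-boosting-lgb-style",
                 seed = derive_seed(seed, "lgb")))
  if (profile == "paper-3.5") {
    base <- c(base, list(
      rankerConfig("extra-trees", seed = derive_seed(seed, "et")),
      rankerConfig("adaboost", seed = derive_seed(seed, "ada"))))
  }
  base
}

ranker_importance <- function(cfg, X, y) {
  feat <- colnames(X)
  p <- cfg$params
  imp <- switch(cfg$family,
    "random-forest" = ,
    "extra-trees" = {
      fit <- ranger::ranger(
        x = as.data.frame(X), y = factor(y),
        num.trees = p$trees, max.depth = p$depth,
        importance = "impurity",
        splitrule = if (cfg$family == "extra-trees") "extratrees" else "gini",
        seed = cfg$seed, num.threads = 1L)
      fit$variable.importance
    },
    "gradient-boosting-xgb-style" = ,
    "gradient-boosting-lgb-style" = {
      # Per-tree feature subsampling decorrelates near-duplicate columns:
      # without it, greedy boosting funnels all gain into one member of a
      # duplicated pair and the ensemble vote cannot see the other.
      pars <- list(objective = "multi:softprob",
                   num_class = length(unique(y)),
                   eta = p$eta, colsample_bytree = 0.8,
                   nthread = 1L, verbosity = 0)
      if (cfg$family == "gradient-boosting-xgb-style") {
        pars$max_depth <- p$depth
      } else {
        # leaf-wise growth with a leaf cap, the LightGBM-style configuration
        pars$grow_policy <- "lossguide"
        pars$max_leaves <- p$leaves
        pars$max_depth <- 0L
        pars$tree_method <- "hist"
      }
      dtr <- xgboost::xgb.DMatrix(X, label = as.integer(y))
      fit <- with_seed(cfg$seed,
        xgboost::xgb.train(params = pars, data = dtr, nrounds = p$rounds,
                           verbose = 0))
      tab <- xgboost::xgb.importance(model = fit)
      setNames(tab$Gain, tab$Feature)
    },
    "adaboost" = adaboost_importance(X, y, p$estimators, cfg$seed))
  out <- setNames(rep(0, length(feat)), feat)
  shared <- intersect(names(imp), feat)
  out[shared] <- imp[shared]
  out
}

# SAMME AdaBoost on decision stumps (rpart, maxdepth 1); feature importance
# is the alpha-weighted sum of each stump's split improvement.
adaboost_importance <- function(X, y, nEstimators, seed) {
  y <- factor(y)
  K <- nlevels(y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  imp <- setNames(rep(0, ncol(X)), colnames(X))
  df <- data.frame(.y = y, X, check.names = FALSE)
  with_seed(seed, {
    for (t in seq_len(nEstimators)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 1, cp = 0, minsplit = 2,
                            xval = 0))
      pred <- predict(fit, df, type = "class")
      err <- sum(w * (pred != y)) / sum(w)
      if (err >= 1 - 1 / K || is.na(err)) break
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err) + log(K - 1)
      vi <- fit$variable.importance
      if (!is.null(vi)) {
        shared <- intersect(names(vi), names(imp))
        imp[shared] <- imp[shared] + alpha * vi[shared] / sum(vi)
      }
      w <- w * exp(alpha * (pred != y))
      w <- w / sum(w)
      if (err < 1e-9) break
    }
  })
  imp
}

#' Aggregate raw importances into ranks and inverse-rank scores
#'
#' Implements the weighted inverse-rank aggregation
#' \eqn{V_f = \sum_m w_m / r_{f,m}} and its normalization
#' \eqn{S_f = V_f / \sum_{f'} V_{f'}}. Rank ties are broken by importance
#' value then feature name order.
#'
#' @param ranks features x rankers matrix of ranks (1 = most important).
#' @param weights per-ranker weights.
#' @return list with \code{V} and \code{S} (named by feature).
#' @export
aggregateRanks <- function(ranks, weights) {
  stopifnot(ncol(ranks) == length(weights))
  V <- rowSums(sweep(1 / ranks, 2, weights, "*"))
  S <- V / sum(V)
  list(V = setNames(V, rownames(ranks)), S = setNames(S, rownames(ranks)))
}

#' Stage 1: ensemble importance ranking
#'
#' Each configured ranker produces a rank permutation over features
#' (1 = most important; ties broken by importance value then name order).
#' Under \code{profile = "inverse_rank_top10"} the weighted inverse-rank
#' scores are aggregated and the top 10 features by normalized score
#' survive. Under \code{"majority_top50"} a feature survives iff it lies in
#' the top 50\% of at least two rankers.
#'
#' @param X fully numeric feature matrix (post-preprocessing).
#' @param y class labels (>= 2 classes).
#' @param configs list of \code{\link{rankerConfig}}s (>= 2).
#' @param profile survivor rule.
#' @return a partially filled \code{\linkS4class{SelectionAudit}}.
#' @export
rankStage1 <- function(X, y, configs,
                       profile = c("majority_top50", "inverse_rank_top10")) {
  profile <- match.arg(profile)
  if (length(unique(y)) < 2L) stopf("y must have at least 2 classes")
  if (length(configs) < 2L) stopf("at least 2 rankers required")
  feat <- colnames(X)
  ranks <- matrix(NA_real_, nrow = length(feat), ncol = length(configs),
                  dimnames = list(feat, vapply(configs, `[[`, "", "family")))
  for (m in seq_along(configs)) {
    imp <- ranker_importance(configs[[m]], X, y)
    ord <- order(-imp, feat)        # ties: importance then name order
    ranks[ord, m] <- seq_along(feat)
  }
  weights <- vapply(configs, `[[`, numeric(1), "weight")
  agg <- aggregateRanks(ranks, weights)
  survivors <- if (profile == "inverse_rank_top10") {
    names(sort(agg$S, decreasing = TRUE))[seq_len(min(10L, length(feat)))]
  } else {
    cutoff <- ceiling(length(feat) / 2)
    votes <- rowSums(ranks <= cutoff)
    feat[votes >= 2L]
  }
  new("SelectionAudit",
      ranks = ranks, weights = weights, scoreV = agg$V, scoreS = agg$S,
      stage1Survivors = survivors,
      dependence = data.frame(fi = character(), fj = character(),
                              value = numeric()),
      removals = data.frame(kept = character(), removed = character(),
                            value = numeric(), threshold = numeric()),
      stage2Survivors = character(), shapValues = numeric(),
      selected = character(), profile = profile,
      seeds = vapply(configs, `[[`, integer(1), "seed"))
}

#' Stage 2: dependence-based redundancy pruning
#'
#' Stage-1 survivors are scanned in descending stage-1 score. When a pair's
#' dependence exceeds the threshold, one member is removed: under
#' \code{tie_rule = "lower_rank"} the lower-ranked feature, under
#' \code{"lower_target_mi"} the one with lower mutual information with the
#' target. Every removal is logged with the offending value and threshold.
#'
#' @param audit stage-1 \code{\linkS4class{SelectionAudit}}.
#' @param X feature matrix (columns cover the survivors).
#' @param y target labels (needed for the \code{lower_target_mi} rule).
#' @param threshold redundancy threshold; must lie in (0, 1] for NMI mode.
#' @param mode "nmi" (Eq.-style normalized MI) or "mi" (raw, scale-sensitive).
#' @param tie_rule which member of a redundant pair to drop.
#' @param bins equal-frequency bin count for the estimator.
#' @return the audit with stage-2 fields filled.
#' @export
pruneStage2 <- function(audit, X, y = NULL, threshold = 0.8,
                        mode = c("nmi", "mi"),
                        tie_rule = c("lower_target_mi", "lower_rank"),
                        bins = 10L) {
  mode <- match.arg(mode)
  tie_rule <- match.arg(tie_rule)
  if (mode == "nmi" && (threshold <= 0 || threshold > 1))
    stopf("NMI threshold must lie in (0, 1]")
  if (tie_rule == "lower_target_mi" && is.null(y))
    stopf("tie_rule 'lower_target_mi' requires y")
  ordered <- audit@stage1Survivors[
    order(-audit@scoreS[audit@stage1Survivors])]
  kept <- character()
  dep <- list(); rem <- list()
  targetMI <- function(f) dependence(X[, f], y, mode = "mi", bins = bins)
  for (f in ordered) {
    clash <- NULL
    for (g in kept) {
      v <- dependence(X[, g], X[, f], mode = mode, bins = bins)
      dep[[length(dep) + 1L]] <- data.frame(fi = g, fj = f, value = v)
      if (v > threshold) { clash <- list(g = g, value = v); break }
    }
    if (is.null(clash)) {
      kept <- c(kept, f)
    } else if (tie_rule == "lower_rank" ||
               targetMI(f) < targetMI(clash$g)) {
      rem[[length(rem) + 1L]] <- data.frame(
        kept = clash$g, removed = f, value = clash$value,
        threshold = threshold)
    } else {
      rem[[length(rem) + 1L]] <- data.frame(
        kept = f, removed = clash$g, value = clash$value,
        threshold = threshold)
      kept <- c(setdiff(kept, clash$g), f)
    }
  }
  audit@dependence <- if (length(dep)) do.call(rbind, dep) else
    audit@dependence
  audit@removals <- if (length(rem)) do.call(rbind, rem) else audit@removals
  audit@stage2Survivors <- kept
  validObject(audit)
  audit
}

#' Stage 3: Shapley validation of surviving features
#'
#' Fits a gradient-boosted classifier on the survivors and computes each
#' feature's mean absolute Shapley value for the predicted probability of a
#' sample's true class, using an interventional value function (features
#' outside the coalition are drawn from a background sample). Exact mode
#' enumerates all \eqn{2^d} coalitions (d <= 15); sampling mode uses
#' Monte-Carlo permutation walks with a recorded seed. Features with mean
#' |Shapley| below \code{shap_threshold} are dropped and the rest ranked.
#'
#' @param audit stage-2 \code{\linkS4class{SelectionAudit}}.
#' @param X feature matrix.
#' @param y class labels.
#' @param shap_threshold exclusion gate (default 0.01).
#' @param estimator_mode "exact_enumeration" or "sampling".
#' @param nPermutations Monte-Carlo permutations in sampling mode.
#' @param nExplain,nBackground number of explained / background rows.
#' @param seed RNG seed (recorded in the audit).
#' @return the completed audit.
#' @export
validateStage3 <- function(audit, X, y, shap_threshold = 0.01,
                           estimator_mode = c("exact_enumeration",
                                              "sampling"),
                           nPermutations = 2000L, nExplain = 30L,
                           nBackground = 25L, seed = 7L) {
  estimator_mode <- match.arg(estimator_mode)
  survivors <- audit@stage2Survivors
  if (!length(survivors)) stopf("no surviving features to validate")
  d <- length(survivors)
  if (estimator_mode == "exact_enumeration" && d > 15L)
    stopf(paste("exact enumeration of 2^%d coalitions refused for d = %d;",
                "use estimator_mode = 'sampling'"), d, d)
  phi <- meanAbsShapley(X[, survivors, drop = FALSE], y,
                        mode = estimator_mode,
                        nPermutations = nPermutations,
                        nExplain = nExplain, nBackground = nBackground,
                        seed = seed)
  keep <- names(phi)[phi >= shap_threshold]
  audit@shapValues <- phi
  audit@selected <- keep[order(-phi[keep])]
  audit@seeds <- c(audit@seeds, shap = as.integer(seed))
  validObject(audit)
  audit
}

#' Run the full three-stage selection pipeline
#'
#' @param X numeric feature matrix.
#' @param y class labels.
#' @param profile "paper-4.2" style (3 rankers, top-50\% majority voting,
#'   NMI > 0.8, lower-target-MI tie rule, SHAP < 0.01; the default because
#'   its threshold is bounded and its hyperparameters fully determined) or
#'   "paper-3.5" style (5 rankers, weighted inverse-rank top 10, raw
#'   MI > 0.85 — scale-sensitive — lower-rank tie rule).
#' @param seed master seed; per-ranker seeds derive from it.
#' @param ... passed to \code{\link{validateStage3}}.
#' @return a completed \code{\linkS4class{SelectionAudit}}.
#' @export
selectFeatures <- function(X, y, profile = c("paper-4.2", "paper-3.5"),
                           seed = 1L, ...) {
  profile <- match.arg(profile)
  configs <- default_rankers(profile, seed)
  if (profile == "paper-4.2") {
    a <- rankStage1(X, y, configs, profile = "majority_top50")
    a <- pruneStage2(a, X, y, threshold = 0.8, mode = "nmi",
                     tie_rule = "lower_target_mi")
  } else {
    a <- rankStage1(X, y, configs, profile = "inverse_rank_top10")
    a <- pruneStage2(a, X, y, threshold = 0.85, mode = "mi",
                     tie_rule = "lower_rank")
  }
  a@profile <- profile
  validateStage3(a, X, y, seed = derive_seed(seed, "shap"), ...)
}

#' Export a selection audit as JSON
#'
#' @param audit a \code{\linkS4class{SelectionAudit}}.
#' @param path output file.
#' @export
writeAudit <- function(audit, path) {
  jsonlite::write_json(list(
    profile = audit@profile,
    ranks = as.data.frame(audit@ranks),
    weights = audit@weights,
    score_V = as.list(audit@scoreV),
    score_S = as.list(audit@scoreS),
    stage1_survivors = audit@stage1Survivors,
    dependence = audit@dependence,
    removals = audit@removals,
    stage2_survivors = audit@stage2Survivors,
    shap_values = as.list(audit@shapValues),
    selected = audit@selected,
    seeds = as.list(audit@seeds)), path, auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}
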