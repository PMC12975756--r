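#' Training configuration
#'
#' Defaults follow the published recipe: AdamW-style decoupled weight
#' decay, learning rate 1e-4 under cosine annealing (T_max 50, eta_min
#' 1e-6), weight decay 1e-5, dropout 0.5 on the classifier, stochastic
#' depth 0.2, mixup alpha 0.2 (images) / 0.1 (metadata), early stopping
#' with patience 20 on validation focal loss.
#'
#' @param lr,tMax,etaMin cosine schedule parameters.
#' @param weightDecay decoupled L2 coefficient.
#' @param dropout classifier dropout probability.
#' @param stochasticDepth residual drop probability.
#' @param alphaImg,alphaMeta mixup Beta parameters per stream.
#' @param batchSize,epochs loop sizes.
#' @param patience early-stopping patience (epochs, >= 1).
#' @param clipNorm global gradient-norm clip (keeps the small-batch
#'   composite loss stable; set \code{Inf} to disable).
#' @param augment apply geometric/intensity augmentation to training
#'   images.
#' @param mixup apply mixup to the training image stream.
#' @param seed master seed.
#' @export
trainConfig <- function(lr = 1e-4, tMax = 50L, etaMin = 1e-6,
                        weightDecay = 1e-5, dropout = 0.5,
                        stochasticDepth = 0.2, alphaImg = 0.2,
                        alphaMeta = 0.1, batchSize = 16L, epochs = 50L,
                        patience = 20L, clipNorm = 1.0, augment = TRUE,
                        mixup = TRUE, seed = 1L) {
  stopifnot(patience >= 1L, lr > 0, etaMin > 0, weightDecay >= 0)
  structure(list(lr = lr, tMax = tMax, etaMin = etaMin,
                 weightDecay = weightDecay, dropout = dropout,
                 stochasticDepth = stochasticDepth, alphaImg = alphaImg,
                 alphaMeta = alphaMeta, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience), clipNorm = clipNorm,
                 augment = augment, mixup = mixup,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Subject-level stratified split: held-out set plus CV folds
#'
#' Subjects (not scans) are the unit of assignment, so every volume of a
#' subject shares its partition and no subject can appear on both sides of
#' a boundary. 20\% of subjects per class are reserved as the held-out
#' set; the remaining development subjects are assigned to stratified
#' folds. Deterministic under \code{seed}.
#'
#' @param subjectIds subject identifier per subject (unique).
#' @param labels class label per subject.
#' @param seed RNG seed.
#' @param heldoutFrac held-out fraction (default 0.2).
#' @param nFolds number of folds (default 5).
#' @return a \code{\linkS4class{SplitPlan}}.
#' @export
makeSplit <- function(subjectIds, labels, seed = 1L, heldoutFrac = 0.2,
                      nFolds = 5L) {
  stopifnot(length(subjectIds) == length(labels),
            !anyDuplicated(subjectIds))
  assignment <- setNames(rep("dev", length(subjectIds)), subjectIds)
  fold <- integer()
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      subj <- subjectIds[labels == cl]
      subj <- sample(subj)
      nHold <- round(heldoutFrac * length(subj))
      hold <- subj[seq_len(nHold)]
      dev <- setdiff(subj, hold)
      if (length(dev) < nFolds)
        stopf("stratification error: class %s has %d development subjects (< %d folds)",
              cl, length(dev), nFolds)
      assignment[hold] <- "heldout"
      fold <- c(fold, setNames(rep_len(seq_len(nFolds), length(dev)), dev))
    }
  })
  new("SplitPlan", assignment = assignment, fold = fold,
      strata = setNames(as.character(labels), subjectIds),
      nFolds = as.integer(nFolds))
}

#' Expand a subject-level plan to scans
#'
#' @param plan a \code{\linkS4class{SplitPlan}}.
#' @param scanSubjects subject id per scan.
#' @return character partition per scan.
#' @export
scanAssignment <- function(plan, scanSubjects) {
  unname(plan@assignment[scanSubjects])
}

# --- metrics --------------------------------------------------------------

rank_auc <- function(score, positive) {
  npos <- sum(positive); nneg <- sum(!positive)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Classification metrics from one prediction pass
#'
#' Per-class and macro precision/recall/F1, overall accuracy, K x K
#' confusion matrix, one-vs-rest AUC, and a 10-bin reliability table.
#' Classes absent from the truth get \code{NA} (undefined), not zero.
#' Metrics are invariant to sample order.
#'
#' @param truth integer labels in 0..K-1.
#' @param probs n x K predicted probability matrix.
#' @return list of metric components.
#' @export
metricsReport <- function(truth, probs) {
  probs <- as_mat(probs)
  K <- ncol(probs)
  pred <- max.col(probs, ties.method = "first") - 1L
  conf <- matrix(0L, K, K, dimnames = list(paste0("true", 0:(K - 1)),
                                           paste0("pred", 0:(K - 1))))
  for (i in seq_along(truth)) {
    conf[truth[i] + 1L, pred[i] + 1L] <- conf[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  perClass <- data.frame(class = 0:(K - 1), precision = NA_real_,
                         recall = NA_real_, f1 = NA_real_,
                         auc = NA_real_)
  for (k in seq_len(K)) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k]); fn <- sum(conf[k, -k])
    if (sum(conf[k, ]) > 0) {
      perClass$recall[k] <- tp / (tp + fn)
      perClass$precision[k] <- if (tp + fp > 0) tp / (tp + fp) else NA
      pr <- perClass$precision[k]; rc <- perClass$recall[k]
      perClass$f1[k] <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0)
        2 * pr * rc / (pr + rc) else NA
      perClass$auc[k] <- rank_auc(probs[, k], truth == (k - 1L))
    }
  }
  conf_pred <- probs[cbind(seq_along(truth), pred + 1L)]
  bins <- pmin(floor(conf_pred * 10) + 1L, 10L)
  rel <- data.frame(bin = 1:10,
                    meanConfidence = NA_real_, empiricalAccuracy = NA_real_,
                    n = tabulate(bins, 10))
  for (b in 1:10) {
    inb <- bins == b
    if (any(inb)) {
      rel$meanConfidence[b] <- mean(conf_pred[inb])
      rel$empiricalAccuracy[b] <- mean((pred == truth)[inb])
    }
  }
  list(accuracy = mean(pred == truth), confusion = conf,
       perClass = perClass,
       macroPrecision = mean(perClass$precision, na.rm = TRUE),
       macroRecall = mean(perClass$recall, na.rm = TRUE),
       macroF1 = mean(perClass$f1, na.rm = TRUE),
       reliability = rel)
}

# --- AdamW ----------------------------------------------------------------

# Decoupled-weight-decay Adam over a named list of parameter matrices.
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weightDecay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * weightDecay * params[[nm]]
  }
  list(params = params, state = state)
}
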