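#' Build the desk-scale trainable multimodal staging model
#'
#' A compact instantiation of the full architecture that trains on one
#' CPU: a small convolutional image branch over downsampled axial slices
#' (each slice becomes one 256-d token), the transformer text branch with
#' frozen base weights and trainable LoRA adapters feeding a trainable
#' 256-d projection, bidirectional multi-head cross-attention fusion with
#' a sigmoid gate, and a 3-class head. All trainable weights live in a
#' flat named list consumed by the AdamW optimizer; gradients flow through
#' the package's autodiff tape.
#'
#' @param imgSize working slice edge (slices are resized to this).
#' @param nSlices slices per volume (= image tokens).
#' @param convCh convolution channels of the image stem.
#' @param heads cross-attention heads (fixed mode).
#' @param textCfg \code{\link{encoderConfig}} for the text branch.
#' @param lora \code{\link{loraConfig}} for the adapters.
#' @param dim shared embedding dimension (256).
#' @param seed initialization seed.
#' @export
buildMultimodalModel <- function(imgSize = 16L, nSlices = 4L, convCh = 8L,
                                 heads = 4L,
                                 textCfg = encoderConfig(
                                   layers = 1L, hidden = 32L, heads = 4L,
                                   vocabSize = length(defaultVocab()),
                                   maxLen = 48L, intermediate = 64L),
                                 lora = loraConfig(r = 4L, alpha = 16),
                                 dim = 256L, seed = 1L) {
  enc <- buildTextEncoder(textCfg, seed = derive_seed(seed, "enc"))
  enc <- injectLora(enc, lora, seed = derive_seed(seed, "lora"))$encoder
  pooledDim <- (imgSize %/% 2L)^2 * convCh
  with_seed(seed, {
    mk <- function(nr, nc, s = sqrt(2 / nr)) matrix(rnorm(nr * nc, 0, s),
                                                    nr, nc)
    params <- list(
      convW = mk(9, convCh), convB = matrix(0, 1, convCh),
      imgW = mk(pooledDim, dim), imgB = matrix(0, 1, dim),
      txtW = mk(textCfg$hidden, dim), txtB = matrix(0, 1, dim),
      fq1 = mk(dim, dim, 0.05), fk1 = mk(dim, dim, 0.05),
      fv1 = mk(dim, dim, 0.05), fo1 = mk(dim, dim, 0.05),
      fq2 = mk(dim, dim, 0.05), fk2 = mk(dim, dim, 0.05),
      fv2 = mk(dim, dim, 0.05), fo2 = mk(dim, dim, 0.05),
      gateW = mk(2 * dim, dim, 0.02), gateB = matrix(0, 1, dim),
      clsW = mk(dim, 3L, 0.05), clsB = matrix(0, 1, 3L))
    for (l in seq_len(textCfg$layers)) {
      for (tg in lora$targets) {
        ad <- enc$lora$adapters[[l]][[tg]]
        params[[sprintf("lora_%d_%s_A", l, tg)]] <- ad$A
        params[[sprintf("lora_%d_%s_B", l, tg)]] <- ad$B
      }
    }
    structure(list(params = params, enc = enc, imgSize = as.integer(imgSize),
                   nSlices = as.integer(nSlices), convCh = as.integer(convCh),
                   heads = as.integer(heads), dim = as.integer(dim),
                   lora = lora,
                   convIdx = conv_indices(c(imgSize, imgSize), 3L, 1L),
                   poolMat = mean_pool_matrix(imgSize, 2L)),
              class = "multimodalModel")
  })
}

# Axial slice positions: a central window rather than the full extent,
# since skull-stripped spatially normalized brains carry the informative
# deep structures centrally and extreme slices are background.
slice_positions <- function(nz, nSlices, window = c(0.25, 0.75)) {
  unique(pmax(1L, pmin(nz, round(seq(window[1], window[2],
                                     length.out = nSlices) * nz))))
}

# block-averaging matrix for 2x2 mean pooling of a column-major s x s grid
mean_pool_matrix <- function(s, k = 2L) {
  so <- s %/% k
  P <- matrix(0, so * so, s * s)
  for (oy in seq_len(so)) for (ox in seq_len(so)) {
    o <- (oy - 1L) * so + ox
    for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
      ix <- (ox - 1L) * k + 1L + dx
      iy <- (oy - 1L) * k + 1L + dy
      P[o, (iy - 1L) * s + ix] <- 1 / (k * k)
    }
  }
  P
}

#' Prepare cohort subjects for the multimodal model
#'
#' Downsamples each subject's volume(s) to \code{nSlices} axial slices at
#' the model's working size and serializes the (imputed) clinical record
#' to token ids.
#'
#' @param cohort \code{\link{generateCohort}} output.
#' @param imputed an imputed \code{\linkS4class{ClinicalTable}} for the
#'   same subjects.
#' @param model a \code{\link{buildMultimodalModel}}.
#' @param template serialization template.
#' @param vocab tokenizer vocabulary.
#' @return list of subject inputs (slices, token ids, label, subjectId).
#' @export
prepareSubjects <- function(cohort, imputed, model,
                            template = defaultTemplate(),
                            vocab = defaultVocab()) {
  lapply(seq_along(cohort$samples), function(i) {
    s <- cohort$samples[[i]]
    zIdx <- slice_positions(dim(s@voxels)[3], model$nSlices)
    slices <- lapply(zIdx, function(z)
      resize_bilinear(s@voxels[, , z], model$imgSize, model$imgSize))
    row <- which(imputed@subjectIds == s@subjectId)[1]
    rec <- as.list(imputed@values[row, , drop = FALSE])
    list(slices = slices,
         ids = tokenize(serializeRecord(rec, template), vocab,
                        model$enc$cfg$maxLen),
         label = s@label, subjectId = s@subjectId)
  })
}

# parameter nodes (trainable) + frozen encoder nodes for one tape
mm_nodes <- function(tape, model) {
  pn <- lapply(model$params, function(p) adParam(tape, p))
  enc <- model$enc
  en <- list(tok = adConst(tape, enc$w$tok), pos = adConst(tape, enc$w$pos),
             lnEg = adConst(tape, matrix(enc$w$lnEg, 1)),
             lnEb = adConst(tape, matrix(enc$w$lnEb, 1)))
  en$layers <- lapply(enc$w$layers, function(lw)
    lapply(lw, function(v)
      if (is.matrix(v)) adConst(tape, v) else adConst(tape, matrix(v, 1))))
  en$adapters <- lapply(seq_along(enc$w$layers), function(l)
    setNames(lapply(model$lora$targets, function(tg) list(
      A = pn[[sprintf("lora_%d_%s_A", l, tg)]],
      B = pn[[sprintf("lora_%d_%s_B", l, tg)]])), model$lora$targets))
  list(pn = pn, en = en)
}

ad_cross_attend <- function(tape, Q0, K0, heads, Wq, Wk, Wv, Wo) {
  d <- ncol(Q0$val)
  dh <- d %/% heads
  Q <- adMatmul(tape, Q0, Wq)
  K <- adMatmul(tape, K0, Wk)
  V <- adMatmul(tape, K0, Wv)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    ci <- ((h - 1L) * dh + 1L):(h * dh)
    A <- adSoftmaxRows(tape, adScale(tape,
           adMatmul(tape, adCols(tape, Q, ci),
                    adTranspose(tape, adCols(tape, K, ci))), 1 / sqrt(dh)))
    outs[[h]] <- adMatmul(tape, A, adCols(tape, V, ci))
  }
  att <- outs[[1L]]
  if (heads > 1L) for (h in 2:heads) att <- adCbind(tape, att, outs[[h]])
  adMatmul(tape, att, Wo)
}

# forward one subject on an existing tape; returns nodes
mm_forward_one <- function(tape, model, nodes, subject, training = FALSE,
                           dropout = 0) {
  pn <- nodes$pn
  tokens <- vector("list", length(subject$slices))
  convActs <- vector("list", length(subject$slices))
  for (s in seq_along(subject$slices)) {
    sl <- subject$slices[[s]]
    patches <- adConst(tape, im2col(matrix(as.numeric(sl), ncol = 1),
                                    model$convIdx))
    act <- adRelu(tape, adAdd(tape, adMatmul(tape, patches, pn$convW),
                              pn$convB))
    convActs[[s]] <- act
    pooled <- adMatmul(tape, adConst(tape, model$poolMat), act)
    flat <- adReshape(tape, adTranspose(tape, pooled), 1L,
                      length(pooled$val))
    tokens[[s]] <- adRelu(tape, adAdd(tape, adMatmul(tape, flat, pn$imgW),
                                      pn$imgB))
  }
  imgTok <- adRbind(tape, tokens)
  encOut <- encoder_forward(tape, model$enc, subject$ids, nodes$en)
  txtTok <- adAdd(tape, adMatmul(tape, encOut$tokens, pn$txtW), pn$txtB)
  u <- adColMeans(tape, ad_cross_attend(tape, imgTok, txtTok, model$heads,
                                        pn$fq1, pn$fk1, pn$fv1, pn$fo1))
  v <- adColMeans(tape, ad_cross_attend(tape, txtTok, imgTok, model$heads,
                                        pn$fq2, pn$fk2, pn$fv2, pn$fo2))
  z <- adCbind(tape, u, v)
  g <- adSigmoid(tape, adAdd(tape, adMatmul(tape, z, pn$gateW), pn$gateB))
  oneMinusG <- adShift(tape, adScale(tape, g, -1), 1)
  fused <- adAdd(tape, adMul(tape, u, g), adMul(tape, v, oneMinusG))
  if (training && dropout > 0) {
    mask <- matrix(rbinom(model$dim, 1L, 1 - dropout) / (1 - dropout), 1)
    fused <- adMul(tape, fused, adConst(tape, mask))
  }
  logits <- adAdd(tape, adMatmul(tape, fused, pn$clsW), pn$clsB)
  list(logits = logits, probs = adSoftmaxRows(tape, logits), fused = fused,
       u = u, v = v, gate = g, convActs = convActs)
}

# focal term for one sample (nodes); target is a numeric 1xK vector
ad_focal_one <- function(tape, probs, target, gamma) {
  oneMinusP <- adShift(tape, adScale(tape, probs, -1), 1)
  w <- if (gamma == 0) NULL else adPow(tape, oneMinusP, gamma)
  lp <- adLog(tape, probs)
  inner <- if (is.null(w)) lp else adMul(tape, lp, w)
  adScale(tape, adSum(tape, adMul(tape, inner, adConst(tape, target))), -1)
}

ad_mean_of <- function(tape, nodes) {
  adMean(tape, adRbind(tape, nodes))
}

ad_dist <- function(tape, a, b) {
  adSqrt(tape, adRowSums(tape, adPow(tape, adSub(tape, a, b), 2)), 1e-12)
}

# batch forward + composite loss; returns tape, loss components, probs
mm_batch_loss <- function(model, batch, lossCfg, training = FALSE,
                          dropout = 0, targets = NULL) {
  tape <- adTape()
  nodes <- mm_nodes(tape, model)
  outs <- lapply(batch, function(sub)
    mm_forward_one(tape, model, nodes, sub, training, dropout))
  labels <- vapply(batch, `[[`, integer(1), "label")
  if (is.null(targets))
    targets <- smoothTargets(labels, lossCfg$nClasses, lossCfg$epsilon)
  focalN <- ad_mean_of(tape, lapply(seq_along(outs), function(i)
    ad_focal_one(tape, outs[[i]]$probs, targets[i, , drop = FALSE],
                 lossCfg$gamma)))
  E <- do.call(rbind, lapply(outs, function(o) o$fused$val))
  trip <- tryCatch(mineTriplets(E, labels), error = function(e) NULL)
  tripletN <- if (!is.null(trip) && lossCfg$lambdaTriplet > 0) {
    ad_mean_of(tape, lapply(seq_len(nrow(trip)), function(r) {
      a <- outs[[trip$anchor[r]]]$fused
      p <- outs[[trip$positive[r]]]$fused
      ng <- outs[[trip$negative[r]]]$fused
      adRelu(tape, adShift(tape,
        adSub(tape, ad_dist(tape, a, p), ad_dist(tape, a, ng)),
        lossCfg$margin))
    }))
  } else adConst(tape, matrix(0, 1, 1))
  consN <- if (lossCfg$lambdaCons > 0) {
    ad_mean_of(tape, lapply(outs, function(o) {
      nu <- adSqrt(tape, adRowSums(tape, adPow(tape, o$u, 2)), 1e-12)
      nv <- adSqrt(tape, adRowSums(tape, adPow(tape, o$v, 2)), 1e-12)
      dotuv <- adRowSums(tape, adMul(tape, o$u, o$v))
      adShift(tape, adScale(tape,
        adDiv(tape, dotuv, adMul(tape, nu, nv)), -1), 1)
    }))
  } else adConst(tape, matrix(0, 1, 1))
  loss <- adAdd(tape, adScale(tape, focalN, lossCfg$lambdaFocal),
                adAdd(tape, adScale(tape, tripletN, lossCfg$lambdaTriplet),
                      adScale(tape, consN, lossCfg$lambdaCons)))
  probs <- do.call(rbind, lapply(outs, function(o) o$probs$val))
  list(tape = tape, nodes = nodes, loss = loss, focal = focalN,
       triplet = tripletN, cons = consN, probs = probs, outs = outs)
}

#' Predict class probabilities for prepared subjects
#' @param model a trained \code{\link{buildMultimodalModel}}.
#' @param subjects prepared subject list.
#' @export
predictSubjects <- function(model, subjects) {
  do.call(rbind, lapply(subjects, function(sub) {
    tape <- adTape()
    nodes <- mm_nodes(tape, model)
    out <- mm_forward_one(tape, model, nodes, sub, training = FALSE)
    out$probs$val
  }))
}

#' Train the multimodal model
#'
#' AdamW with cosine-annealed learning rate on the composite loss
#' lambda_f focal + lambda_t triplet + lambda_c consistency; geometric/
#' intensity augmentation and mixup on training images only; early
#' stopping on validation focal loss with best-weight restoration; the
#' full component-loss history is logged per epoch. Deterministic under
#' the configuration seed.
#'
#' @param model a \code{\link{buildMultimodalModel}}.
#' @param subjects prepared subject list (\code{\link{prepareSubjects}}).
#' @param plan a \code{\linkS4class{SplitPlan}}; fold 1 is the validation
#'   fold, the remaining development folds train. When \code{NULL}, all
#'   subjects train and early stopping monitors training focal loss.
#' @param trainCfg a \code{\link{trainConfig}}.
#' @param lossCfg a \code{\link{lossConfig}}.
#' @param stopAtTrainAcc optionally stop once training accuracy reaches
#'   this level (overfit-capacity checks).
#' @return list with the trained \code{model}, \code{history} data.frame,
#'   \code{bestEpoch} and \code{stoppedEpoch}.
#' @export
trainModel <- function(model, subjects, plan = NULL,
                       trainCfg = trainConfig(), lossCfg = lossConfig(),
                       stopAtTrainAcc = NULL) {
  subjIds <- vapply(subjects, `[[`, character(1), "subjectId")
  if (!is.null(plan)) {
    part <- scanAssignment(plan, subjIds)
    trainIdx <- which(part == "dev" & plan@fold[subjIds] != 1L)
    valIdx <- which(part == "dev" & plan@fold[subjIds] == 1L)
  } else {
    trainIdx <- seq_along(subjects)
    valIdx <- integer()
  }
  params <- model$params
  state <- adamw_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  history <- list()
  stoppedEpoch <- trainCfg$epochs
  with_seed(trainCfg$seed, {
    for (epoch in seq_len(trainCfg$epochs)) {
      lr <- cosineLR(epoch - 1L, trainCfg$lr, trainCfg$tMax,
                     trainCfg$etaMin)
      ord <- sample(trainIdx)
      epochLoss <- c(focal = 0, triplet = 0, cons = 0, total = 0)
      nb <- 0L
      correct <- 0L
      model$params <- params
      for (b0 in seq(1, length(ord), by = trainCfg$batchSize)) {
        bidx <- ord[b0:min(b0 + trainCfg$batchSize - 1L, length(ord))]
        batch <- subjects[bidx]
        if (trainCfg$augment) {
          batch <- lapply(batch, function(sub) {
            sub$slices <- lapply(sub$slices, augmentSlice)
            sub
          })
        }
        targets <- NULL
        if (trainCfg$mixup && length(batch) >= 2L &&
            trainCfg$alphaImg > 0) {
          lab <- vapply(batch, `[[`, integer(1), "label")
          tg <- smoothTargets(lab, lossCfg$nClasses, lossCfg$epsilon)
          perm <- sample(length(batch))
          lam <- rbeta(length(batch), trainCfg$alphaImg, trainCfg$alphaImg)
          orig <- batch
          for (i in seq_along(batch)) {
            for (s in seq_along(batch[[i]]$slices)) {
              batch[[i]]$slices[[s]] <-
                lam[i] * orig[[i]]$slices[[s]] +
                (1 - lam[i]) * orig[[perm[i]]]$slices[[s]]
            }
            # the text branch receives the dominant component's record
            # (mixing serialized text is ill-defined), and the dominant
            # label drives triplet mining
            if (lam[i] < 0.5) {
              batch[[i]]$ids <- orig[[perm[i]]]$ids
              batch[[i]]$label <- orig[[perm[i]]]$label
            }
          }
          targets <- lam * tg + (1 - lam) * tg[perm, , drop = FALSE]
        }
        model$params <- params
        r <- mm_batch_loss(model, batch, lossCfg, training = TRUE,
                           dropout = trainCfg$dropout, targets = targets)
        if (!is.finite(r$loss$val)) {
          stopf("non-finite loss at epoch %d (focal %.4g, triplet %.4g, consistency %.4g)",
                epoch, r$focal$val, r$triplet$val, r$cons$val)
        }
        adBackward(r$tape, r$loss)
        grads <- lapply(r$nodes$pn, gradOf)
        if (is.finite(trainCfg$clipNorm)) {
          gn <- sqrt(sum(vapply(grads, function(g)
            if (is.null(g)) 0 else sum(g^2), numeric(1))))
          if (gn > trainCfg$clipNorm) {
            sc <- trainCfg$clipNorm / gn
            grads <- lapply(grads, function(g)
              if (is.null(g)) g else g * sc)
          }
        }
        st <- adamw_step(params, grads, state, lr, trainCfg$weightDecay)
        params <- st$params
        state <- st$state
        epochLoss <- epochLoss + c(r$focal$val, r$triplet$val, r$cons$val,
                                   r$loss$val)
        nb <- nb + 1L
        pred <- max.col(r$probs) - 1L
        correct <- correct +
          sum(pred == vapply(batch, `[[`, integer(1), "label"))
      }
      model$params <- params
      trainAcc <- correct / length(ord)
      valFocal <- if (length(valIdx)) {
        rv <- mm_batch_loss(model, subjects[valIdx], lossCfg,
                            training = FALSE)
        rv$focal$val
      } else epochLoss[["focal"]] / nb
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = lr,
        focal = epochLoss[["focal"]] / nb,
        triplet = epochLoss[["triplet"]] / nb,
        consistency = epochLoss[["cons"]] / nb,
        total = epochLoss[["total"]] / nb,
        trainAccuracy = trainAcc, valFocal = valFocal)
      if (valFocal < best$val - 1e-9) {
        best <- list(val = valFocal, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= trainCfg$patience) {
        stoppedEpoch <- epoch
        break
      }
      if (!is.null(stopAtTrainAcc) && trainAcc >= stopAtTrainAcc) {
        best <- list(val = valFocal, params = params, epoch = epoch)
        stoppedEpoch <- epoch
        break
      }
      stoppedEpoch <- epoch
    }
  })
  model$params <- best$params
  list(model = model, history = do.call(rbind, history),
       bestEpoch = best$epoch, stoppedEpoch = stoppedEpoch)
}

#' Evaluate a trained model on prepared subjects
#' @param model trained model.
#' @param subjects prepared subject list (disjoint from training by the
#'   split plan).
#' @return \code{\link{metricsReport}} output.
#' @export
evaluateModel <- function(model, subjects) {
  probs <- predictSubjects(model, subjects)
  truth <- vapply(subjects, `[[`, integer(1), "label")
  metricsReport(truth, probs)
}
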