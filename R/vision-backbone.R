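#' Specify a convolutional backbone
#'
#' @param architecture "efficientnet-b0" (the working backbone),
#'   "resnet-18" or "vgg-16" (reference architectures constructed for
#'   parameter accounting and optional baselines).
#' @param inputMode "2d_slices" (axial slices encoded independently and
#'   mean-pooled; the mode whose parameter count matches the published
#'   figures) or "3d" (volumetric convolutions, for synthetic experiments;
#'   excluded from count targets).
#' @param numClasses classifier width (1000 is the convention under which
#'   the published counts hold; the staging model uses 3).
#' @param withMobileCbam insert a Mobile CBAM block after the expansion
#'   convolution of every MBConv block (efficientnet-b0 only).
#' @param stochasticDepth residual drop probability during training.
#' @param inputSize spatial edge length expected by the encoder.
#' @return a "backboneSpec" list.
#' @export
backboneSpec <- function(architecture = c("efficientnet-b0", "resnet-18",
                                          "vgg-16"),
                         inputMode = c("2d_slices", "3d"),
                         numClasses = 1000L,
                         withMobileCbam = FALSE,
                         stochasticDepth = 0.2,
                         inputSize = 64L) {
  architecture <- tryCatch(match.arg(architecture), error = function(e)
    stopf("unknown architecture '%s'; supported: efficientnet-b0, resnet-18, vgg-16",
          architecture[1]))
  inputMode <- match.arg(inputMode)
  if (withMobileCbam && architecture != "efficientnet-b0")
    stopf("withMobileCbam is only valid for efficientnet-b0")
  structure(list(architecture = architecture, inputMode = inputMode,
                 numClasses = as.integer(numClasses),
                 withMobileCbam = withMobileCbam,
                 stochasticDepth = stochasticDepth,
                 inputSize = as.integer(inputSize)),
            class = "backboneSpec")
}

#' Build a backbone and its exact parameter report
#'
#' EfficientNet-B0 models are materialized with seeded random weights and
#' support a forward pass; the ResNet-18 and VGG-16 constructors provide
#' exact parameter accounting only.
#'
#' @param spec a \code{\link{backboneSpec}}.
#' @param seed weight-initialization seed.
#' @return list with \code{model} and \code{report}
#'   (\code{\linkS4class{ParamReport}}).
#' @export
buildBackbone <- function(spec, seed = 1L) {
  nd <- if (spec$inputMode == "3d") 3L else 2L
  mods <- switch(spec$architecture,
    "efficientnet-b0" = count_efficientnet_b0(spec$numClasses,
                                              spec$withMobileCbam, nd = nd),
    "resnet-18" = count_resnet18(spec$numClasses),
    "vgg-16" = count_vgg16(spec$numClasses))
  report <- param_report(mods)
  model <- list(spec = spec, report = report, weights = NULL)
  if (spec$architecture == "efficientnet-b0") {
    model$weights <- with_seed(seed, init_effnet_weights(spec, nd))
    model$nd <- nd
  }
  class(model) <- "backboneModel"
  list(model = model, report = report)
}

# --- generic n-dimensional convolution via im2col -------------------------

# Gather indices for an im2col patch matrix. dims: spatial input dims.
# Returns padded flat indices (nOut x k^nd), output dims, and the original
# positions inside the padded flat grid.
conv_indices <- function(dims, k, stride) {
  nd <- length(dims)
  pad <- (k - 1) %/% 2
  dp <- dims + 2L * pad
  dout <- (dims + 2L * pad - k) %/% stride + 1L
  mult <- cumprod(c(1L, dp[-nd]))
  # per-dim starting coordinates of each output position, and kernel offsets
  starts <- lapply(seq_len(nd), function(d)
    (seq_len(dout[d]) - 1L) * stride)
  offs <- lapply(seq_len(nd), function(d) 0:(k - 1L))
  outGrid <- as.matrix(expand.grid(starts))       # nOut x nd (0-based)
  offGrid <- as.matrix(expand.grid(offs))         # k^nd x nd (0-based)
  base <- as.vector(outGrid %*% mult)             # nOut
  shift <- as.vector(offGrid %*% mult)            # k^nd
  idx <- outer(base, shift, "+") + 1L             # nOut x k^nd
  origMult <- mult
  origCoords <- as.matrix(expand.grid(lapply(dims, function(d)
    pad + 0:(d - 1L))))
  origPos <- as.vector(origCoords %*% mult) + 1L
  list(idx = idx, dout = dout, nPad = prod(dp), origPos = origPos)
}

# X: (prod(dims) x C) feature matrix. Returns (nOut x k^nd*C) patch matrix.
im2col <- function(X, ci) {
  Xp <- matrix(0, ci$nPad, ncol(X))
  Xp[ci$origPos, ] <- X
  matrix(Xp[as.vector(ci$idx), ], nrow(ci$idx), ncol(ci$idx) * ncol(X))
}

conv_forward <- function(X, dims, W, k, stride) {
  ci <- conv_indices(dims, k, stride)
  list(out = im2col(X, ci) %*% W, dims = ci$dout)
}

depthwise_forward <- function(X, dims, Wd, k, stride) {
  ci <- conv_indices(dims, k, stride)
  P <- im2col(X, ci)
  kp <- ncol(ci$idx)
  out <- matrix(0, nrow(P), ncol(X))
  for (c in seq_len(ncol(X)))
    out[, c] <- P[, (c - 1L) * kp + seq_len(kp), drop = FALSE] %*% Wd[, c]
  list(out = out, dims = ci$dout)
}

silu <- function(x) x / (1 + exp(-x))

bn_forward <- function(X, bn) {
  sweep(sweep(X, 2, bn$gamma, "*"), 2, bn$beta, "+")
}

# --- EfficientNet-B0 weights ----------------------------------------------

rn <- function(n, sd = 0.05) rnorm(n, 0, sd)

new_bn <- function(C) list(gamma = rep(1, C), beta = rep(0, C))

init_mbconv_weights <- function(inCh, outCh, expand, k, nd, withCbam) {
  mid <- inCh * expand
  kp <- k^nd
  w <- list(inCh = inCh, outCh = outCh, expand = expand, k = k, mid = mid)
  if (expand != 1) {
    w$expandW <- matrix(rn(inCh * mid, sd = sqrt(2 / inCh)), inCh, mid)
    w$expandBn <- new_bn(mid)
  }
  w$dwW <- matrix(rn(kp * mid, sd = sqrt(2 / kp)), kp, mid)
  w$dwBn <- new_bn(mid)
  sq <- max(1L, inCh %/% 4L)
  w$seW1 <- matrix(rn(mid * sq, sd = sqrt(2 / mid)), mid, sq)
  w$seB1 <- rep(0, sq)
  w$seW2 <- matrix(rn(sq * mid, sd = sqrt(2 / sq)), sq, mid)
  w$seB2 <- rep(0, mid)
  w$projW <- matrix(rn(mid * outCh, sd = sqrt(2 / mid)), mid, outCh)
  w$projBn <- new_bn(outCh)
  if (withCbam) w$cbam <- init_mobile_cbam_weights(nd)
  w
}

init_mobile_cbam_weights <- function(nd = 2L) {
  list(
    chDw = rn(5, 0.3),       # shared 1-D depthwise kernel over channels
    chDwB = 0,
    chPw = 1, chPwB = 0,     # pointwise 1x1 on the single descriptor channel
    spDw = matrix(rn(2 * 7^nd, 0.05), 7^nd, 2),  # depthwise 7^nd, 2 maps
    spPw = c(0.5, 0.5), spPwB = 0)
}

init_effnet_weights <- function(spec, nd) {
  st <- effnet_b0_stages()
  w <- list(stemW = matrix(rn(3 * 32 * 3^nd, sd = sqrt(2 / (3 * 3^nd))),
                           3^nd * 3, 32),
            stemBn = new_bn(32))
  blocks <- list()
  inCh <- 32L
  for (s in seq_len(nrow(st))) {
    for (b in seq_len(st$n[s])) {
      blocks[[length(blocks) + 1L]] <- c(
        init_mbconv_weights(inCh, st$out[s], st$expand[s], st$kernel[s],
                            nd, spec$withMobileCbam),
        list(stride = if (b == 1L) st$stride[s] else 1L, stage = s))
      inCh <- st$out[s]
    }
  }
  w$blocks <- blocks
  w$headW <- matrix(rn(inCh * 1280, sd = sqrt(2 / inCh)), inCh, 1280)
  w$headBn <- new_bn(1280)
  w$clsW <- matrix(rn(1280 * spec$numClasses, sd = 0.01), 1280,
                   spec$numClasses)
  w$clsB <- rep(0, spec$numClasses)
  w$projW <- matrix(rn(1280 * 256, sd = sqrt(1 / 1280)), 1280, 256)
  w$projB <- rep(0, 256)
  w
}

#' Mobile CBAM forward refinement
#'
#' Sequential channel-then-spatial attention built entirely from
#' depthwise-separable operations. Channel attention runs a shared
#' depthwise-separable 1-D convolution across the pooled channel descriptor
#' for the average- and max-pooled branches and gates channels through a
#' sigmoid; spatial attention runs a depthwise 7-per-axis convolution over
#' the two channel-pooled maps with a pointwise combiner. Both gates lie
#' strictly in (0, 1) and the output shape equals the input shape.
#'
#' @param X feature matrix (positions x channels).
#' @param dims spatial dimensions of the grid (prod(dims) = nrow(X)).
#' @param w CBAM weights (from the built model, or
#'   \code{initMobileCbam()}).
#' @return refined feature matrix, same shape.
#' @export
mobileCbamForward <- function(X, dims, w) {
  C <- ncol(X)
  branch <- function(desc) {
    # depthwise-separable 1-D conv (kernel 5, same padding) across the
    # length-C descriptor
    k <- length(w$chDw)
    xp <- c(rep(0, (k - 1) / 2), desc, rep(0, (k - 1) / 2))
    z <- as.numeric(xp[outer(seq_len(C) - 1L, seq_len(k), "+")] |>
                      matrix(C, k) %*% w$chDw)
    w$chPw * (z + w$chDwB) + w$chPwB
  }
  mc <- 1 / (1 + exp(-(branch(colMeans(X)) + branch(apply(X, 2, max)))))
  X1 <- sweep(X, 2, mc, "*")
  pooled <- cbind(rowMeans(X1), apply(X1, 1, max))
  dwo <- depthwise_forward(pooled, dims, w$spDw, 7L, 1L)$out
  ms <- 1 / (1 + exp(-(dwo %*% w$spPw + w$spPwB)))
  out <- X1 * as.numeric(ms)
  attr(out, "channelGate") <- mc
  attr(out, "spatialGate") <- as.numeric(ms)
  out
}

#' Initialize a standalone Mobile CBAM block (for direct testing)
#' @param nd spatial dimensionality (2 or 3).
#' @param seed RNG seed.
#' @export
initMobileCbam <- function(nd = 2L, seed = 1L) {
  with_seed(seed, init_mobile_cbam_weights(nd))
}

mbconv_forward <- function(X, dims, bw, nd, training = FALSE,
                           dropProb = 0) {
  inX <- X
  inDims <- dims
  if (bw$expand != 1) {
    X <- silu(bn_forward(X %*% bw$expandW, bw$expandBn))
  }
  if (!is.null(bw$cbam)) X <- mobileCbamForward(X, dims, bw$cbam)
  dwo <- depthwise_forward(X, dims, bw$dwW, bw$k, bw$stride)
  X <- silu(bn_forward(dwo$out, bw$dwBn))
  dims <- dwo$dims
  s <- silu(colMeans(X) %*% bw$seW1 + bw$seB1)
  g <- 1 / (1 + exp(-(s %*% bw$seW2 + bw$seB2)))
  X <- sweep(X, 2, as.numeric(g), "*")
  X <- bn_forward(X %*% bw$projW, bw$projBn)
  if (bw$stride == 1L && bw$inCh == bw$outCh) {
    if (training && dropProb > 0) {
      if (runif(1) < dropProb) X <- inX
      else X <- inX + X / (1 - dropProb)
    } else {
      X <- inX + X
    }
  }
  list(out = X, dims = dims)
}

effnet_features <- function(model, X, dims, training = FALSE) {
  w <- model$weights
  nd <- model$nd
  st <- conv_forward(X, dims, w$stemW, 3L, 2L)
  Xc <- silu(bn_forward(st$out, w$stemBn))
  dims <- st$dims
  for (bw in w$blocks) {
    r <- mbconv_forward(Xc, dims, bw, nd, training,
                        model$spec$stochasticDepth)
    Xc <- r$out
    dims <- r$dims
  }
  Xh <- silu(bn_forward(Xc %*% w$headW, w$headBn))
  list(map = Xh, dims = dims, pooled = colMeans(Xh))
}

#' Encode a volume into the shared 256-dimensional space
#'
#' In "2d_slices" mode a fixed set of evenly spaced axial slices is resized
#' to the configured input edge, replicated to three channels, encoded
#' independently, mean-pooled over slices and projected to 256-d. In "3d"
#' mode the convolutions are volumetric. Evaluation mode is deterministic;
#' training mode applies stochastic depth under the supplied seed.
#'
#' @param model an efficientnet-b0 model from \code{\link{buildBackbone}}.
#' @param sample a \code{\linkS4class{VolumeSample}} (or a raw 3-D array).
#' @param nSlices slices encoded in 2d_slices mode.
#' @param training apply stochastic depth (seeded).
#' @param seed RNG seed for training-mode stochasticity.
#' @return numeric length-256 embedding.
#' @export
encodeVolume <- function(model, sample, nSlices = 8L, training = FALSE,
                         seed = 1L) {
  if (is(sample, "VolumeSample")) vox <- sample@voxels else vox <- sample
  if (is.null(model$weights))
    stopf("forward pass is only supported for efficientnet-b0 models")
  sz <- model$spec$inputSize
  run <- function() {
    if (model$spec$inputMode == "2d_slices") {
      zIdx <- slice_positions(dim(vox)[3], nSlices)
      pooled <- matrix(0, length(zIdx), 1280)
      for (i in seq_along(zIdx)) {
        sl <- resize_bilinear(vox[, , zIdx[i]], sz, sz)
        X <- matrix(as.numeric(sl), ncol = 1)[, c(1, 1, 1)]
        pooled[i, ] <- effnet_features(model, X, c(sz, sz), training)$pooled
      }
      emb <- colMeans(pooled)
    } else {
      if (!identical(dim(vox), rep(sz, 3L)))
        vox <- resize_volume(vox, sz)
      X <- matrix(as.numeric(vox), ncol = 1)[, c(1, 1, 1)]
      emb <- effnet_features(model, X, rep(sz, 3L), training)$pooled
    }
    as.numeric(emb %*% model$weights$projW + model$weights$projB)
  }
  if (training) with_seed(seed, run()) else run()
}

resize_bilinear <- function(m, nr, nc) {
  if (identical(dim(m), as.integer(c(nr, nc)))) return(m)
  xi <- seq(1, nrow(m), length.out = nr)
  yi <- seq(1, ncol(m), length.out = nc)
  x0 <- pmin(floor(xi), nrow(m) - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), ncol(m) - 1L); fy <- yi - y0
  a <- m[x0, y0, drop = FALSE]; b <- m[x0 + 1, y0, drop = FALSE]
  cc <- m[x0, y0 + 1, drop = FALSE]; d <- m[x0 + 1, y0 + 1, drop = FALSE]
  a * outer(1 - fx, 1 - fy) + b * outer(fx, 1 - fy) +
    cc * outer(1 - fx, fy) + d * outer(fx, fy)
}

resize_volume <- function(vox, sz) {
  out <- array(0, dim = rep(sz, 3L))
  zi <- round(seq(1, dim(vox)[3], length.out = sz))
  for (k in seq_len(sz))
    out[, , k] <- resize_bilinear(vox[, , zi[k]], sz, sz)
  out
}
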