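# Exact parameter accounting for the reference backbones. Counts follow the
# standard convention: convolution weights (+bias where the architecture
# uses one), batch-norm gain and bias (running statistics are buffers, not
# parameters), and fully connected weights + biases.

# EfficientNet-B0 stage table: expansion factor, output width, repeats,
# kernel, stride. Stem 32ch, head 1280ch, squeeze-excitation at 1/4 of the
# block's input width.
effnet_b0_stages <- function() {
  data.frame(
    expand = c(1, 6, 6, 6, 6, 6, 6),
    out    = c(16, 24, 40, 80, 112, 192, 320),
    n      = c(1, 2, 2, 3, 3, 4, 1),
    kernel = c(3, 3, 5, 3, 5, 5, 3),
    stride = c(1, 2, 2, 2, 1, 2, 1))
}

mbconv_params <- function(inCh, outCh, expand, k, nd = 2L) {
  mid <- inCh * expand
  p <- 0
  if (expand != 1) p <- p + inCh * mid + 2 * mid         # expansion 1x1 + BN
  p <- p + k^nd * mid + 2 * mid                          # depthwise + BN
  sq <- max(1L, inCh %/% 4L)                             # squeeze-excitation
  p <- p + mid * sq + sq + sq * mid + mid
  p + mid * outCh + 2 * outCh                            # projection + BN
}

count_efficientnet_b0 <- function(numClasses = 1000L, withCbam = FALSE,
                                  nd = 2L) {
  st <- effnet_b0_stages()
  mods <- c(stem = 3 * 32 * 3^nd + 2 * 32)
  inCh <- 32L
  nBlocks <- 0L
  for (s in seq_len(nrow(st))) {
    p <- 0
    for (b in seq_len(st$n[s])) {
      p <- p + mbconv_params(inCh, st$out[s], st$expand[s], st$kernel[s],
                             nd)
      inCh <- st$out[s]
      nBlocks <- nBlocks + 1L
    }
    mods[sprintf("stage%d", s)] <- p
  }
  mods["head"] <- inCh * 1280 + 2 * 1280
  mods["classifier"] <- 1280 * numClasses + numClasses
  if (withCbam) mods["mobile_cbam"] <- nBlocks * mobile_cbam_params(nd)
  mods
}

count_resnet18 <- function(numClasses = 1000L) {
  basic <- function(inCh, outCh, down) {
    p <- 9 * inCh * outCh + 2 * outCh + 9 * outCh * outCh + 2 * outCh
    if (down) p <- p + inCh * outCh + 2 * outCh
    p
  }
  mods <- c(stem = 3 * 64 * 49 + 2 * 64)
  widths <- c(64, 128, 256, 512)
  inCh <- 64
  for (s in seq_along(widths)) {
    w <- widths[s]
    p <- basic(inCh, w, down = (s > 1)) + basic(w, w, down = FALSE)
    mods[sprintf("layer%d", s)] <- p
    inCh <- w
  }
  mods["classifier"] <- 512 * numClasses + numClasses
  mods
}

count_vgg16 <- function(numClasses = 1000L) {
  cfg <- list(c(64, 64), c(128, 128), c(256, 256, 256),
              c(512, 512, 512), c(512, 512, 512))
  mods <- numeric()
  inCh <- 3
  for (s in seq_along(cfg)) {
    p <- 0
    for (w in cfg[[s]]) {
      p <- p + 9 * inCh * w + w
      inCh <- w
    }
    mods[sprintf("block%d", s)] <- p
  }
  mods["fc"] <- (512 * 49) * 4096 + 4096 + 4096 * 4096 + 4096
  mods["classifier"] <- 4096 * numClasses + numClasses
  mods
}

# Mobile CBAM parameter count per block. Channel attention is a shared
# depthwise-separable 1-D convolution across the pooled channel descriptor
# (depthwise kernel 5 + bias, pointwise 1x1 + bias = 8 parameters,
# independent of width); spatial attention is a depthwise 7x7 over the two
# channel-pooled maps plus a pointwise combiner (98 + 2 + 1 = 101).
mobile_cbam_params <- function(nd = 2L) {
  channel <- 5 + 1 + 1 + 1
  spatial <- 2 * 7^nd + 2 + 1
  channel + spatial
}

# Standard CBAM at width C for comparison: shared two-layer bottleneck MLP
# (reduction 16, no bias) plus a dense 7x7 spatial convolution.
standard_cbam_params <- function(C, reduction = 16L) {
  hidden <- max(1L, C %/% reduction)
  2 * C * hidden + 2 * 49 + 1
}

#' Parameter ratio of a standard square convolution vs its
#' depthwise-separable factorization
#'
#' For a bias-free C-to-C convolution with k x k kernels, the standard form
#' costs \eqn{C^2 k^2} weights while the depthwise + pointwise factorization
#' costs \eqn{C k^2 + C^2}; the ratio approaches \eqn{k^2} for wide layers
#' (about 8x at C = 64, k = 3).
#'
#' @param C channel count (>= 1).
#' @param k odd kernel size.
#' @return the parameter ratio (standard / separable).
#' @export
dwconvParamRatio <- function(C, k = 3L) {
  stopifnot(C >= 1, k %% 2 == 1)
  (C^2 * k^2) / (C * k^2 + C^2)
}

#' Mobile vs standard CBAM parameter comparison at width C
#'
#' @param C channel count.
#' @return named vector with \code{mobile} and \code{standard} counts.
#' @export
cbamParamComparison <- function(C) {
  c(mobile = mobile_cbam_params(), standard = standard_cbam_params(C))
}

param_report <- function(mods, trainable = NULL, macs = NA_real_,
                         inputSize = "not computed") {
  total <- sum(mods)
  new("ParamReport", modules = mods, total = total,
      totalM = round_half_up(total / 1e6, 1),
      trainable = trainable %||% total,
      frozen = total - (trainable %||% total),
      macs = macs, inputSize = inputSize)
}
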