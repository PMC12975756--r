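#' Grad-CAM++ map from activations and gradients
#'
#' Standard closed form under exponentiated class scores: per-location
#' channel weights \eqn{\alpha = g^2 / (2 g^2 + (\sum_{pos} A) g^3)} (the
#' denominator floored at 1e-8), channel importance
#' \eqn{w_k = \sum_{pos} \alpha \, \mathrm{relu}(g)}, and the map
#' \eqn{\mathrm{relu}(\sum_k w_k A_k)}. With a single feature map and a
#' spatially uniform positive gradient this reduces to Grad-CAM (a map
#' proportional to the rectified feature map).
#'
#' @param A activations (positions x channels).
#' @param G gradients of the class score w.r.t. A (same shape).
#' @param dims spatial dimensions (prod(dims) = nrow(A)).
#' @return relevance matrix of shape \code{dims}, not yet normalized.
#' @export
gradCamPPMap <- function(A, G, dims) {
  sumA <- colSums(A)
  denom <- 2 * G^2 + sweep(G^3, 2, sumA, "*")
  alpha <- ifelse(abs(denom) < 1e-8, 0, G^2 / denom)
  w <- colSums(alpha * pmax(G, 0))
  matrix(pmax(as.numeric(A %*% w), 0), dims[1], dims[2])
}

#' Grad-CAM++ saliency for a multimodal-model subject
#'
#' Computes per-slice maps over the image stem's final convolutional
#' activations (gradients taken from the target-class logit through the
#' full fused model), upsamples each map to the native slice resolution,
#' reassembles the volume by nearest encoded slice, and max-normalizes to
#' [0, 1].
#'
#' @param model a trained \code{\link{buildMultimodalModel}}.
#' @param sample the subject's \code{\linkS4class{VolumeSample}}.
#' @param subject the prepared subject input (slices + token ids), e.g.
#'   one element of \code{\link{prepareSubjects}}.
#' @param targetClass class to explain (0, 1, 2).
#' @return a \code{\linkS4class{SaliencyMap}}.
#' @export
gradCamPP <- function(model, sample, subject, targetClass) {
  if (!targetClass %in% 0:2) stopf("target class out of range")
  tape <- adTape()
  nodes <- mm_nodes(tape, model)
  out <- mm_forward_one(tape, model, nodes, subject, training = FALSE)
  score <- adCols(tape, out$logits, targetClass + 1L)
  adBackward(tape, score)
  vol <- array(0, dim = dim(sample@voxels))
  nz <- dim(vol)[3]
  zIdx <- slice_positions(nz, model$nSlices)
  sliceOf <- vapply(seq_len(nz), function(z)
    which.min(abs(zIdx - z)), integer(1))
  for (s in seq_along(zIdx)) {
    A <- out$convActs[[s]]$val
    G <- out$convActs[[s]]$grad
    if (is.null(G)) G <- A * 0
    mp <- gradCamPPMap(A, G, c(model$imgSize, model$imgSize))
    mpFull <- resize_bilinear(mp, dim(vol)[1], dim(vol)[2])
    for (z in which(sliceOf == s)) vol[, , z] <- mpFull
  }
  mx <- max(vol)
  if (mx > 0) vol <- vol / mx
  new("SaliencyMap", relevance = vol, targetClass = as.integer(targetClass),
      maxValue = mx)
}

#' Write a saliency map as a NIfTI overlay
#' @param map a \code{\linkS4class{SaliencyMap}}.
#' @param path output .nii.gz path.
#' @export
writeSaliency <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map@relevance), path)
  invisible(path)
}
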