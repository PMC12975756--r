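#' Loss configuration
#'
#' @param gamma focal focusing parameter (default 2).
#' @param margin triplet margin (default 0.3).
#' @param lambdaFocal,lambdaTriplet,lambdaCons component weights
#'   (defaults 1, 0.5, 0.5).
#' @param epsilon label-smoothing mass (default 0.1).
#' @param nClasses class count K (default 3).
#' @export
lossConfig <- function(gamma = 2, margin = 0.3, lambdaFocal = 1,
                       lambdaTriplet = 0.5, lambdaCons = 0.5,
                       epsilon = 0.1, nClasses = 3L) {
  stopifnot(gamma >= 0, margin >= 0, lambdaFocal >= 0, lambdaTriplet >= 0,
            lambdaCons >= 0, epsilon >= 0, epsilon < 1)
  structure(list(gamma = gamma, margin = margin,
                 lambdaFocal = lambdaFocal, lambdaTriplet = lambdaTriplet,
                 lambdaCons = lambdaCons, epsilon = epsilon,
                 nClasses = as.integer(nClasses)), class = "lossConfig")
}

#' Smoothed one-hot targets
#'
#' True class receives 1 - epsilon + epsilon/K, the rest epsilon/K; rows
#' sum to 1.
#'
#' @param labels integer labels in 0..K-1.
#' @param K class count.
#' @param epsilon smoothing mass.
#' @export
smoothTargets <- function(labels, K, epsilon = 0.1) {
  t <- matrix(epsilon / K, length(labels), K)
  t[cbind(seq_along(labels), labels + 1L)] <-
    1 - epsilon + epsilon / K
  t
}

#' Focal loss
#'
#' Mean over the batch of \eqn{-\sum_k t_k (1-p_k)^\gamma \log p_k}
#' against epsilon-smoothed targets; gamma = 0 and epsilon = 0 reduce it
#' to cross-entropy. Probabilities are floored at 1e-12 inside the log.
#'
#' @param probs n x K matrix of predicted probabilities (rows sum to 1).
#' @param labels integer labels in 0..K-1.
#' @param gamma focusing parameter.
#' @param epsilon label smoothing.
#' @export
focalLoss <- function(probs, labels, gamma = 2, epsilon = 0) {
  probs <- as_mat(probs)
  K <- ncol(probs)
  t <- smoothTargets(labels, K, epsilon)
  p <- pmax(probs, 1e-12)
  mean(rowSums(-t * (1 - probs)^gamma * log(p)))
}

#' Pairwise Euclidean distances between embedding rows
#' @param E n x d embedding matrix.
#' @export
pairwiseDist <- function(E) {
  g <- E %*% t(E)
  d2 <- outer(diag(g), diag(g), "+") - 2 * g
  sqrt(pmax(d2, 0))
}

#' Batch-hard triplet mining
#'
#' For each anchor: hardest positive = most distant same-class row
#' (excluding the anchor), hardest negative = closest other-class row.
#' Anchors whose class has no second member are skipped; a batch without
#' two classes (or without any valid anchor) is degenerate and raises an
#' error.
#'
#' @param E n x d embeddings; \code{labels} length-n classes.
#' @param labels class labels.
#' @return data.frame with anchor/positive/negative indices.
#' @export
mineTriplets <- function(E, labels) {
  if (length(unique(labels)) < 2L)
    stopf("degenerate batch: triplet mining needs at least two classes")
  D <- pairwiseDist(E)
  rows <- list()
  for (a in seq_len(nrow(E))) {
    same <- which(labels == labels[a]); same <- setdiff(same, a)
    diff <- which(labels != labels[a])
    if (!length(same) || !length(diff)) next
    rows[[length(rows) + 1L]] <- data.frame(
      anchor = a,
      positive = same[which.max(D[a, same])],
      negative = diff[which.min(D[a, diff])])
  }
  if (!length(rows))
    stopf("degenerate batch: no anchor has a positive partner")
  do.call(rbind, rows)
}

#' Triplet loss
#'
#' Mean of \eqn{\max(0, d(a,p) - d(a,n) + m)} over supplied triplets
#' (vectors or matrices of row-aligned embeddings).
#'
#' @param anchor,positive,negative embeddings (row-aligned matrices or
#'   single vectors).
#' @param margin hinge margin.
#' @export
tripletLoss <- function(anchor, positive, negative, margin = 0.3) {
  a <- as_mat(anchor); p <- as_mat(positive); n <- as_mat(negative)
  dap <- sqrt(rowSums((a - p)^2))
  dan <- sqrt(rowSums((a - n)^2))
  mean(pmax(0, dap - dan + margin))
}

#' Multimodal consistency loss
#'
#' Mean over the batch of 1 - cos(u, v) between the two modality
#' embeddings of the same sample; range [0, 2]. Norms are floored at
#' 1e-12.
#'
#' @param imageEmb,textEmb row-aligned embedding matrices (or vectors).
#' @export
consistencyLoss <- function(imageEmb, textEmb) {
  u <- as_mat(imageEmb); v <- as_mat(textEmb)
  nu <- pmax(sqrt(rowSums(u^2)), 1e-12)
  nv <- pmax(sqrt(rowSums(v^2)), 1e-12)
  mean(1 - rowSums(u * v) / (nu * nv))
}

#' Mixup augmentation over a batch
#'
#' Per-pair mixing coefficients are drawn from Beta(alpha, alpha),
#' independently for the image and metadata streams, and each stream is
#' mixed convexly with the same random pairing permutation. Targets are
#' mixed with the image-stream coefficients (one target per sample).
#' alpha <= 0 disables mixing for that stream.
#'
#' @param images n x p matrix (rows = flattened image features).
#' @param meta n x q metadata matrix.
#' @param targets n x K (smoothed) target matrix.
#' @param alphaImg,alphaMeta Beta parameters (defaults 0.2, 0.1).
#' @param lambda optional fixed coefficient overriding the Beta draw
#'   (applied to both streams; for limit checks).
#' @return list with mixed \code{images}, \code{meta}, \code{targets},
#'   the \code{permutation} and the drawn \code{lambdaImg}/
#'   \code{lambdaMeta}.
#' @export
mixupBatch <- function(images, meta, targets, alphaImg = 0.2,
                       alphaMeta = 0.1, lambda = NULL) {
  n <- nrow(targets)
  stopifnot(n >= 2L)
  perm <- sample(n)
  li <- if (!is.null(lambda)) rep(lambda, n)
        else if (alphaImg > 0) rbeta(n, alphaImg, alphaImg) else rep(1, n)
  lm <- if (!is.null(lambda)) rep(lambda, n)
        else if (alphaMeta > 0) rbeta(n, alphaMeta, alphaMeta)
        else rep(1, n)
  mix <- function(M, l) M * l + M[perm, , drop = FALSE] * (1 - l)
  list(images = mix(images, li), meta = mix(meta, lm),
       targets = mix(targets, li), permutation = perm,
       lambdaImg = li, lambdaMeta = lm)
}

#' Cosine-annealed learning rate
#'
#' \eqn{\eta(t) = \eta_{min} + (\eta_0 - \eta_{min}) (1 + \cos(\pi t /
#' T_{max})) / 2}; equals \eqn{\eta_0} at t = 0 and exactly
#' \eqn{\eta_{min}} at t = T_max.
#'
#' @param epoch current epoch t (0-based).
#' @param lr0 initial rate (default 1e-4).
#' @param tMax annealing horizon (default 50).
#' @param etaMin floor rate (default 1e-6).
#' @export
cosineLR <- function(epoch, lr0 = 1e-4, tMax = 50, etaMin = 1e-6) {
  etaMin + 0.5 * (lr0 - etaMin) * (1 + cos(pi * min(epoch, tMax) / tMax))
}
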