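# Isolation forest (Liu, Ting & Zhou): anomalies are isolated by fewer
# random axis-aligned splits, so short average path lengths mean high
# anomaly scores. Used for clinical outlier detection; no installed package
# provides it, so it is implemented directly.

iso_c <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

iso_build <- function(X, depth, maxDepth) {
  n <- nrow(X)
  if (n <= 1L || depth >= maxDepth) return(list(size = n))
  spread <- apply(X, 2, function(v) diff(range(v)))
  usable <- which(spread > 0)
  if (!length(usable)) return(list(size = n))
  q <- usable[sample.int(length(usable), 1L)]
  rng <- range(X[, q])
  p <- runif(1, rng[1], rng[2])
  left <- X[, q] < p
  list(q = q, p = p,
       left = iso_build(X[left, , drop = FALSE], depth + 1L, maxDepth),
       right = iso_build(X[!left, , drop = FALSE], depth + 1L, maxDepth))
}

iso_path <- function(tree, x, depth = 0) {
  if (is.null(tree$q)) return(depth + iso_c(tree$size))
  if (x[tree$q] < tree$p) iso_path(tree$left, x, depth + 1)
  else iso_path(tree$right, x, depth + 1)
}

#' Isolation-forest anomaly scores
#'
#' @param X numeric matrix (rows = observations).
#' @param nTrees number of isolation trees.
#' @param sampleSize subsample size per tree (capped at n).
#' @param seed RNG seed for tree construction.
#' @return anomaly scores in (0, 1); larger = more anomalous.
#' @export
isolationScores <- function(X, nTrees = 100L, sampleSize = 256L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  psi <- min(sampleSize, n)
  maxDepth <- ceiling(log2(max(psi, 2)))
  with_seed(seed, {
    trees <- lapply(seq_len(nTrees), function(i) {
      idx <- sample.int(n, psi)
      iso_build(X[idx, , drop = FALSE], 0L, maxDepth)
    })
    avg <- vapply(seq_len(n), function(i) {
      mean(vapply(trees, iso_path, numeric(1), x = X[i, ]))
    }, numeric(1))
    2^(-avg / iso_c(psi))
  })
}
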