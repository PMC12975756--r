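#' Pairwise dependence via (normalized) mutual information
#'
#' Continuous vectors are discretized into \code{bins} equal-frequency bins
#' (vectors with at most \code{bins} distinct values are used as-is, so
#' ordinal/categorical codes keep their categories). Entropies and mutual
#' information are plug-in estimates in nats; \code{mode = "nmi"} returns
#' \eqn{2 MI / (H_i + H_j)}, which lies in [0, 1].
#'
#' A constant vector has zero entropy; under \code{"nmi"} the value is
#' defined as 0 with a warning.
#'
#' @param fi,fj equal-length vectors, \code{length >= bins}.
#' @param mode "mi" (raw, in nats) or "nmi" (normalized).
#' @param bins number of equal-frequency bins (default 10).
#' @return a single dependence value.
#' @export
dependence <- function(fi, fj, mode = c("nmi", "mi"), bins = 10L) {
  mode <- match.arg(mode)
  stopifnot(length(fi) == length(fj), length(fi) >= bins)
  bi <- discretize_ef(fi, bins)
  bj <- discretize_ef(fj, bins)
  tab <- table(bi, bj)
  p <- tab / sum(tab)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  hi <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hj <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pi_, pj_)[nz]))
  if (mode == "mi") return(mi)
  if (hi == 0 || hj == 0) {
    warning("constant vector (zero entropy): NMI defined as 0")
    return(0)
  }
  2 * mi / (hi + hj)
}

# Equal-frequency discretization; low-cardinality vectors pass through.
discretize_ef <- function(x, bins) {
  x <- as.numeric(as.factor(x))
  if (length(unique(x)) <= bins) return(x)
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}
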