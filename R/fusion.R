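#' Configure the gated dynamic cross-attention fusion module
#'
#' Bidirectional multi-head cross-attention between image and text token
#' sets in the shared 256-d space, with either a fixed head count or a
#' learnable controller over a candidate set, and a sigmoid gate balancing
#' the two attended modalities. Candidate head counts that do not divide
#' the embedding dimension use per-head width floor(dim/h) with a learned
#' output re-projection back to dim.
#'
#' @param mode "fixed" or "dynamic".
#' @param heads fixed head count (default 4, the configuration the
#'   ablations favour).
#' @param candidates candidate set for dynamic mode (default 2:6).
#' @param dim shared embedding dimension (256).
#' @param gateHidden controller hidden width.
#' @return a "fusionConfig" list.
#' @export
fusionConfig <- function(mode = c("fixed", "dynamic"), heads = 4L,
                         candidates = 2:6, dim = 256L, gateHidden = 32L) {
  mode <- match.arg(mode)
  if (mode == "fixed" && !heads %in% c(candidates, 1L, 8L, 16L))
    stopf("fixed head count must lie in the candidate set or {1, 8, 16}")
  structure(list(mode = mode, heads = as.integer(heads),
                 candidates = as.integer(candidates), dim = as.integer(dim),
                 gateHidden = as.integer(gateHidden)), class = "fusionConfig")
}

#' Initialize fusion weights
#'
#' @param cfg a \code{\link{fusionConfig}}.
#' @param seed RNG seed.
#' @return weight list: shared Q/K/V projections and per-candidate output
#'   re-projections for both attention directions, gate affine, and the
#'   head-selection controller (dynamic mode).
#' @export
buildFusion <- function(cfg, seed = 1L) {
  d <- cfg$dim
  hs <- if (cfg$mode == "dynamic") cfg$candidates else cfg$heads
  with_seed(seed, {
    mk <- function(nr, nc, s = sqrt(1 / nr)) matrix(rnorm(nr * nc, 0, s),
                                                    nr, nc)
    dir <- function() {
      Wo <- lapply(hs, function(h) {
        dh <- d %/% h
        mk(h * dh, d)
      })
      names(Wo) <- as.character(hs)
      list(Wq = mk(d, d), Wk = mk(d, d), Wv = mk(d, d), Wo = Wo)
    }
    list(cfg = cfg,
         imgToTxt = dir(), txtToImg = dir(),
         gateW = mk(2 * d, d, 0.02), gateB = rep(0, d),
         ctrlW1 = mk(2 * d, cfg$gateHidden, 0.02),
         ctrlB1 = rep(0, cfg$gateHidden),
         ctrlW2 = mk(cfg$gateHidden, length(cfg$candidates), 0.02),
         ctrlB2 = rep(0, length(cfg$candidates)))
  })
}

#' Scaled dot-product multi-head cross-attention
#'
#' One modality supplies queries, the other keys/values; softmax rows are
#' normalized. Head widths are floor(dim/heads); the concatenated heads are
#' re-projected to dim.
#'
#' @param queries n_q x dim matrix.
#' @param keysValues n_kv x dim matrix (>= 1 rows).
#' @param heads head count (>= 1).
#' @param w direction weights (\code{Wq}, \code{Wk}, \code{Wv}, \code{Wo}
#'   keyed by head count), e.g. \code{buildFusion(cfg)$imgToTxt}.
#' @return list with \code{out} (n_q x dim) and \code{attention} (list of
#'   per-head n_q x n_kv row-stochastic matrices).
#' @export
crossAttend <- function(queries, keysValues, heads, w) {
  if (is.null(dim(keysValues)) || nrow(keysValues) < 1L)
    stopf("empty key/value sequence")
  d <- ncol(queries)
  dh <- d %/% heads
  Wo <- w$Wo[[as.character(heads)]]
  if (is.null(Wo)) stopf("no output projection for %d heads", heads)
  Q <- queries %*% w$Wq
  K <- keysValues %*% w$Wk
  V <- keysValues %*% w$Wv
  outs <- vector("list", heads)
  attn <- vector("list", heads)
  for (h in seq_len(heads)) {
    ci <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, ci, drop = FALSE] %*% t(K[, ci, drop = FALSE]) / sqrt(dh)
    S <- S - apply(S, 1, max)
    A <- exp(S) / rowSums(exp(S))
    attn[[h]] <- A
    outs[[h]] <- A %*% V[, ci, drop = FALSE]
  }
  list(out = do.call(cbind, outs) %*% Wo, attention = attn)
}

#' Head-count selection weights
#'
#' Dynamic mode: a small controller maps the concatenated pooled
#' embeddings to a probability vector over the candidate head counts
#' (training mixes candidates by these probabilities; inference takes the
#' argmax). Fixed mode returns a one-hot on the configured count.
#'
#' @param imageEmb,textEmb pooled 256-d embeddings.
#' @param fusion weights from \code{\link{buildFusion}}.
#' @return named probability vector over candidate head counts.
#' @export
selectHeads <- function(imageEmb, textEmb, fusion) {
  cfg <- fusion$cfg
  if (cfg$mode == "fixed") {
    p <- as.numeric(cfg$candidates == cfg$heads)
    if (sum(p) == 0) {  # fixed count outside the candidate list
      return(setNames(1, as.character(cfg$heads)))
    }
    return(setNames(p, as.character(cfg$candidates)))
  }
  z <- matrix(c(imageEmb, textEmb), 1)
  h <- pmax(z %*% fusion$ctrlW1 + fusion$ctrlB1, 0)
  s <- h %*% fusion$ctrlW2 + fusion$ctrlB2
  e <- exp(s - max(s))
  setNames(as.numeric(e / sum(e)), as.character(cfg$candidates))
}

#' Gated fusion of the two attended modality embeddings
#'
#' g = sigmoid(affine([u; v])), fused = g * u + (1 - g) * v. The gate is
#' recorded for interpretability; the fused vector is an elementwise convex
#' combination of its inputs.
#'
#' @param u,v 256-d vectors (image-attended, text-attended).
#' @param fusion weights from \code{\link{buildFusion}}.
#' @param gateLogitOffset additive offset on the gate logits (0 by
#'   default; large values saturate the gate for limit checks).
#' @return list with \code{fused} and \code{gate}.
#' @export
gatedFuse <- function(u, v, fusion, gateLogitOffset = 0) {
  if (length(u) != length(v)) stopf("dimension mismatch")
  z <- matrix(c(u, v), 1)
  g <- 1 / (1 + exp(-(z %*% fusion$gateW + fusion$gateB +
                        gateLogitOffset)))
  g <- as.numeric(g)
  list(fused = g * u + (1 - g) * v, gate = g)
}

#' Fuse image and text token sets into a joint embedding
#'
#' Bidirectional cross-attention (image tokens attending text and vice
#' versa), mean-pooled per direction, then gated fusion. Dynamic mode
#' computes the probability-weighted mixture over candidate head counts in
#' training and the argmax candidate at inference.
#'
#' @param imageTokens,textTokens token matrices in the shared 256-d space.
#' @param fusion weights from \code{\link{buildFusion}}.
#' @param training probability-weighted mixture (TRUE) vs argmax (FALSE).
#' @return list with \code{fused}, \code{gate}, \code{headWeights},
#'   \code{attention} (per direction, selected/first candidate).
#' @export
fuseModalities <- function(imageTokens, textTokens, fusion,
                           training = FALSE) {
  cfg <- fusion$cfg
  uPool <- colMeans(imageTokens)
  vPool <- colMeans(textTokens)
  hw <- selectHeads(uPool, vPool, fusion)
  cands <- as.integer(names(hw))
  active <- if (cfg$mode == "fixed" || !training) {
    which.max(hw)
  } else {
    seq_along(cands)
  }
  u <- v <- 0
  attn <- NULL
  for (i in active) {
    h <- cands[i]
    a1 <- crossAttend(imageTokens, textTokens, h, fusion$imgToTxt)
    a2 <- crossAttend(textTokens, imageTokens, h, fusion$txtToImg)
    wgt <- if (length(active) > 1L) hw[i] else 1
    u <- u + wgt * colMeans(a1$out)
    v <- v + wgt * colMeans(a2$out)
    if (is.null(attn)) attn <- list(imgToTxt = a1$attention,
                                    txtToImg = a2$attention)
  }
  gf <- gatedFuse(u, v, fusion)
  list(fused = gf$fused, gate = gf$gate, headWeights = hw,
       attention = attn, imageAttended = u, textAttended = v)
}
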