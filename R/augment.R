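# Training-time image augmentation on 2-D slices: random horizontal flips,
# rotations (+/- 15 degrees), affine jitter (translation +/- 10%, scale
# 0.9-1.1), elastic deformation (alpha = 50, sigma = 5 in the convention of
# 224-pixel images, rescaled to the working slice size), and intensity
# scaling 0.9-1.1. All draws come from the caller's RNG stream so training
# remains seed-deterministic.

sample_bilinear <- function(m, xs, ys) {
  nr <- nrow(m); nc <- ncol(m)
  out <- numeric(length(xs))
  ok <- xs >= 1 & xs <= nr & ys >= 1 & ys <= nc
  x0 <- pmin(pmax(floor(xs[ok]), 1L), nr - 1L)
  y0 <- pmin(pmax(floor(ys[ok]), 1L), nc - 1L)
  fx <- xs[ok] - x0; fy <- ys[ok] - y0
  out[ok] <- m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    m[cbind(x0 + 1L, y0 + 1L)] * fx * fy
  out
}

warp_affine <- function(m, rotDeg = 0, tx = 0, ty = 0, scale = 1) {
  nr <- nrow(m); nc <- ncol(m)
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  th <- rotDeg * pi / 180
  grid <- expand.grid(x = seq_len(nr), y = seq_len(nc))
  # inverse mapping: output pixel -> source location
  gx <- (grid$x - cx - tx * nr)
  gy <- (grid$y - cy - ty * nc)
  sx <- (cos(-th) * gx - sin(-th) * gy) / scale + cx
  sy <- (sin(-th) * gx + cos(-th) * gy) / scale + cy
  matrix(sample_bilinear(m, sx, sy), nr, nc)
}

gaussian_blur_1d <- function(v, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  vp <- c(rep(v[1], r), v, rep(v[n], r))
  as.numeric(vp[outer(seq_len(n) - 1L, seq_len(2 * r + 1), "+")] |>
               matrix(n, 2 * r + 1) %*% k)
}

gaussian_blur <- function(m, sigma) {
  m <- apply(m, 2, gaussian_blur_1d, sigma = sigma)
  t(apply(m, 1, gaussian_blur_1d, sigma = sigma))
}

warp_elastic <- function(m, alpha = 50, sigma = 5, ref = 224) {
  nr <- nrow(m); nc <- ncol(m)
  # Displacement amplitude follows the standard convention at the
  # reference resolution: alpha scales a sigma-smoothed unit-uniform
  # field, whose smoothing shrinks its std to ~1/(2 sigma sqrt(pi)); at
  # alpha = 50, sigma = 5 that is ~1.6 px of smooth displacement at
  # 224 px, rescaled here to the working size. Fields are re-normalized
  # to unit std before scaling so the working-size smoothing floor does
  # not inflate the amplitude.
  sc <- nr / ref
  amp <- alpha * 0.033 * sc
  sEff <- max(sigma * sc, 0.5)
  field <- function() {
    f <- gaussian_blur(matrix(runif(nr * nc, -1, 1), nr, nc), sEff)
    f / max(sd(f), 1e-9) * amp
  }
  dx <- field(); dy <- field()
  grid <- expand.grid(x = seq_len(nr), y = seq_len(nc))
  matrix(sample_bilinear(m, grid$x + as.numeric(dx), grid$y + as.numeric(dy)),
         nr, nc)
}

#' Apply the training augmentation stack to one slice
#'
#' @param m numeric slice matrix.
#' @param pFlip horizontal-flip probability.
#' @param maxRot rotation bound in degrees.
#' @param maxShift translation bound as a fraction of the edge.
#' @param scaleRange multiplicative scale range.
#' @param elasticAlpha,elasticSigma elastic parameters (224-pixel
#'   convention).
#' @param intensityRange multiplicative intensity range.
#' @return augmented slice, same shape.
#' @export
augmentSlice <- function(m, pFlip = 0.5, maxRot = 15, maxShift = 0.1,
                         scaleRange = c(0.9, 1.1), elasticAlpha = 50,
                         elasticSigma = 5, intensityRange = c(0.9, 1.1)) {
  if (runif(1) < pFlip) m <- m[, rev(seq_len(ncol(m)))]
  m <- warp_affine(m, rotDeg = runif(1, -maxRot, maxRot),
                   tx = runif(1, -maxShift, maxShift),
                   ty = runif(1, -maxShift, maxShift),
                   scale = runif(1, scaleRange[1], scaleRange[2]))
  m <- warp_elastic(m, elasticAlpha, elasticSigma)
  m * runif(1, intensityRange[1], intensityRange[2])
}
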