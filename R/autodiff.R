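# Minimal reverse-mode automatic differentiation on matrices.
#
# This is the package's numerics core for every trainable component (the
# convolutional branch, the transformer text encoder with its low-rank
# adapters, cross-attention fusion, gating, and the composite loss). Nodes
# are environments holding a value, an accumulated gradient, and a backward
# closure; a tape records creation order and backward() replays it in
# reverse. All values are numeric matrices (scalars are 1x1).
#
# The engine is deliberately small: only the operations the model family
# needs, each with a closed-form backward that is finite-difference checked
# in the test suite.

adTape <- function() {
  t <- new.env(parent = emptyenv())
  t$last <- NULL
  t$n <- 0L
  t
}

# Nodes form a singly linked list (constant-time append; backward walks
# the chain in reverse creation order). `need` marks nodes whose gradient
# is required (parameters and anything downstream of one); backward work
# is skipped for the rest, so constant inputs (image patches, pooling
# matrices, frozen encoder weights) cost nothing beyond their forward
# value.
ad_node <- function(tape, val, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  need <- FALSE
  for (p in parents) if (p$need) { need <- TRUE; break }
  nd$need <- need
  nd$prev <- tape$last
  tape$last <- nd
  tape$n <- tape$n + 1L
  nd
}

#' Create a constant (non-trainable) tape node
#' @param tape a tape from \code{adTape()}.
#' @param val numeric matrix (or vector, treated as one row).
#' @export
adConst <- function(tape, val) {
  ad_node(tape, as_mat(val))
}

#' Create a parameter (trainable leaf) tape node
#' @param tape a tape from \code{adTape()}.
#' @param val numeric matrix of initial values.
#' @export
adParam <- function(tape, val) {
  nd <- ad_node(tape, as_mat(val))
  nd$need <- TRUE
  nd
}

#' Mark an existing node as requiring gradients (e.g. activations probed
#' by saliency methods)
#' @param node a tape node.
#' @export
adRequireGrad <- function(node) {
  node$need <- TRUE
  node
}

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, nrow = 1)
}

acc_grad <- function(node, g) {
  if (!node$need) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Run backward pass from a scalar node
#' @param tape the tape.
#' @param loss a 1x1 node.
#' @export
adBackward <- function(tape, loss) {
  stopifnot(length(loss$val) == 1L)
  loss$grad <- matrix(1, 1, 1)
  nd <- tape$last
  while (!is.null(nd)) {
    if (nd$need && !is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
    nd <- nd$prev
  }
  invisible(NULL)
}

# --- arithmetic -----------------------------------------------------------

adMatmul <- function(tape, a, b) {
  ad_node(tape, a$val %*% b$val, list(a, b), function(g) {
    if (a$need) acc_grad(a, g %*% t(b$val))
    if (b$need) acc_grad(b, t(a$val) %*% g)
  })
}

# addition with row-vector or scalar broadcast on b
adAdd <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  val <- if (identical(dim(av), dim(bv))) av + bv
         else if (length(bv) == 1L) av + bv[1L]
         else sweep(av, 2, as.numeric(bv), "+")
  ad_node(tape, val, list(a, b), function(g) {
    acc_grad(a, g)
    if (identical(dim(av), dim(bv))) acc_grad(b, g)
    else if (length(bv) == 1L) acc_grad(b, matrix(sum(g), 1, 1))
    else acc_grad(b, matrix(colSums(g), 1))
  })
}

adSub <- function(tape, a, b) adAdd(tape, a, adScale(tape, b, -1))

# elementwise product with row-vector or scalar broadcast on b
adMul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  bfull <- if (identical(dim(av), dim(bv))) bv
           else if (length(bv) == 1L) matrix(bv[1L], nrow(av), ncol(av))
           else matrix(as.numeric(bv), nrow(av), ncol(av), byrow = TRUE)
  ad_node(tape, av * bfull, list(a, b), function(g) {
    if (a$need) acc_grad(a, g * bfull)
    if (b$need) {
      gb <- g * av
      if (identical(dim(av), dim(bv))) acc_grad(b, gb)
      else if (length(bv) == 1L) acc_grad(b, matrix(sum(gb), 1, 1))
      else acc_grad(b, matrix(colSums(gb), 1))
    }
  })
}

adScale <- function(tape, a, k) {
  ad_node(tape, a$val * k, list(a), function(g) acc_grad(a, g * k))
}

adShift <- function(tape, a, k) {
  ad_node(tape, a$val + k, list(a), function(g) acc_grad(a, g))
}

adDiv <- function(tape, a, b) adMul(tape, a, adPow(tape, b, -1))

# --- nonlinearities -------------------------------------------------------

adRelu <- function(tape, a) {
  m <- a$val > 0
  ad_node(tape, a$val * m, list(a), function(g) acc_grad(a, g * m))
}

adSigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(tape, s, list(a), function(g) acc_grad(a, g * s * (1 - s)))
}

adTanh <- function(tape, a) {
  s <- tanh(a$val)
  ad_node(tape, s, list(a), function(g) acc_grad(a, g * (1 - s^2)))
}

adExp <- function(tape, a) {
  s <- exp(a$val)
  ad_node(tape, s, list(a), function(g) acc_grad(a, g * s))
}

adLog <- function(tape, a, floor = 1e-12) {
  s <- pmax(a$val, floor)
  ad_node(tape, log(s), list(a), function(g)
    acc_grad(a, g * ifelse(a$val > floor, 1 / s, 0)))
}

adPow <- function(tape, a, p) {
  s <- a$val^p
  ad_node(tape, s, list(a), function(g)
    acc_grad(a, g * p * a$val^(p - 1)))
}

adSqrt <- function(tape, a, eps = 1e-12) {
  s <- sqrt(a$val + eps)
  ad_node(tape, s, list(a), function(g) acc_grad(a, g * 0.5 / s))
}

# --- reductions / shape ---------------------------------------------------

adSum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$val), 1, 1), list(a), function(g)
    acc_grad(a, matrix(g[1L], nrow(a$val), ncol(a$val))))
}

adMean <- function(tape, a) {
  n <- length(a$val)
  ad_node(tape, matrix(mean(a$val), 1, 1), list(a), function(g)
    acc_grad(a, matrix(g[1L] / n, nrow(a$val), ncol(a$val))))
}

adRowSums <- function(tape, a) {
  ad_node(tape, matrix(rowSums(a$val), ncol = 1), list(a), function(g)
    acc_grad(a, matrix(g, nrow(a$val), ncol(a$val))))
}

adColMeans <- function(tape, a) {
  n <- nrow(a$val)
  ad_node(tape, matrix(colMeans(a$val), 1), list(a), function(g)
    acc_grad(a, matrix(as.numeric(g) / n, nrow(a$val), ncol(a$val),
                       byrow = TRUE)))
}

adRows <- function(tape, a, idx) {
  ad_node(tape, a$val[idx, , drop = FALSE], list(a), function(g) {
    if (!a$need) return(invisible(NULL))
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    for (j in seq_along(idx))
      ga[idx[j], ] <- ga[idx[j], ] + g[j, ]
    acc_grad(a, ga)
  })
}

adCols <- function(tape, a, idx) {
  ad_node(tape, a$val[, idx, drop = FALSE], list(a), function(g) {
    if (!a$need) return(invisible(NULL))
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    for (j in seq_along(idx))
      ga[, idx[j]] <- ga[, idx[j]] + g[, j]
    acc_grad(a, ga)
  })
}

adReshape <- function(tape, a, nr, nc) {
  d0 <- dim(a$val)
  ad_node(tape, matrix(as.numeric(a$val), nr, nc), list(a), function(g)
    acc_grad(a, matrix(as.numeric(g), d0[1], d0[2])))
}

adTranspose <- function(tape, a) {
  ad_node(tape, t(a$val), list(a), function(g) acc_grad(a, t(g)))
}

adCbind <- function(tape, a, b) {
  na <- ncol(a$val)
  ad_node(tape, cbind(a$val, b$val), list(a, b), function(g) {
    acc_grad(a, g[, seq_len(na), drop = FALSE])
    acc_grad(b, g[, -seq_len(na), drop = FALSE])
  })
}

adRbind <- function(tape, nodes) {
  rows <- vapply(nodes, function(n) nrow(n$val), integer(1))
  ad_node(tape, do.call(rbind, lapply(nodes, function(n) n$val)), nodes,
          function(g) {
    off <- 0L
    for (k in seq_along(nodes)) {
      acc_grad(nodes[[k]], g[(off + 1L):(off + rows[k]), , drop = FALSE])
      off <- off + rows[k]
    }
  })
}

# --- structured ops -------------------------------------------------------

adSoftmaxRows <- function(tape, a) {
  z <- a$val - apply(a$val, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  ad_node(tape, s, list(a), function(g)
    acc_grad(a, (g - rowSums(g * s)) * s))
}

# rowwise layer normalization with learnable gain/bias (1 x d each)
adLayerNorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$val
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$val)
  val <- sweep(sweep(xhat, 2, gv, "*"), 2, as.numeric(beta$val), "+")
  ad_node(tape, val, list(x, gamma, beta), function(g) {
    acc_grad(gamma, matrix(colSums(g * xhat), 1))
    acc_grad(beta, matrix(colSums(g), 1))
    gx <- sweep(g, 2, gv, "*")
    term <- gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)
    acc_grad(x, term * inv)
  })
}

value <- function(node) node$val
gradOf <- function(node) node$grad
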