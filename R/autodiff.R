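# Reverse-mode tape autodiff on dense R arrays.
#
# Feature maps are stored channel-first as [C, H, W, B] so a channel
# slice collapses to a Cin x (Ho*Wo*B) matrix and every convolution
# offset becomes one BLAS matmul.  Dense activations are [n, d] matrices.
# Nodes are environments; the tape is the creation order, so reverse
# iteration is a valid topological order for backpropagation.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$recording <- FALSE

adStartTape <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$ntape <- 0L
  .ad$recording <- TRUE
  invisible(NULL)
}

adStopTape <- function() {
  .ad$recording <- FALSE
  .ad$tape <- NULL
  .ad$ntape <- 0L
  invisible(NULL)
}

# A leaf holding values that may receive gradients (weights, inputs).
adParam <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backward <- NULL
  nd
}

adNode <- function(val, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backward <- backward
  if (.ad$recording && !is.null(backward)) {
    n <- .ad$ntape + 1L
    if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
    .ad$tape[[n]] <- nd
    .ad$ntape <- n
  }
  nd
}

adAccum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the active tape.
adBackward <- function(loss) {
  loss$grad <- 1
  if (.ad$ntape > 0L) {
    for (i in rev(seq_len(.ad$ntape))) {
      nd <- .ad$tape[[i]]
      if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
    }
  }
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

adRelu <- function(x) {
  mask <- x$val > 0
  adNode(x$val * mask, function(nd) adAccum(x, nd$grad * mask))
}

adSigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  adNode(s, function(nd) adAccum(x, nd$grad * s * (1 - s)))
}

adTanh <- function(x) {
  t <- tanh(x$val)
  adNode(t, function(nd) adAccum(x, nd$grad * (1 - t^2)))
}

adSin <- function(x) {
  xv <- x$val
  adNode(sin(xv), function(nd) adAccum(x, nd$grad * cos(xv)))
}

adAdd <- function(x, y) {
  adNode(x$val + y$val, function(nd) {
    adAccum(x, nd$grad)
    adAccum(y, nd$grad)
  })
}

adMul <- function(x, y) {
  adNode(x$val * y$val, function(nd) {
    adAccum(x, nd$grad * y$val)
    adAccum(y, nd$grad * x$val)
  })
}

adOneMinus <- function(x) {
  adNode(1 - x$val, function(nd) adAccum(x, -nd$grad))
}

adDropout <- function(x, rate, train = TRUE) {
  if (!train || rate <= 0) return(x)
  mask <- (array(runif(length(x$val)), dim(x$val) %||% length(x$val)) > rate) / (1 - rate)
  adNode(x$val * mask, function(nd) adAccum(x, nd$grad * mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- dense ----------------------------------------------------------------

adMatmul <- function(x, w) {
  adNode(x$val %*% w$val, function(nd) {
    adAccum(x, nd$grad %*% t(w$val))
    adAccum(w, crossprod(x$val, nd$grad))
  })
}

adAddBias <- function(x, b) {
  adNode(sweep(x$val, 2, b$val, "+"), function(nd) {
    adAccum(x, nd$grad)
    adAccum(b, colSums(nd$grad))
  })
}

adConcatCols <- function(x, y) {
  nx <- ncol(x$val)
  adNode(cbind(x$val, y$val), function(nd) {
    adAccum(x, nd$grad[, seq_len(nx), drop = FALSE])
    adAccum(y, nd$grad[, -seq_len(nx), drop = FALSE])
  })
}

# Mean softmax cross-entropy; labels are 1-based integers.
adSoftmaxCE <- function(logits, labels, nclass) {
  z <- logits$val
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  adNode(loss, function(nd) {
    g <- p
    g[idx] <- g[idx] - 1
    adAccum(logits, nd$grad * g / n)
  })
}

# Mean squared error against a one-hot target matrix.
adMSE <- function(x, target) {
  d <- x$val - target
  adNode(mean(d^2), function(nd) adAccum(x, nd$grad * 2 * d / length(d)))
}

adSoftmaxProbs <- function(logits) {
  z <- logits$val - apply(logits$val, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

## ---- convolution path ([C, H, W, B]) --------------------------------------

.padCHWB <- function(xv, pad) {
  if (pad == 0) return(xv)
  d <- dim(xv)
  xp <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- xv
  xp
}

# Flattened column indices of the (stride-strided) output grid inside a
# padded [C, Hp, Wp, B] tensor viewed as a [C, Hp*Wp*B] matrix; adding
# (i-1) + (j-1)*Hp shifts to kernel offset (i, j).
.convColBase <- function(Hp, Wp, B, Ho, Wo, stride) {
  ri <- seq.int(1L, by = stride, length.out = Ho)
  ci <- seq.int(0L, by = stride, length.out = Wo) * Hp
  bi <- (seq_len(B) - 1L) * (Hp * Wp)
  rc <- outer(ri, ci, "+")
  as.integer(outer(as.vector(rc), bi, "+"))
}

# K x (kh*kw) matrix of column indices, offsets ordered i-fastest.
.convColMat <- function(base, kh, kw, Hp) {
  off <- as.integer(outer(seq_len(kh) - 1L, (seq_len(kw) - 1L) * Hp, "+"))
  matrix(rep(base, length(off)) + rep(off, each = length(base)),
         length(base), length(off))
}

# wv: [Cin, Cout, kh, kw]; bias length Cout.
adConv2d <- function(x, w, b, stride = 1L, pad = NULL) {
  xv <- x$val
  wv <- w$val
  d <- dim(xv)
  Cin <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  kh <- dim(wv)[3]; kw <- dim(wv)[4]; Cout <- dim(wv)[2]
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L  # same padding for odd kernels

  if (kh == 1L && kw == 1L && pad == 0L && stride == 1L) {
    # 1x1 fast path: plain channel mixing.
    K <- H * W * B
    xm <- xv; dim(xm) <- c(Cin, K)
    Wm <- wv; dim(Wm) <- c(Cin, Cout)
    yv <- crossprod(Wm, xm) + b$val
    dim(yv) <- c(Cout, H, W, B)
    return(adNode(yv, function(nd) {
      dy <- nd$grad; dim(dy) <- c(Cout, K)
      dw <- tcrossprod(xm, dy); dim(dw) <- dim(wv)
      adAccum(w, dw)
      adAccum(b, rowSums(dy))
      dx <- Wm %*% dy; dim(dx) <- d
      adAccum(x, dx)
    }))
  }

  xp <- .padCHWB(xv, pad)
  Hp <- dim(xp)[2]; Wp <- dim(xp)[3]
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  K <- Ho * Wo * B
  dim(xp) <- c(Cin, Hp * Wp * B)
  base <- .convColBase(Hp, Wp, B, Ho, Wo, stride)
  nk <- kh * kw

  colsMat <- .convColMat(base, kh, kw, Hp)

  if (Cin <= 2L * Cout) {
    # narrow input: full im2col, one GEMM over a (Cin*nk) x K patch
    patch <- cpp_im2col(xp, colsMat)
    Wm <- aperm(wv, c(1, 3, 4, 2))          # (cin, i, j) major
    dim(Wm) <- c(Cin * nk, Cout)
    yv <- crossprod(Wm, patch) + b$val
    dim(yv) <- c(Cout, Ho, Wo, B)
    return(adNode(yv, function(nd) {
      dy <- nd$grad; dim(dy) <- c(Cout, K)
      dwm <- tcrossprod(patch, dy)          # (Cin*nk) x Cout
      dim(dwm) <- c(Cin, kh, kw, Cout)
      adAccum(w, aperm(dwm, c(1, 4, 2, 3)))
      adAccum(b, rowSums(dy))
      dpatch <- Wm %*% dy
      dxp <- matrix(0, Cin, Hp * Wp * B)
      cpp_col2im_add(dxp, colsMat, dpatch)
      if (pad > 0) {
        dim(dxp) <- c(Cin, Hp, Wp, B)
        dx <- dxp[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
      } else dx <- dxp
      dim(dx) <- d
      adAccum(x, dx)
    }))
  }

  # wide input: accumulate one GEMM per kernel offset (inner dim Cin)
  ymat <- matrix(b$val, Cout, K)
  for (o in seq_len(nk)) {
    i <- (o - 1L) %% kh + 1L
    j <- (o - 1L) %/% kh + 1L
    xs <- cpp_gather_cols(xp, colsMat[, o])
    ymat <- ymat + crossprod(matrix(wv[, , i, j], Cin, Cout), xs)
  }
  yv <- ymat
  dim(yv) <- c(Cout, Ho, Wo, B)
  adNode(yv, function(nd) {
    dy <- nd$grad; dim(dy) <- c(Cout, K)
    dyT <- t(dy)
    dxp <- matrix(0, Cin, Hp * Wp * B)
    dw <- array(0, dim(wv))
    for (o in seq_len(nk)) {
      i <- (o - 1L) %% kh + 1L
      j <- (o - 1L) %/% kh + 1L
      xs <- cpp_gather_cols(xp, colsMat[, o])
      dw[, , i, j] <- xs %*% dyT
      cpp_scatter_add_cols(dxp, colsMat[, o],
                           matrix(wv[, , i, j], Cin, Cout) %*% dy)
    }
    adAccum(w, dw)
    adAccum(b, rowSums(dy))
    if (pad > 0) {
      dim(dxp) <- c(Cin, Hp, Wp, B)
      dx <- dxp[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
    } else dx <- dxp
    dim(dx) <- d
    adAccum(x, dx)
  })
}

adMaxPool <- function(x, k = 2L, stride = k, pad = 0L) {
  xv <- x$val
  d <- dim(xv)
  if (pad > 0) {  # padded border must never win the max
    xp <- array(-Inf, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
    xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- xv
  } else xp <- xv
  Hp <- dim(xp)[2]; Wp <- dim(xp)[3]
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  K <- Ho * Wo * d[4]
  dim(xp) <- c(d[1], Hp * Wp * d[4])
  base <- .convColBase(Hp, Wp, d[4], Ho, Wo, stride)
  colsMat <- .convColMat(base, k, k, Hp)
  best <- matrix(-Inf, d[1], K)
  arg <- matrix(0L, d[1], K)
  for (o in seq_len(k * k)) {
    xs <- cpp_gather_cols(xp, colsMat[, o])
    upd <- xs > best
    best[upd] <- xs[upd]
    arg[upd] <- o
  }
  yv <- best
  dim(yv) <- c(d[1], Ho, Wo, d[4])
  adNode(yv, function(nd) {
    dy <- nd$grad; dim(dy) <- c(d[1], K)
    dxp <- matrix(0, d[1], Hp * Wp * d[4])
    for (o in seq_len(k * k)) {
      cpp_scatter_add_cols(dxp, colsMat[, o], dy * (arg == o))
    }
    if (pad > 0) {
      dim(dxp) <- c(d[1], Hp, Wp, d[4])
      dx <- dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
    } else dx <- dxp
    dim(dx) <- d
    adAccum(x, dx)
  })
}

# Batch normalization over (H, W, B) per channel.  `layer` carries the
# learnable scale/shift and running statistics (updated in train mode).
adBatchNorm <- function(x, layer, train = TRUE, eps = 1e-5) {
  xv <- x$val
  d <- dim(xv)
  C <- d[1]
  m <- prod(d[-1])
  gamma <- layer$gamma; beta <- layer$beta
  if (!train) {
    # fold into one per-channel affine map (recycled down dim 1)
    istd <- 1 / sqrt(layer$rv$val + eps)
    a <- gamma$val * istd
    bb <- beta$val - layer$rm$val * a
    yv <- xv * a + bb
    return(adNode(yv, function(nd) {
      dy <- nd$grad; dim(dy) <- c(C, m)
      xhat <- (xv - layer$rm$val) * istd
      dim(xhat) <- c(C, m)
      adAccum(gamma, rowSums(dy * xhat))
      adAccum(beta, rowSums(dy))
      dx <- nd$grad * a
      dim(dx) <- d
      adAccum(x, dx)
    }))
  }
  xm <- xv; dim(xm) <- c(C, m)
  mu <- rowMeans(xm)
  v <- rowMeans(xm^2) - mu^2
  layer$rm$val <- 0.9 * layer$rm$val + 0.1 * mu
  layer$rv$val <- 0.9 * layer$rv$val + 0.1 * v * m / max(m - 1, 1)
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd
  yv <- gamma$val * xhat + beta$val
  dim(yv) <- d
  adNode(yv, function(nd) {
    dy <- nd$grad; dim(dy) <- c(C, m)
    adAccum(gamma, rowSums(dy * xhat))
    adAccum(beta, rowSums(dy))
    dxhat <- dy * gamma$val
    dx <- istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    dim(dx) <- d
    adAccum(x, dx)
  })
}

adConcatC <- function(nodes) {
  dims <- lapply(nodes, function(n) dim(n$val))
  cs <- vapply(dims, `[`, integer(1), 1L)
  tot <- sum(cs)
  d1 <- dims[[1]]
  yv <- array(0, c(tot, d1[2], d1[3], d1[4]))
  at <- 0L
  for (i in seq_along(nodes)) {
    yv[at + seq_len(cs[i]), , , ] <- nodes[[i]]$val
    at <- at + cs[i]
  }
  adNode(yv, function(nd) {
    at <- 0L
    for (i in seq_along(nodes)) {
      adAccum(nodes[[i]], nd$grad[at + seq_len(cs[i]), , , , drop = FALSE])
      at <- at + cs[i]
    }
  })
}

adSplitC <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    lo <- at + 1L; hi <- at + s
    at <<- hi
    adNode(x$val[lo:hi, , , , drop = FALSE], local({
      lo0 <- lo; hi0 <- hi
      function(nd) {
        g <- array(0, dim(x$val))
        g[lo0:hi0, , , ] <- nd$grad
        adAccum(x, g)
      }
    }))
  })
}

# Global average pooling: [C, H, W, B] -> [B, C] feature matrix.
adGlobalAvgPool <- function(x) {
  d <- dim(x$val)
  C <- d[1]; hw <- d[2] * d[3]; B <- d[4]
  xm <- matrix(x$val, C * d[2] * d[3], B)
  # mean over H, W per (C, B)
  y <- t(apply(array(x$val, c(C, hw, B)), c(1, 3), mean))  # [B, C]
  adNode(y, function(nd) {
    g <- t(nd$grad) / hw  # [C, B]
    dx <- array(0, d)
    for (b in seq_len(B)) dx[, , , b] <- array(rep(g[, b], hw), c(C, d[2], d[3]))
    adAccum(x, dx)
  })
}

## ---- parameters and optimizer ---------------------------------------------

# He-uniform initialized convolution parameter pair.
mkConv <- function(Cin, Cout, k, stride = 1L) {
  fan <- Cin * k * k
  lim <- sqrt(6 / fan)
  list(type = "conv",
       W = adParam(array(runif(Cin * Cout * k * k, -lim, lim), c(Cin, Cout, k, k))),
       b = adParam(numeric(Cout)),
       stride = as.integer(stride))
}

mkBN <- function(C) {
  list(type = "bn",
       gamma = adParam(rep(1, C)), beta = adParam(numeric(C)),
       rm = adParam(numeric(C)), rv = adParam(rep(1, C)))
}

mkDense <- function(din, dout, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / din)
  list(type = "dense",
       W = adParam(matrix(rnorm(din * dout, sd = scale), din, dout)),
       b = adParam(numeric(dout)))
}

# Collect every adParam reachable in a (nested) layer list.
adCollectParams <- function(x) {
  out <- list()
  walk <- function(e) {
    if (is.environment(e)) {
      out[[length(out) + 1L]] <<- e
    } else if (is.list(e)) {
      for (i in seq_along(e)) {
        nm <- names(e)[i]
        if (!is.null(nm) && nm %in% c("rm", "rv")) next  # running stats: not trained
        walk(e[[i]])
      }
    }
  }
  walk(x)
  out
}

adZeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

adamInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0))
}

adamStep <- function(params, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * p$val
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g^2
    p$val <- p$val - lr * (st$m[[i]] / b1t) / (sqrt(st$v[[i]] / b2t) + eps)
  }
  st
}
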